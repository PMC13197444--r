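# dualpet

Concordance-aware lesion-level quantification of dual-tracer whole-body
PET, with the downstream outcome analysis used to relate imaging burden to
therapy response and survival.

In myeloma imaged with two PET tracers — a glucose-metabolism tracer
("FDG") marking vital disease and a CXCR4-directed tracer marking the
therapeutic target — the biology of a lesion depends on whether it is seen
by both tracers. `dualpet` makes that distinction quantitative:

* **Lesion extraction** — connected components (26-connectivity) of
  per-tracer segmentation masks on NIfTI volumes in SUV units.
* **Concordance adjudication** — a lesion is *concordant* when a
  cross-tracer pair of segmentations overlaps by strictly more than 10% of
  the smaller volume, `|A ∩ B| / min(|A|, |B|) > 0.10`; otherwise it is
  FDG-only or CXCR4-only. Concordant partner groups count as one lesion,
  so concordant + FDG-only + CXCR4-only partitions the lesion total.
* **Site classification** — medullary when ≥ 10% of lesion voxels fall in
  the bone mask, extramedullary otherwise; splenic lesions are flagged and
  excluded from the spleen reference uptake.
* **Patient features** — SUVmean (volume-weighted), SUVmax, MTV, and
  TLG/TLC (MTV × SUVmean) per stratum in bracket notation, e.g.
  `SUVmean[FDG medullary concordant]`; plus `sDmax` (maximum inter-lesion
  centroid distance in cm standardized by DuBois body-surface area, cm/m²)
  and spleen SUVmean.
* **Outcome analysis** — Welch tests with Hedges' g and CIs;
  chi-square/Fisher with odds ratios; median-split Kaplan–Meier, log-rank
  tests and event-rate-ratio hazard ratios; decision trees under repeated
  stratified 5-fold cross-validation (10 repeats) with **exact single-tree
  SHAP** attribution aggregated across validation folds, including an
  inter-fold sign-agreement stability score.
* **Synthetic cohort generator** — paired phantom volumes with planted
  lesion categories, geometry, uptake and model-based outcomes, so the
  whole chain is testable without patient data.

## Worked example

Generate a synthetic cohort with known planted effects (responders have
lower `SUVmean[FDG medullary concordant]`; higher
`TLG[FDG medullary concordant]` shortens survival), extract features from
the rendered volumes, and run the analyses:

```r
library(dualpet)

cfg <- synth_config(
  n_patients = 60, seed = 42,
  response_model = list(intercept = 0,
    coef = c("SUVmean[FDG medullary concordant]" = -2)),
  survival_model = list(baseline_hazard = log(2) / 198,
    coef = c("TLG[FDG medullary concordant]" = 1)))
cohort <- generate_cohort(cfg)
feats  <- extract_cohort_features(cohort)$features

# response: Welch + Hedges' g on the planted feature
f <- "SUVmean[FDG medullary concordant]"
r <- feats$response
wt <- welch_test(feats[[f]][r == "responder"],
                 feats[[f]][r == "non_responder"])
#> Welch p = 0.0003, mean diff = -0.69, Hedges g = -0.95 (95% CI -1.50 to -0.41)

# survival: median split, event-rate HR, log-rank
grp <- dichotomize_median(feats[["TLG[FDG medullary concordant]"]])
hi <- grp == "high"
event_rate_hr(feats$os_days[hi],  feats$os_event[hi],
              feats$os_days[!hi], feats$os_event[!hi])
logrank_test(feats$os_days[hi],  feats$os_event[hi],
             feats$os_days[!hi], feats$os_event[!hi])
#> HR = 2.80 (95% CI 1.62-4.84), log-rank p = 0.0016

# decision tree + cross-validated SHAP attribution
run_model(feats, NULL, pipeline_config())$response$features
#>                                   feature mean_abs_shap direction sign_agreement
#>         SUVmean[FDG medullary concordant]    0.21135371        -1              1
#>  SUVmean[CXCR4 extramedullary discordant]    0.01451308         1              1
#>        MTV[FDG extramedullary discordant]    0.01291342         1              1
```

Read: the planted predictor dominates the attribution ranking
(mean |SHAP| 0.21 vs ≤ 0.015 for everything else), its direction is
negative (higher uptake pushes predictions toward non-response) and that
direction is stable in 100% of cross-validation folds. The univariate
results agree: responders are about one pooled standard deviation lower on
the feature (g = −0.95), and the high-TLG half of the cohort dies at 2.8
times the event rate of the low half.

File-based workflows mirror the in-memory one: `write_cohort()` writes the
NIfTI volumes and cohort CSV; `run_extract()`, `run_analyze()` and
`run_model()` consume directories and emit CSV/JSON plus a checksummed run
manifest. A thin CLI wraps the same functions:

```sh
exec/dualpet simulate --out data/ --seed 7
exec/dualpet extract  --in data/ --out results/
exec/dualpet analyze  --features results/features.csv --out results/
exec/dualpet model    --features results/features.csv --out results/
```

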