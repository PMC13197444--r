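#' Configuration for the synthetic paired-PET cohort generator
#'
#' Defines the study conditions the phantom cohort emulates: per-patient
#' lesion counts drawn uniformly from `lesions_per_patient_range` (default
#' 20-109, giving a median of 64.5), a per-patient concordant-lesion
#' fraction drawn from a Beta distribution with mean
#' `concordant_fraction_mean` (default 0.40) and concentration
#' `fraction_concentration` (default 5, spreading patients over roughly
#' 5-90% concordance), and likewise an extramedullary fraction (default
#' mean 0.40).  Discordant lesions are FDG-only with probability
#' `fdg_only_fraction` (default 0.206, i.e. about one FDG-only lesion for
#' every four CXCR4-only lesions).  Lesions are uniform-uptake spheres
#' (optionally Gaussian-tapered) with radii drawn from
#' `lesion_radius_mm_range` and peak SUVs drawn per tracer and concordance
#' class from lognormal distributions.  Outcomes are generated from the
#' planted (ground-truth) patient features: response through a logistic
#' model and survival through an exponential model with independent
#' exponential censoring.
#'
#' @param n_patients Number of patients (default 22).
#' @param grid_shape Integer length-3 voxel grid (default `c(64, 64, 96)`).
#' @param voxel_spacing_mm Positive length-3 voxel pitch (default 3 mm
#'   isotropic).
#' @param lesions_per_patient_range Integer interval, default `c(20, 109)`.
#' @param concordant_fraction_mean Mean per-patient concordant fraction in
#'   \[0, 1\] (default 0.40).
#' @param extramedullary_fraction_mean Mean per-patient extramedullary
#'   fraction in \[0, 1\] (default 0.40).
#' @param fraction_concentration Beta concentration for both per-patient
#'   fractions; 0 makes them deterministic at their means.
#' @param fdg_only_fraction Probability a discordant lesion is FDG-only.
#' @param suv_params Per-tracer, per-class lognormal `meanlog`/`sdlog` for
#'   lesion peak SUV; see default for the structure.
#' @param background_suv Background SUV inside the body (default 1.0).
#' @param lesion_radius_mm_range Radius interval in mm (default `c(3, 6)`).
#' @param radius_jitter_sdlog Lognormal sd of the independent per-tracer
#'   radius jitter applied to concordant pairs (default 0.12; 0 makes the
#'   two supports identical).
#' @param lesion_profile `"uniform"` (default) or `"gaussian"`.
#' @param response_model List `intercept`, `coef` (named by feature),
#'   `standardize` (default TRUE): logistic model on planted features.
#' @param survival_model List `baseline_hazard` (per day, > 0), `coef`,
#'   `standardize`: exponential proportional-hazards model on planted
#'   features.
#' @param censoring_rate Target marginal censoring probability in \[0, 1\].
#' @param seed Integer seed.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_patients = 22,
                         grid_shape = c(64, 64, 96),
                         voxel_spacing_mm = c(3, 3, 3),
                         lesions_per_patient_range = c(20, 109),
                         concordant_fraction_mean = 0.40,
                         extramedullary_fraction_mean = 0.40,
                         fraction_concentration = 5,
                         fdg_only_fraction = 0.206,
                         suv_params = NULL,
                         background_suv = 1.0,
                         lesion_radius_mm_range = c(3, 6),
                         radius_jitter_sdlog = 0.12,
                         lesion_profile = c("uniform", "gaussian"),
                         response_model = NULL,
                         survival_model = NULL,
                         censoring_rate = 0.15,
                         seed = 1) {
  lesion_profile <- match.arg(lesion_profile)
  chk_frac <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
      stop(sprintf("invalid config field `%s`: must be in [0, 1]", nm),
           call. = FALSE)
  }
  chk_frac(concordant_fraction_mean, "concordant_fraction_mean")
  chk_frac(extramedullary_fraction_mean, "extramedullary_fraction_mean")
  chk_frac(fdg_only_fraction, "fdg_only_fraction")
  chk_frac(censoring_rate, "censoring_rate")
  if (length(grid_shape) != 3 || any(grid_shape < 8))
    stop("invalid config field `grid_shape`: need 3 extents >= 8",
         call. = FALSE)
  if (length(voxel_spacing_mm) != 3 || any(voxel_spacing_mm <= 0))
    stop("invalid config field `voxel_spacing_mm`: must be positive",
         call. = FALSE)
  rng <- lesions_per_patient_range
  if (length(rng) != 2 || any(rng < 0) || rng[1] > rng[2] ||
      any(rng != round(rng)))
    stop("invalid config field `lesions_per_patient_range`", call. = FALSE)
  rr <- lesion_radius_mm_range
  if (length(rr) != 2 || rr[1] > rr[2] || rr[1] < min(voxel_spacing_mm) / 2)
    stop(paste("invalid config field `lesion_radius_mm_range`:",
               "lesion radius must cover at least one voxel"), call. = FALSE)
  if (!is.numeric(background_suv) || background_suv < 0)
    stop("invalid config field `background_suv`", call. = FALSE)
  if (fraction_concentration < 0)
    stop("invalid config field `fraction_concentration`", call. = FALSE)
  if (radius_jitter_sdlog < 0)
    stop("invalid config field `radius_jitter_sdlog`", call. = FALSE)
  if (is.null(suv_params)) {
    suv_params <- list(
      FDG = list(concordant = c(meanlog = log(5), sdlog = 0.35),
                 discordant = c(meanlog = log(4.5), sdlog = 0.35)),
      CXCR4 = list(concordant = c(meanlog = log(6), sdlog = 0.35),
                   discordant = c(meanlog = log(5.5), sdlog = 0.35)))
  }
  for (tr in c("FDG", "CXCR4"))
    for (cl in c("concordant", "discordant"))
      if (is.null(suv_params[[tr]][[cl]]) ||
          !all(c("meanlog", "sdlog") %in% names(suv_params[[tr]][[cl]])))
        stop(sprintf("invalid config field `suv_params$%s$%s`", tr, cl),
             call. = FALSE)
  if (is.null(response_model))
    response_model <- list(
      intercept = 0,
      coef = c("SUVmean[FDG medullary concordant]" = -1.0),
      standardize = TRUE)
  if (is.null(survival_model))
    survival_model <- list(
      baseline_hazard = log(2) / 198,
      coef = c("TLG[FDG medullary concordant]" = 0.5),
      standardize = TRUE)
  if (!is.numeric(survival_model$baseline_hazard) ||
      survival_model$baseline_hazard <= 0)
    stop("invalid config field `survival_model$baseline_hazard`: hazard > 0",
         call. = FALSE)
  if (is.null(response_model$standardize)) response_model$standardize <- TRUE
  if (is.null(survival_model$standardize)) survival_model$standardize <- TRUE
  structure(list(
    n_patients = as.integer(n_patients), grid_shape = as.integer(grid_shape),
    voxel_spacing_mm = as.numeric(voxel_spacing_mm),
    lesions_per_patient_range = as.integer(rng),
    concordant_fraction_mean = concordant_fraction_mean,
    extramedullary_fraction_mean = extramedullary_fraction_mean,
    fraction_concentration = fraction_concentration,
    fdg_only_fraction = fdg_only_fraction,
    suv_params = suv_params, background_suv = background_suv,
    lesion_radius_mm_range = as.numeric(rr),
    radius_jitter_sdlog = radius_jitter_sdlog,
    lesion_profile = lesion_profile,
    response_model = response_model, survival_model = survival_model,
    censoring_rate = censoring_rate, seed = as.integer(seed)),
    class = "synth_config")
}

# Ellipsoidal body, box-spine + cylindrical femurs bone phantom, and a
# small ellipsoidal spleen in the left upper body.  Minimal geometry, but
# sufficient for medullary/extramedullary and spleen classification.
build_anatomy <- function(grid_shape, spacing_mm) {
  ext <- grid_shape * spacing_mm
  ctr <- ext / 2
  pts <- list(x = ((seq_len(grid_shape[1]) - 1) * spacing_mm[1]),
              y = ((seq_len(grid_shape[2]) - 1) * spacing_mm[2]),
              z = ((seq_len(grid_shape[3]) - 1) * spacing_mm[3]))
  X <- array(rep(pts$x, times = grid_shape[2] * grid_shape[3]), grid_shape)
  Y <- array(rep(rep(pts$y, each = grid_shape[1]), times = grid_shape[3]),
             grid_shape)
  Z <- array(rep(pts$z, each = grid_shape[1] * grid_shape[2]), grid_shape)
  body <- ((X - ctr[1]) / (0.47 * ext[1]))^2 +
    ((Y - ctr[2]) / (0.47 * ext[2]))^2 +
    ((Z - ctr[3]) / (0.48 * ext[3]))^2 <= 1
  spine <- abs(X - ctr[1]) <= 15 & abs(Y - ctr[2]) <= 15 &
    Z >= 0.08 * ext[3] & Z <= 0.92 * ext[3]
  femur <- ((X - (ctr[1] - 0.28 * ext[1]))^2 + (Y - ctr[2])^2 <= 12^2 |
              (X - (ctr[1] + 0.28 * ext[1]))^2 + (Y - ctr[2])^2 <= 12^2) &
    Z <= 0.30 * ext[3]
  bone <- (spine | femur) & body
  spl_ctr <- c(ctr[1] + 0.26 * ext[1], ctr[2] - 0.10 * ext[2], 0.68 * ext[3])
  spleen <- ((X - spl_ctr[1]) / 22)^2 + ((Y - spl_ctr[2]) / 16)^2 +
    ((Z - spl_ctr[3]) / 26)^2 <= 1
  spleen <- spleen & body & !bone
  mk <- function(m) scalar_volume(array(as.numeric(m), grid_shape),
                                  spacing_mm, c(0, 0, 0), units = "binary")
  list(body = mk(body), bone = mk(bone), spleen = mk(spleen))
}

#' Plant a spherical lesion into a volume
#'
#' Adds a spherical-support blob centered at `center_mm`: the support is the
#' set of voxels whose centers lie within `radius_mm` (or, when no voxel
#' center falls inside a degenerately small radius, the single voxel
#' containing the center).  With the `"uniform"` profile every support voxel
#' takes `peak_suv`; with `"gaussian"` the value tapers as
#' `background + (peak - background) * exp(-d^2 / (2 * (radius/2)^2))`.
#' Existing values are never lowered (the blob is combined with `pmax`), so
#' blob values stay at or above background inside the support.
#'
#' @param volume A `scalar_volume` to paint into.
#' @param center_mm Physical center (mm); must lie inside the grid.
#' @param radius_mm Sphere radius (mm).
#' @param peak_suv Peak uptake value.
#' @param profile `"uniform"` (default) or `"gaussian"`.
#' @param background Background level for the Gaussian taper (default 0).
#' @return List: `volume` (updated) and `support` (linear voxel indices).
#' @export
plant_lesion <- function(volume, center_mm, radius_mm, peak_suv,
                         profile = c("uniform", "gaussian"), background = 0) {
  profile <- match.arg(profile)
  stopifnot(inherits(volume, "scalar_volume"))
  dm <- dim(volume$values)
  sp <- volume$spacing_mm; or <- volume$origin_mm
  lo_mm <- or - sp / 2; hi_mm <- or + (dm - 0.5) * sp
  if (any(center_mm < lo_mm) || any(center_mm > hi_mm))
    stop("lesion center lies outside the grid", call. = FALSE)
  lo <- pmax(1, ceiling((center_mm - radius_mm - or) / sp) + 1)
  hi <- pmin(dm, floor((center_mm + radius_mm - or) / sp) + 1)
  support <- integer(0)
  if (all(lo <= hi)) {
    gi <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2],
                                k = lo[3]:hi[3]))
    cen <- sweep(sweep(gi - 1, 2, sp, "*"), 2, or, "+")
    d2 <- rowSums(sweep(cen, 2, center_mm, "-")^2)
    inside <- d2 <= radius_mm^2
    if (any(inside)) {
      lin <- (gi[inside, 3] - 1) * dm[1] * dm[2] +
        (gi[inside, 2] - 1) * dm[1] + gi[inside, 1]
      support <- as.integer(lin)
      d2 <- d2[inside]
    }
  }
  if (length(support) == 0L) {
    idx <- pmin(dm, pmax(1, round((center_mm - or) / sp) + 1))
    support <- as.integer((idx[3] - 1) * dm[1] * dm[2] +
                            (idx[2] - 1) * dm[1] + idx[1])
    d2 <- 0
  }
  vals <- if (profile == "uniform") rep(peak_suv, length(support))
  else background + (peak_suv - background) *
    exp(-d2 / (2 * (radius_mm / 2)^2))
  volume$values[support] <- pmax(volume$values[support], vals)
  list(volume = volume, support = support)
}

# Mean of the Gaussian taper over the sphere, as a fraction of
# (peak - background): 3 * int_0^1 u^2 exp(-2 u^2) du.
gauss_sphere_mean_factor <- function() {
  stats::integrate(function(u) 3 * u^2 * exp(-2 * u^2), 0, 1)$value
}

draw_fraction <- function(n, mean, conc) {
  if (conc == 0 || mean == 0 || mean == 1) return(rep(mean, n))
  stats::rbeta(n, mean * conc, (1 - mean) * conc)
}

# Sample one patient's lesion plan: categories, sites, per-tracer radii and
# peak SUVs, and non-overlapping centers inside the anatomy.  All random
# draws happen here so rendering does not consume the RNG stream.
plan_patient <- function(config, anatomy, pool_bone, pool_soft) {
  rng <- config$lesions_per_patient_range
  n <- if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1)
  p_conc <- draw_fraction(1, config$concordant_fraction_mean,
                          config$fraction_concentration)
  p_em <- draw_fraction(1, config$extramedullary_fraction_mean,
                        config$fraction_concentration)
  if (n == 0)
    return(list(lesions = empty_plan(), p_conc = p_conc, p_em = p_em))
  concordant <- stats::runif(n) < p_conc
  category <- ifelse(concordant, "concordant",
                     ifelse(stats::runif(n) < config$fdg_only_fraction,
                            "FDG_only", "CXCR4_only"))
  site <- ifelse(stats::runif(n) < p_em, "extramedullary", "medullary")
  radius <- stats::runif(n, config$lesion_radius_mm_range[1],
                         config$lesion_radius_mm_range[2])
  jit <- matrix(exp(stats::rnorm(2 * n, 0, config$radius_jitter_sdlog)),
                n, 2)
  r_fdg <- ifelse(category == "CXCR4_only", NA_real_,
                  radius * ifelse(category == "concordant", jit[, 1], 1))
  r_cx <- ifelse(category == "FDG_only", NA_real_,
                 radius * ifelse(category == "concordant", jit[, 2], 1))
  draw_peak <- function(tracer, cls) {
    par <- config$suv_params[[tracer]][[
      if (cls == "concordant") "concordant" else "discordant"]]
    max(config$background_suv + 0.1,
        stats::rlnorm(1, par[["meanlog"]], par[["sdlog"]]))
  }
  peak_fdg <- vapply(seq_len(n), function(i)
    if (category[i] == "CXCR4_only") NA_real_
    else draw_peak("FDG", category[i]), numeric(1))
  peak_cx <- vapply(seq_len(n), function(i)
    if (category[i] == "FDG_only") NA_real_
    else draw_peak("CXCR4", category[i]), numeric(1))
  # sequential placement with pairwise separation: the gap must exceed the
  # voxel diagonal so distinct lesions cannot touch under 26-connectivity
  sp <- config$voxel_spacing_mm
  gap <- 2 * max(sp)
  vol <- anatomy$body
  dm <- dim(vol$values)
  centers <- matrix(NA_real_, n, 3)
  r_eff <- pmax(r_fdg, r_cx, na.rm = TRUE)
  keep <- logical(n)
  for (i in seq_len(n)) {
    pool <- if (site[i] == "medullary") pool_bone else pool_soft
    placed <- FALSE
    for (try in seq_len(240)) {
      if (try %% 40 == 0) {   # crowded: shrink this lesion and retry
        shrink <- 0.75
        r_fdg[i] <- r_fdg[i] * shrink; r_cx[i] <- r_cx[i] * shrink
        r_eff[i] <- r_eff[i] * shrink
      }
      cand_lin <- pool[sample.int(length(pool), 1)]
      cand <- (arrayInd(cand_lin, dm) - 1) * sp
      prev <- which(keep[seq_len(i - 1)])
      if (length(prev)) {
        dists <- sqrt(rowSums(sweep(centers[prev, , drop = FALSE], 2,
                                    as.numeric(cand), "-")^2))
        if (any(dists < r_eff[i] + r_eff[prev] + gap)) next
      }
      centers[i, ] <- cand
      keep[i] <- TRUE
      placed <- TRUE
      break
    }
    if (!placed) keep[i] <- FALSE
  }
  if (!all(keep))
    warning(sprintf("dropped %d unplaceable lesion(s)", sum(!keep)))
  lesions <- data.frame(
    lesion_id = seq_len(sum(keep)),
    category = category[keep], site = site[keep],
    center_x_mm = centers[keep, 1], center_y_mm = centers[keep, 2],
    center_z_mm = centers[keep, 3],
    radius_fdg_mm = r_fdg[keep], radius_cxcr4_mm = r_cx[keep],
    peak_suv_fdg = peak_fdg[keep], peak_suv_cxcr4 = peak_cx[keep],
    stringsAsFactors = FALSE)
  list(lesions = lesions, p_conc = p_conc, p_em = p_em)
}

empty_plan <- function() {
  data.frame(lesion_id = integer(0), category = character(0),
             site = character(0), center_x_mm = numeric(0),
             center_y_mm = numeric(0), center_z_mm = numeric(0),
             radius_fdg_mm = numeric(0), radius_cxcr4_mm = numeric(0),
             peak_suv_fdg = numeric(0), peak_suv_cxcr4 = numeric(0),
             stringsAsFactors = FALSE)
}

# Ground-truth patient features from the continuous lesion geometry
# (analytic sphere volumes), independent of voxelization.
truth_patient_features <- function(lesions, config, height_cm, weight_kg) {
  out <- stats::setNames(rep(NA_real_, length(canonical_feature_names())),
                         canonical_feature_names())
  gmf <- if (config$lesion_profile == "gaussian")
    gauss_sphere_mean_factor() else 1
  for (tr in c("FDG", "CXCR4")) {
    rcol <- if (tr == "FDG") "radius_fdg_mm" else "radius_cxcr4_mm"
    pcol <- if (tr == "FDG") "peak_suv_fdg" else "peak_suv_cxcr4"
    burden <- if (tr == "FDG") "TLG" else "TLC"
    present <- !is.na(lesions[[rcol]])
    les <- lesions[present, , drop = FALSE]
    vol_ml <- 4 / 3 * pi * les[[rcol]]^3 / 1000
    suv_mean <- if (config$lesion_profile == "uniform") les[[pcol]]
    else config$background_suv +
      (les[[pcol]] - config$background_suv) * gmf
    cls <- ifelse(les$category == "concordant", "concordant", "discordant")
    for (st in c("medullary", "extramedullary")) {
      for (cc in c("concordant", "discordant")) {
        sel <- les$site == st & cls == cc
        nm <- function(metric) bracket_name(metric, tr, st, cc)
        if (any(sel)) {
          out[nm("SUVmean")] <- sum(suv_mean[sel] * vol_ml[sel]) /
            sum(vol_ml[sel])
          out[nm("SUVmax")] <- max(les[[pcol]][sel])
          out[nm("MTV")] <- sum(vol_ml[sel])
          out[nm(burden)] <- sum(suv_mean[sel] * vol_ml[sel])
        } else {
          out[nm("MTV")] <- 0
          out[nm(burden)] <- 0
        }
      }
    }
    cents <- as.matrix(les[, c("center_x_mm", "center_y_mm", "center_z_mm")])
    out[paste0("sDmax_", tr)] <- sdmax(cents, height_cm, weight_kg)
  }
  out["spleen_SUVmean"] <- config$background_suv
  out
}

draw_clinical <- function(n) {
  age <- round(pmin(80, pmax(35, stats::rnorm(n, 56, 8))))
  sex <- ifelse(stats::runif(n) < 0.455, "F", "M")
  height <- round(stats::rnorm(n, 172, 9), 1)
  bmi <- round(pmin(43, pmax(18, stats::rnorm(n, 27, 4.5))), 1)
  weight <- round(bmi * (height / 100)^2, 1)
  data.frame(
    age_years = age, sex = sex, height_cm = height, weight_kg = weight,
    bmi_kg_m2 = round(weight / (height / 100)^2, 1),
    highrisk_cytogenetics = as.integer(stats::runif(n) < 0.583),
    b2m_mg_l = round(stats::rlnorm(n, log(2.95), 0.6), 2),
    disease_duration_months = round(stats::rlnorm(n, log(49.5), 0.8), 1),
    stringsAsFactors = FALSE)
}

#' Generate outcomes from planted feature values
#'
#' Response is Bernoulli with success probability
#' `plogis(intercept + sum(coef * z))` over the (optionally standardized)
#' planted features; survival time is exponential with hazard
#' `baseline_hazard * exp(sum(coef * z))`; censoring is an independent
#' exponential time calibrated so that the marginal probability of being
#' censored first is approximately `censoring_rate` at baseline.  Missing
#' feature values contribute zero to the linear predictors (mean
#' imputation on the standardized scale).
#'
#' @param truth_features Data frame of planted patient features (bracket
#'   columns).
#' @param response_model,survival_model Model lists as in [synth_config()].
#' @param censoring_rate Target marginal censoring probability.
#' @param seed Optional integer seed (`NULL` uses the current RNG state).
#' @return Data frame: `response` (factor, levels
#'   `c("non_responder", "responder")`), `os_days`, `os_event`,
#'   `lp_response`, `lp_survival`.
#' @export
assign_outcomes <- function(truth_features, response_model, survival_model,
                            censoring_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(truth_features)
  lp <- function(model) {
    out <- rep(if (is.null(model$intercept)) 0 else model$intercept, n)
    for (nm in names(model$coef)) {
      if (!nm %in% colnames(truth_features))
        stop(sprintf("model coefficient names unknown feature `%s`", nm),
             call. = FALSE)
      v <- truth_features[[nm]]
      if (isTRUE(model$standardize)) {
        mu <- mean(v, na.rm = TRUE)
        sdv <- stats::sd(v, na.rm = TRUE)
        v <- if (is.na(sdv) || sdv == 0) rep(0, n) else (v - mu) / sdv
      }
      v[is.na(v)] <- 0
      out <- out + model$coef[[nm]] * v
    }
    out
  }
  lp_resp <- lp(response_model)
  response <- stats::rbinom(n, 1, stats::plogis(lp_resp))
  lp_surv <- lp(survival_model)
  h0 <- survival_model$baseline_hazard
  t_event <- stats::rexp(n, rate = h0 * exp(lp_surv))
  if (censoring_rate <= 0) {
    t_cens <- rep(Inf, n)
  } else if (censoring_rate >= 1) {
    t_cens <- rep(0, n)
  } else {
    t_cens <- stats::rexp(n, rate = h0 * censoring_rate /
                            (1 - censoring_rate))
  }
  data.frame(
    response = factor(ifelse(response == 1, "responder", "non_responder"),
                      levels = c("non_responder", "responder")),
    os_days = round(pmin(t_event, t_cens), 1),
    os_event = as.integer(t_event <= t_cens),
    lp_response = lp_resp, lp_survival = lp_surv)
}

#' Generate a synthetic paired-tracer phantom cohort
#'
#' Draws every patient's lesion plan (categories, sites, radii, peak SUVs,
#' non-overlapping centers), clinical covariates and model-based outcomes,
#' and (optionally) renders the paired SUV volumes and per-tracer lesion
#' masks plus the shared anatomical masks.  The planted ground truth —
#' per-lesion categories and geometry, and patient-level features computed
#' analytically from the continuous spheres — is returned alongside, so
#' recovery tests never need to re-derive it.  Bit-identical output for
#' identical configs (including seed); `render = FALSE` produces exactly
#' the same plans and outcomes without voxel painting.
#'
#' @param config A `synth_config`.
#' @param render Paint voxel volumes (default TRUE).
#' @return A `synth_cohort`: list with `patients` (each: `id`, `volumes`,
#'   `lesion_masks`, `truth` lesion table, `clinical`, `outcome`),
#'   `anatomy` (`body`, `bone`, `spleen` masks), `clinical`,
#'   `truth_features`, `outcomes`, `truth_lesions`, `config`.
#' @export
generate_cohort <- function(config, render = TRUE) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  anatomy <- build_anatomy(config$grid_shape, config$voxel_spacing_mm)
  pool_bone <- which(anatomy$bone$values > 0)
  pool_soft <- which(anatomy$body$values > 0 & anatomy$bone$values == 0)
  n <- config$n_patients
  clinical <- draw_clinical(n)
  ids <- sprintf("P%03d", seq_len(n))
  patients <- vector("list", n)
  truth_rows <- list()
  feat_rows <- matrix(NA_real_, n, length(canonical_feature_names()),
                      dimnames = list(NULL, canonical_feature_names()))
  for (i in seq_len(n)) {
    plan <- plan_patient(config, anatomy, pool_bone, pool_soft)
    les <- plan$lesions
    feat_rows[i, ] <- truth_patient_features(les, config,
                                             clinical$height_cm[i],
                                             clinical$weight_kg[i])
    vols <- NULL; masks <- NULL
    if (render) {
      rendered <- render_patient(les, config, anatomy)
      vols <- rendered$volumes; masks <- rendered$masks
    }
    patients[[i]] <- list(id = ids[i], volumes = vols, lesion_masks = masks,
                          truth = les,
                          planted_concordant_fraction = plan$p_conc,
                          planted_extramedullary_fraction = plan$p_em)
    if (nrow(les))
      truth_rows[[length(truth_rows) + 1L]] <-
        cbind(patient_id = ids[i], les, stringsAsFactors = FALSE)
  }
  truth_features <- as.data.frame(feat_rows, check.names = FALSE)
  outcomes <- assign_outcomes(truth_features, config$response_model,
                              config$survival_model, config$censoring_rate)
  clinical <- cbind(patient_id = ids, clinical, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    patients[[i]]$clinical <- clinical[i, , drop = FALSE]
    patients[[i]]$outcome <- outcomes[i, , drop = FALSE]
  }
  tf <- truth_features
  tf[["patient_id"]] <- ids
  tf <- tf[, c("patient_id", setdiff(names(tf), "patient_id"))]
  structure(list(
    patients = patients, anatomy = anatomy, clinical = clinical,
    truth_features = tf,
    outcomes = cbind(data.frame(patient_id = ids), outcomes),
    truth_lesions = if (length(truth_rows))
      do.call(rbind, truth_rows) else
        cbind(patient_id = character(0), empty_plan()),
    config = config), class = "synth_cohort")
}

render_patient <- function(les, config, anatomy) {
  bg <- scalar_volume(anatomy$body$values * config$background_suv,
                      config$voxel_spacing_mm, c(0, 0, 0), units = "SUV")
  zero_mask <- function() array(0, config$grid_shape)
  vols <- list(FDG = bg, CXCR4 = bg)
  masks <- list(FDG = zero_mask(), CXCR4 = zero_mask())
  paint <- function(tracer, rcol, pcol) {
    v <- vols[[tracer]]
    m <- masks[[tracer]]
    for (i in seq_len(nrow(les))) {
      if (is.na(les[[rcol]][i])) next
      res <- plant_lesion(v, c(les$center_x_mm[i], les$center_y_mm[i],
                               les$center_z_mm[i]),
                          les[[rcol]][i], les[[pcol]][i],
                          profile = config$lesion_profile,
                          background = config$background_suv)
      v <- res$volume
      m[res$support] <- 1
    }
    vols[[tracer]] <<- v
    masks[[tracer]] <<- m
  }
  paint("FDG", "radius_fdg_mm", "peak_suv_fdg")
  paint("CXCR4", "radius_cxcr4_mm", "peak_suv_cxcr4")
  # clip to the body: lesions centered near the surface may poke out
  for (tr in c("FDG", "CXCR4")) {
    vols[[tr]]$values <- vols[[tr]]$values * anatomy$body$values
    masks[[tr]] <- masks[[tr]] * anatomy$body$values
  }
  list(volumes = vols,
       masks = lapply(masks, function(m)
         scalar_volume(m, config$voxel_spacing_mm, c(0, 0, 0),
                       units = "binary")))
}

#' @export
print.synth_cohort <- function(x, ...) {
  nles <- vapply(x$patients, function(p) nrow(p$truth), integer(1))
  cat(sprintf("<synth_cohort> %d patients, %d planted lesions (median %s/patient)\n",
              length(x$patients), sum(nles), stats::median(nles)))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Per patient: `<id>_fdg_pet.nii.gz`, `<id>_cxcr4_pet.nii.gz`,
#' `<id>_fdg_mask.nii.gz`, `<id>_cxcr4_mask.nii.gz`, `<id>_bone.nii.gz`,
#' `<id>_spleen.nii.gz`, `<id>_body.nii.gz`; plus `cohort.csv` (clinical
#' covariates and outcomes), `truth_lesions.csv` and `truth_features.csv`.
#'
#' @param cohort A rendered `synth_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synth_cohort"))
  if (is.null(cohort$patients[[1]]$volumes))
    stop("cohort was generated with render = FALSE; nothing to write",
         call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in cohort$patients) {
    pre <- file.path(dir, p$id)
    write_volume(p$volumes$FDG, paste0(pre, "_fdg_pet.nii.gz"))
    write_volume(p$volumes$CXCR4, paste0(pre, "_cxcr4_pet.nii.gz"))
    write_volume(p$lesion_masks$FDG, paste0(pre, "_fdg_mask.nii.gz"))
    write_volume(p$lesion_masks$CXCR4, paste0(pre, "_cxcr4_mask.nii.gz"))
    write_volume(cohort$anatomy$bone, paste0(pre, "_bone.nii.gz"))
    write_volume(cohort$anatomy$spleen, paste0(pre, "_spleen.nii.gz"))
    write_volume(cohort$anatomy$body, paste0(pre, "_body.nii.gz"))
  }
  cohort_tab <- cbind(cohort$clinical,
                      cohort$outcomes[, c("response", "os_days", "os_event")])
  names(cohort_tab)[names(cohort_tab) == "age_years"] <- "age"
  names(cohort_tab)[names(cohort_tab) == "bmi_kg_m2"] <- "bmi"
  utils::write.csv(cohort_tab, file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth_lesions, file.path(dir, "truth_lesions.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth_features,
                   file.path(dir, "truth_features.csv"), row.names = FALSE)
  invisible(dir)
}

#' Plant a standardized two-group difference in a feature
#'
#' Feature-level simulator for effect-recovery studies: group labels are
#' assigned first, then the feature is drawn as
#' `N(mean_ref + g * sd, sd)` in the first group and `N(mean_ref, sd)` in
#' the second, so the planted standardized mean difference (first minus
#' second) is exactly `g`.
#'
#' @param n Total units.
#' @param g Planted standardized difference.
#' @param mean_ref Reference-group mean (default 5).
#' @param sd Common standard deviation (default 1.2).
#' @param prop_first Proportion in the first group (default 0.5).
#' @param labels Group labels, first and second (default
#'   `c("responder", "non_responder")`).
#' @return Data frame `group` (factor, first label first), `value`.
#' @export
plant_group_difference <- function(n, g, mean_ref = 5, sd = 1.2,
                                   prop_first = 0.5,
                                   labels = c("responder", "non_responder")) {
  n1 <- round(n * prop_first); n2 <- n - n1
  data.frame(
    group = factor(rep(labels, c(n1, n2)), levels = labels),
    value = c(stats::rnorm(n1, mean_ref + g * sd, sd),
              stats::rnorm(n2, mean_ref, sd)))
}

#' Plant a survival rate ratio across a median split
#'
#' Draws a positive burden-like feature (lognormal), splits it at the
#' cohort median, and generates exponential survival with hazard
#' `baseline_hazard * rate_ratio^(group == "high")`, with optional
#' independent exponential censoring as in [assign_outcomes()].
#'
#' @param n Total units.
#' @param rate_ratio True hazard (event-rate) ratio, high vs. low group.
#' @param baseline_hazard Low-group hazard per day.
#' @param censoring_rate Target marginal censoring probability (default 0).
#' @param feature_meanlog,feature_sdlog Lognormal parameters of the
#'   feature.
#' @return Data frame `feature`, `group` (`low`/`high`), `os_days`,
#'   `os_event`.
#' @export
plant_survival_split <- function(n, rate_ratio,
                                 baseline_hazard = log(2) / 198,
                                 censoring_rate = 0,
                                 feature_meanlog = log(50),
                                 feature_sdlog = 0.8) {
  feature <- stats::rlnorm(n, feature_meanlog, feature_sdlog)
  group <- dichotomize_median(feature)
  rate <- baseline_hazard * rate_ratio^(group == "high")
  t_event <- stats::rexp(n, rate)
  t_cens <- if (censoring_rate <= 0) rep(Inf, n)
  else if (censoring_rate >= 1) rep(0, n)
  else stats::rexp(n, baseline_hazard * censoring_rate /
                     (1 - censoring_rate))
  data.frame(feature = feature, group = group,
             os_days = pmin(t_event, t_cens),
             os_event = as.integer(t_event <= t_cens))
}
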