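#' Pipeline configuration
#'
#' Resolves the analysis configuration from defaults, an optional YAML file
#' and explicit overrides (in that order of increasing precedence).  Every
#' adjudication rule the pipeline applies is exposed here: the concordance
#' overlap threshold (default 0.10, strict `>`), the bone overlap threshold
#' (default 0.10, inclusive `>=`), the overlap-fraction denominator
#' (default `"min"`), connectivity, sDmax endpoint convention and BSA
#' formula, SUVmean pooling, the survival dichotomization horizon (183
#' days) and the cross-validation layout (5 folds x 10 repeats).
#'
#' @param path Optional YAML file with configuration entries.
#' @param overrides Named list of entries overriding file and defaults.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(path = NULL, overrides = list()) {
  cfg <- list(
    concordance_threshold = 0.10, concordance_strict = TRUE,
    overlap_denominator = "min",
    bone_threshold = 0.10, bone_strict = FALSE,
    connectivity = 26,
    segment_suv_threshold = 2.5, use_threshold_segmentation = FALSE,
    suvmean_pooled = TRUE,
    bsa_formula = "DuBois",
    analysis_unit = "cycle",
    horizon_days = 183,
    cv = list(n_folds = 5, n_repeats = 10, max_depth = 3, min_leaf = 3,
              inner_folds = 3),
    seed = 1)
  if (!is.null(path)) {
    if (!file.exists(path))
      stop(sprintf("config file not found: %s", path), call. = FALSE)
    file_cfg <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, file_cfg)
  }
  cfg <- utils::modifyList(cfg, overrides)
  for (nm in c("concordance_threshold", "bone_threshold"))
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0 || cfg[[nm]] >= 1)
      stop(sprintf("config `%s` must lie in (0, 1)", nm), call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

clinical_columns <- function() {
  c("age", "sex", "height_cm", "weight_kg", "bmi", "highrisk_cytogenetics",
    "b2m_mg_l", "disease_duration_months")
}

# Full per-unit imaging chain: label lesions per tracer, adjudicate
# concordance on the FDG grid, classify site and spleen membership,
# compute per-lesion metrics and the patient feature row.
extract_patient <- function(id, pet_fdg, pet_cxcr4, mask_fdg, mask_cxcr4,
                            bone, spleen, height_cm, weight_kg, config) {
  if (isTRUE(config$use_threshold_segmentation)) {
    body <- scalar_volume(array(1, dim(pet_fdg$values)), pet_fdg$spacing_mm,
                          pet_fdg$origin_mm, units = "binary")
    mask_fdg <- threshold_segment(pet_fdg, config$segment_suv_threshold, body)
    mask_cxcr4 <- threshold_segment(pet_cxcr4, config$segment_suv_threshold,
                                    body)
  }
  ls_fdg <- label_components(mask_fdg, pet_fdg, tracer = "FDG",
                             connectivity = config$connectivity)
  ls_cx <- label_components(mask_cxcr4, pet_cxcr4, tracer = "CXCR4",
                            connectivity = config$connectivity)
  # overlap is computed on the FDG grid; propagate the CXCR4 mask there
  # when the grids differ (each tracer is quantified on its own grid)
  ls_cx_on_fdg <- ls_cx
  if (!same_grid(mask_cxcr4, mask_fdg)) {
    moved <- resample_mask(mask_cxcr4, mask_fdg)
    ls_cx_on_fdg <- label_components(moved, tracer = "CXCR4",
                                     connectivity = config$connectivity)
  }
  pairs <- overlap_matrix(ls_fdg, ls_cx_on_fdg)
  conc <- adjudicate_concordance(pairs, ls_fdg, ls_cx_on_fdg,
                                 threshold = config$concordance_threshold,
                                 denominator = config$overlap_denominator,
                                 strict = config$concordance_strict)
  site_fdg <- classify_site(ls_fdg, bone, threshold = config$bone_threshold,
                            strict = config$bone_strict)
  site_cx <- classify_site(ls_cx, bone, threshold = config$bone_threshold,
                           strict = config$bone_strict)
  spleen_fdg <- flag_spleen(ls_fdg, spleen)
  spleen_cx <- flag_spleen(ls_cx, spleen)
  met_fdg <- lesion_metrics_or_empty(ls_fdg, pet_fdg)
  met_cx <- lesion_metrics_or_empty(ls_cx, pet_cxcr4)
  feats <- aggregate_patient(met_fdg, met_cx, conc$category_a,
                             conc$category_b, site_fdg, site_cx,
                             pooled = isTRUE(config$suvmean_pooled))
  cents <- function(ls) as.matrix(ls$lesions[, c("centroid_x_mm",
                                                 "centroid_y_mm",
                                                 "centroid_z_mm")])
  feats[["sDmax_FDG"]] <- sdmax(cents(ls_fdg), height_cm, weight_kg,
                                bsa_formula = config$bsa_formula)
  feats[["sDmax_CXCR4"]] <- sdmax(cents(ls_cx), height_cm, weight_kg,
                                  bsa_formula = config$bsa_formula)
  feats[["spleen_SUVmean"]] <- spleen_reference(
    pet_fdg, spleen, list(mask_fdg, mask_cxcr4))
  lesion_tab <- rbind(
    lesion_table_rows(id, ls_fdg, met_fdg, conc$category_a, site_fdg,
                      spleen_fdg),
    lesion_table_rows(id, ls_cx, met_cx, conc$category_b, site_cx,
                      spleen_cx))
  pair_tab <- if (nrow(conc$pairs))
    cbind(patient_id = id, conc$pairs, stringsAsFactors = FALSE)
  else cbind(patient_id = character(0), conc$pairs)
  list(features = feats, lesions = lesion_tab, pairs = pair_tab,
       counts = conc$counts)
}

lesion_metrics_or_empty <- function(ls, pet) {
  if (nrow(ls$lesions) == 0L)
    return(data.frame(label = integer(0), n_voxels = integer(0),
                      volume_ml = numeric(0), suv_mean = numeric(0),
                      suv_max = numeric(0), mtv_ml = numeric(0),
                      tl_burden = numeric(0)))
  lesion_metrics(ls, pet)
}

lesion_table_rows <- function(id, ls, met, category, site, in_spleen) {
  data.frame(patient_id = rep(id, nrow(ls$lesions)),
             tracer = rep(ls$tracer, nrow(ls$lesions)),
             lesion_id = ls$lesions$label,
             n_voxels = ls$lesions$n_voxels,
             volume_ml = ls$lesions$volume_ml,
             centroid_x_mm = ls$lesions$centroid_x_mm,
             centroid_y_mm = ls$lesions$centroid_y_mm,
             centroid_z_mm = ls$lesions$centroid_z_mm,
             suv_mean = met$suv_mean, suv_max = met$suv_max,
             category = category, site = site, in_spleen = in_spleen,
             stringsAsFactors = FALSE)
}

#' Extract lesion and patient-level features from a cohort directory
#'
#' Reads the cohort table and the seven per-unit NIfTI volumes, runs the
#' lesion chain (components, concordance, site, spleen, metrics,
#' aggregation) and writes `lesions.csv`, `pairs.csv` and `features.csv`
#' into `out_dir`.  Missing files and grid inconsistencies raise errors
#' naming the unit.
#'
#' @param input_dir Directory with `cohort.csv` and the NIfTI volumes.
#' @param out_dir Output directory.
#' @param config A `pipeline_config`.
#' @return Invisibly, list `features`, `lesions`, `pairs`.
#' @export
run_extract <- function(input_dir, out_dir, config = pipeline_config()) {
  cohort <- utils::read.csv(file.path(input_dir, "cohort.csv"),
                            check.names = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  feats <- list(); lesions <- list(); pairs <- list()
  for (i in seq_len(nrow(cohort))) {
    id <- cohort$patient_id[i]
    pth <- function(suffix) {
      p <- file.path(input_dir, paste0(id, "_", suffix, ".nii.gz"))
      if (!file.exists(p))
        stop(sprintf("unit %s: missing volume file %s", id, p),
             call. = FALSE)
      p
    }
    res <- extract_patient(
      id,
      pet_fdg = read_volume(pth("fdg_pet"), units = "SUV"),
      pet_cxcr4 = read_volume(pth("cxcr4_pet"), units = "SUV"),
      mask_fdg = read_volume(pth("fdg_mask"), units = "binary"),
      mask_cxcr4 = read_volume(pth("cxcr4_mask"), units = "binary"),
      bone = read_volume(pth("bone"), units = "binary"),
      spleen = read_volume(pth("spleen"), units = "binary"),
      height_cm = cohort$height_cm[i], weight_kg = cohort$weight_kg[i],
      config = config)
    if (sum(res$counts$total_unique) == 0)
      message(sprintf("unit %s: no lesions; burden features are zero", id))
    message(sprintf(
      "unit %s: %d concordant unit(s), %d FDG-only, %d CXCR4-only",
      id, res$counts$concordant_units, res$counts$a_only, res$counts$b_only))
    feats[[i]] <- c(list(patient_id = id), as.list(res$features),
                    as.list(cohort[i, intersect(clinical_columns(),
                                                names(cohort)),
                                   drop = FALSE]),
                    as.list(cohort[i, intersect(c("response", "os_days",
                                                  "os_event"), names(cohort)),
                                   drop = FALSE]))
    lesions[[i]] <- res$lesions
    pairs[[i]] <- res$pairs
  }
  features <- do.call(rbind, lapply(feats, function(x)
    as.data.frame(x, check.names = FALSE, stringsAsFactors = FALSE)))
  lesions <- do.call(rbind, lesions)
  pairs <- do.call(rbind, pairs)
  utils::write.csv(features, file.path(out_dir, "features.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(lesions, file.path(out_dir, "lesions.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(pairs, file.path(out_dir, "pairs.csv"),
                   row.names = FALSE, na = "")
  invisible(list(features = features, lesions = lesions, pairs = pairs))
}

#' Extract patient features from an in-memory synthetic cohort
#'
#' Same chain as [run_extract()] without file round-trips; the cohort must
#' have been generated with `render = TRUE`.
#'
#' @param cohort A `synth_cohort`.
#' @param config A `pipeline_config`.
#' @return List `features` (data frame), `lesions`, `pairs`, `counts`.
#' @export
extract_cohort_features <- function(cohort, config = pipeline_config()) {
  stopifnot(inherits(cohort, "synth_cohort"))
  feats <- list(); lesions <- list(); pairs <- list(); counts <- list()
  for (i in seq_along(cohort$patients)) {
    p <- cohort$patients[[i]]
    if (is.null(p$volumes))
      stop("cohort was generated with render = FALSE", call. = FALSE)
    res <- extract_patient(
      p$id, p$volumes$FDG, p$volumes$CXCR4,
      p$lesion_masks$FDG, p$lesion_masks$CXCR4,
      cohort$anatomy$bone, cohort$anatomy$spleen,
      p$clinical$height_cm, p$clinical$weight_kg, config)
    row <- c(list(patient_id = p$id), as.list(res$features))
    feats[[i]] <- as.data.frame(row, check.names = FALSE)
    lesions[[i]] <- res$lesions
    pairs[[i]] <- res$pairs
    counts[[i]] <- res$counts
  }
  features <- do.call(rbind, feats)
  clin <- cohort$clinical
  names(clin)[names(clin) == "age_years"] <- "age"
  names(clin)[names(clin) == "bmi_kg_m2"] <- "bmi"
  features <- merge(features, clin, by = "patient_id", sort = FALSE)
  features <- merge(features, cohort$outcomes[, c("patient_id", "response",
                                                  "os_days", "os_event")],
                    by = "patient_id", sort = FALSE)
  list(features = features, lesions = do.call(rbind, lesions),
       pairs = do.call(rbind, pairs), counts = counts)
}

#' Univariate outcome analysis over a feature matrix
#'
#' For therapy response: Welch tests with Hedges' g for every continuous
#' feature (imaging plus continuous clinical covariates) and
#' chi-square/Fisher tests with odds ratios for binary covariates.  For
#' overall survival: each continuous feature is dichotomized at the cohort
#' median, compared by log-rank test and summarized by the
#' event-rate-ratio hazard ratio (high vs. low); Kaplan-Meier step
#' functions per group are exported for plotting.  Units missing a feature
#' are dropped for that feature (complete-case per feature, with counts
#' reported); constant features are skipped with a warning.  No
#' multiple-comparison correction is applied: p-values are descriptive.
#'
#' @param features Feature matrix with `response`, `os_days`, `os_event`
#'   columns (as from [run_extract()]).
#' @param out_dir Optional output directory for
#'   `response_tests.csv`, `survival_tests.csv`, `km_curves.csv`.
#' @param config A `pipeline_config`.
#' @return List `response_tests`, `survival_tests`, `km_curves`.
#' @export
run_analyze <- function(features, out_dir = NULL,
                        config = pipeline_config()) {
  stopifnot(all(c("response", "os_days", "os_event") %in% names(features)))
  resp <- factor(features$response)
  binary_covs <- intersect(c("sex", "highrisk_cytogenetics"),
                           names(features))
  skip <- c("patient_id", "response", "os_days", "os_event", binary_covs)
  cont <- setdiff(names(features)[vapply(features, is.numeric, logical(1))],
                  skip)
  resp_rows <- list()
  for (f in cont) {
    v <- features[[f]]
    sdv <- stats::sd(v, na.rm = TRUE)
    if (is.na(sdv) || sdv == 0) {
      warning(sprintf("feature `%s` is constant or empty; skipped", f))
      next
    }
    x <- v[resp == levels(resp)[2]]   # responder minus non-responder
    y <- v[resp == levels(resp)[1]]
    if (sum(!is.na(x)) < 2 || sum(!is.na(y)) < 2) next
    wt <- tryCatch(welch_test(x, y), error = function(e) NULL)
    if (is.null(wt)) next
    resp_rows[[f]] <- data.frame(
      feature = f, type = "welch", estimate = wt$mean_diff,
      ci_low = wt$ci95[1], ci_high = wt$ci95[2], p = wt$p_two_sided,
      hedges_g = wt$hedges_g, g_ci_low = wt$g_ci95[1],
      g_ci_high = wt$g_ci95[2], n_group1 = wt$n[1], n_group2 = wt$n[2],
      stringsAsFactors = FALSE)
  }
  for (f in binary_covs) {
    v <- factor(features[[f]])
    if (nlevels(v) != 2) next
    tab <- table(v, resp)
    ct <- tryCatch(contingency_test(tab), error = function(e) NULL)
    if (is.null(ct)) next
    resp_rows[[f]] <- data.frame(
      feature = f, type = ct$method, estimate = ct$odds_ratio,
      ci_low = ct$or_ci95[1], ci_high = ct$or_ci95[2], p = ct$p,
      hedges_g = NA, g_ci_low = NA, g_ci_high = NA,
      n_group1 = sum(tab[, 2]), n_group2 = sum(tab[, 1]),
      stringsAsFactors = FALSE)
  }
  response_tests <- do.call(rbind, resp_rows)
  surv_rows <- list(); km_rows <- list()
  if (sum(features$os_event, na.rm = TRUE) == 0) {
    warning("no events in cohort; survival analysis skipped")
    survival_tests <- NULL
  } else {
    for (f in cont) {
      v <- features[[f]]
      ok <- !is.na(v) & !is.na(features$os_days)
      if (sum(ok) < 4 || stats::sd(v[ok]) == 0) next
      grp <- dichotomize_median(v[ok])
      td <- features$os_days[ok]; ev <- features$os_event[ok]
      if (min(table(grp)) == 0) next
      lr <- suppressWarnings(
        logrank_test(td[grp == "high"], ev[grp == "high"],
                     td[grp == "low"], ev[grp == "low"]))
      hr <- suppressWarnings(
        event_rate_hr(td[grp == "high"], ev[grp == "high"],
                      td[grp == "low"], ev[grp == "low"]))
      surv_rows[[f]] <- data.frame(
        feature = f, median_cut = attr(grp, "median"), hr = hr$hr,
        hr_ci_low = hr$ci95[1], hr_ci_high = hr$ci95[2],
        logrank_chi2 = lr$chi2, logrank_p = lr$p,
        n_high = sum(grp == "high"), n_low = sum(grp == "low"),
        stringsAsFactors = FALSE)
      for (side in c("low", "high")) {
        km <- km_fit(td[grp == side], ev[grp == side])
        km_rows[[paste(f, side)]] <- data.frame(
          feature = f, group = side, time = km$time, surv = km$surv,
          lower = km$lower, upper = km$upper, stringsAsFactors = FALSE)
      }
    }
    survival_tests <- do.call(rbind, surv_rows)
  }
  km_curves <- if (length(km_rows)) do.call(rbind, km_rows) else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(response_tests))
      utils::write.csv(response_tests,
                       file.path(out_dir, "response_tests.csv"),
                       row.names = FALSE, na = "")
    if (!is.null(survival_tests))
      utils::write.csv(survival_tests,
                       file.path(out_dir, "survival_tests.csv"),
                       row.names = FALSE, na = "")
    if (!is.null(km_curves))
      utils::write.csv(km_curves, file.path(out_dir, "km_curves.csv"),
                       row.names = FALSE, na = "")
  }
  list(response_tests = response_tests, survival_tests = survival_tests,
       km_curves = km_curves)
}

#' Decision-tree models with cross-validated SHAP attribution
#'
#' Trains the two parallel binary decision-tree models — therapy response
#' and short (< horizon) vs. long survival — under repeated stratified
#' cross-validation, computes exact SHAP attributions on the validation
#' folds and aggregates them into stability reports.  Units censored alive
#' before the horizon are excluded from the survival model and their count
#' reported.  Missing feature values are routed to the majority child at
#' each split.
#'
#' @param features Feature matrix with outcome columns.
#' @param out_dir Optional directory for `response_attribution.json` and
#'   `survival_attribution.json`.
#' @param config A `pipeline_config`.
#' @return List `response` and `survival`, each an `attribution_report`
#'   (survival additionally records `n_excluded`).
#' @export
run_model <- function(features, out_dir = NULL, config = pipeline_config()) {
  skip <- c("patient_id", "response", "os_days", "os_event", "sex")
  xcols <- setdiff(names(features)[vapply(features, is.numeric,
                                          logical(1))], skip)
  x <- features[, xcols, drop = FALSE]
  cv <- config$cv
  reports <- list()
  y_resp <- factor(features$response,
                   levels = sort(unique(as.character(features$response))))
  if (nlevels(droplevels(y_resp)) < 2)
    stop("response endpoint has a single class", call. = FALSE)
  cvres <- run_cv_shap(x, y_resp, n_folds = cv$n_folds,
                       n_repeats = cv$n_repeats, seed = config$seed,
                       max_depth = cv$max_depth, min_leaf = cv$min_leaf,
                       inner_folds = cv$inner_folds)
  reports$response <- aggregate_attributions(cvres)
  y_surv <- survival_to_binary(features$os_days, features$os_event,
                               config$horizon_days)
  keep <- !is.na(y_surv)
  n_excl <- sum(!keep)
  if (n_excl)
    message(sprintf(
      "%d unit(s) censored before the %d-day horizon excluded from the survival model",
      n_excl, config$horizon_days))
  if (nlevels(droplevels(y_surv[keep])) < 2)
    stop("survival endpoint has a single class after exclusions",
         call. = FALSE)
  cvres2 <- run_cv_shap(x[keep, , drop = FALSE], y_surv[keep],
                        n_folds = cv$n_folds, n_repeats = cv$n_repeats,
                        seed = config$seed + 1, max_depth = cv$max_depth,
                        min_leaf = cv$min_leaf,
                        inner_folds = cv$inner_folds)
  reports$survival <- aggregate_attributions(cvres2)
  reports$survival$n_excluded <- n_excl
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in c("response", "survival")) {
      rep <- reports[[nm]]
      jsonlite::write_json(
        list(features = rep$features, performance = rep$performance,
             n_excluded = if (nm == "survival") n_excl else 0),
        file.path(out_dir, paste0(nm, "_attribution.json")),
        dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }
  reports
}

#' Write a run manifest
#'
#' Records the resolved configuration, package version, seed and MD5
#' checksums of every produced file, so silent changes in intermediate
#' tables are detectable across reruns.
#'
#' @param out_dir Directory whose files are checksummed.
#' @param config The `pipeline_config` used.
#' @param extra Optional named list folded into the manifest.
#' @return Path of the written `manifest.json`, invisibly.
#' @export
write_manifest <- function(out_dir, config, extra = list()) {
  files <- setdiff(list.files(out_dir, full.names = TRUE,
                              recursive = TRUE),
                   file.path(out_dir, "manifest.json"))
  sums <- tools::md5sum(files)
  manifest <- c(list(
    package_version = as.character(utils::packageVersion("dualpet")),
    seed = config$seed,
    config = unclass(config),
    checksums = as.list(stats::setNames(unname(sums), basename(files)))),
    extra)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
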