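small_cfg <- function(...) {
  args <- list(n_patients = 3, grid_shape = c(32, 32, 48),
               lesions_per_patient_range = c(5, 10), seed = 7)
  do.call(synth_config, utils::modifyList(args, list(...)))
}

test_that("cohort generation is deterministic given the seed", {
  c1 <- generate_cohort(small_cfg())
  c2 <- generate_cohort(small_cfg())
  expect_identical(c1$patients[[2]]$volumes$FDG$values,
                   c2$patients[[2]]$volumes$FDG$values)
  expect_identical(c1$patients[[3]]$lesion_masks$CXCR4$values,
                   c2$patients[[3]]$lesion_masks$CXCR4$values)
  expect_identical(c1$outcomes, c2$outcomes)
  expect_identical(c1$truth_lesions, c2$truth_lesions)

  # plan-only generation yields identical plans and outcomes
  c3 <- generate_cohort(small_cfg(), render = FALSE)
  expect_identical(c3$outcomes, c1$outcomes)
  expect_identical(c3$truth_lesions, c1$truth_lesions)
  expect_null(c3$patients[[1]]$volumes)
})

test_that("zero-lesion and forced-concordance corner cases", {
  c0 <- generate_cohort(small_cfg(lesions_per_patient_range = c(0, 0)))
  expect_equal(nrow(c0$truth_lesions), 0)
  expect_equal(sum(c0$patients[[1]]$lesion_masks$FDG$values), 0)
  expect_equal(c0$truth_features[["MTV[FDG medullary concordant]"]],
               rep(0, 3))
  expect_true(all(is.na(c0$truth_features[["SUVmean[FDG medullary concordant]"]])))

  cf <- generate_cohort(small_cfg(concordant_fraction_mean = 1,
                                  fraction_concentration = 0,
                                  radius_jitter_sdlog = 0))
  expect_true(all(cf$truth_lesions$category == "concordant"))
  for (p in cf$patients)
    expect_identical(p$lesion_masks$FDG$values, p$lesion_masks$CXCR4$values)
})

test_that("planted categories partition the lesion total", {
  co <- generate_cohort(small_cfg(seed = 9, n_patients = 4))
  tab <- table(co$truth_lesions$category)
  expect_equal(sum(tab), nrow(co$truth_lesions))
  expect_setequal(intersect(names(tab),
                            c("concordant", "FDG_only", "CXCR4_only")),
                  names(tab))
  # masks are subsets of the body
  for (p in co$patients) {
    expect_true(all(co$anatomy$body$values[p$lesion_masks$FDG$values == 1] == 1))
    expect_true(all(co$anatomy$bone$values * co$anatomy$spleen$values == 0))
  }
})

test_that("defaults are calibrated to the configured cohort profile", {
  cfg <- synth_config(n_patients = 200, seed = 13)
  co <- generate_cohort(cfg, render = FALSE)
  nles <- vapply(co$patients, function(p) nrow(p$truth), integer(1))
  expect_true(all(nles >= 20 & nles <= 109))
  frac <- vapply(co$patients, function(p)
    mean(p$truth$category == "concordant"), numeric(1))
  expect_lt(abs(mean(frac) - 0.40), 0.05)
  em <- vapply(co$patients, function(p)
    mean(p$truth$site == "extramedullary"), numeric(1))
  expect_lt(abs(mean(em) - 0.40), 0.05)
})

test_that("planted lesions have the brute-force voxel support", {
  vol <- make_vol(array(1, c(24, 24, 24)))  # 2 mm spacing
  res <- plant_lesion(vol, center_mm = c(23, 23, 23), radius_mm = 10,
                      peak_suv = 4)
  n_oracle <- 0
  for (i in 1:24) for (j in 1:24) for (k in 1:24)
    if (sum(((c(i, j, k) - 1) * 2 - 23)^2) <= 100) n_oracle <- n_oracle + 1
  expect_equal(length(res$support), n_oracle)
  expect_true(all(res$volume$values[res$support] == 4))

  # degenerate radius: single-voxel lesion
  tiny <- plant_lesion(vol, c(23.3, 22.9, 23.1), radius_mm = 0.4,
                       peak_suv = 9)
  expect_equal(length(tiny$support), 1)

  expect_error(plant_lesion(vol, c(500, 0, 0), 5, 4), "outside")

  # two non-overlapping blobs label as two lesions downstream
  v2 <- plant_lesion(vol, c(10, 10, 10), 5, 4)
  v3 <- plant_lesion(v2$volume, c(36, 36, 36), 5, 4)
  m <- array(0, c(24, 24, 24))
  m[c(v2$support, v3$support)] <- 1
  expect_equal(nrow(label_components(make_mask(m))$lesions), 2)
})

test_that("outcome models follow their closed forms", {
  # null logistic model: response rate ~ logistic(intercept)
  set.seed(17)
  tf <- data.frame(x = rnorm(1000))
  out <- assign_outcomes(tf, list(intercept = 0, coef = c(x = 0)),
                         list(baseline_hazard = 0.01, coef = c(x = 0)),
                         censoring_rate = 0)
  expect_lt(abs(mean(out$response == "responder") - 0.5), 0.065)
  expect_true(all(out$os_event == 1))

  # exponential model with binary covariate: event-rate ratio ~ exp(beta)
  tf2 <- data.frame(x = rep(c(0, 1), each = 1000))
  out2 <- assign_outcomes(
    tf2, list(intercept = 0, coef = NULL),
    list(baseline_hazard = 0.005, coef = c(x = log(2)),
         standardize = FALSE),
    censoring_rate = 0, seed = 23)
  hi <- out2[tf2$x == 1, ]; lo <- out2[tf2$x == 0, ]
  rr <- (sum(hi$os_event) / sum(hi$os_days)) /
    (sum(lo$os_event) / sum(lo$os_days))
  expect_lt(abs(rr - 2) / 2, 0.1)

  # full censoring: no events at all
  out3 <- assign_outcomes(tf, list(intercept = 0, coef = NULL),
                          list(baseline_hazard = 0.01, coef = NULL),
                          censoring_rate = 1)
  expect_equal(sum(out3$os_event), 0)

  expect_error(assign_outcomes(tf, list(intercept = 0, coef = c(zz = 1)),
                               list(baseline_hazard = 0.01, coef = NULL)),
               "zz")
})

test_that("config validation names the offending field", {
  expect_error(synth_config(concordant_fraction_mean = 1.4),
               "concordant_fraction_mean")
  expect_error(synth_config(voxel_spacing_mm = c(3, 0, 3)),
               "voxel_spacing_mm")
  expect_error(synth_config(lesions_per_patient_range = c(10, 5)),
               "lesions_per_patient_range")
  expect_error(synth_config(lesion_radius_mm_range = c(0.2, 6)),
               "lesion_radius_mm_range")
  expect_error(synth_config(censoring_rate = -0.1), "censoring_rate")
  expect_error(
    synth_config(survival_model = list(baseline_hazard = 0, coef = NULL)),
    "baseline_hazard")
})

test_that("written cohorts round-trip through the CSV/NIfTI layout", {
  co <- generate_cohort(small_cfg())
  dir <- file.path(tempdir(), "synthpet")
  unlink(dir, recursive = TRUE)
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "P001_fdg_pet.nii.gz")))
  expect_true(file.exists(file.path(dir, "P002_cxcr4_mask.nii.gz")))
  tab <- read.csv(file.path(dir, "cohort.csv"))
  expect_equal(nrow(tab), 3)
  expect_true(all(c("patient_id", "age", "sex", "height_cm", "weight_kg",
                    "bmi", "highrisk_cytogenetics", "b2m_mg_l",
                    "disease_duration_months", "response", "os_days",
                    "os_event") %in% names(tab)))
  # BMI consistent with height and weight
  expect_true(all(abs(tab$bmi - tab$weight_kg / (tab$height_cm / 100)^2)
                  < 0.1))
  back <- read_volume(file.path(dir, "P001_fdg_pet.nii.gz"))
  expect_equal(back$values, co$patients[[1]]$volumes$FDG$values,
               tolerance = 1e-6)
  unlink(dir, recursive = TRUE)
})
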