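test_that("analytic phantoms give exact MTV and TLG", {
  # uniform 10x10x10-voxel lesion at 2 mm isotropic spacing, SUV 4
  m <- array(0, c(16, 16, 16)); m[4:13, 4:13, 4:13] <- 1
  pet <- array(1, c(16, 16, 16)); pet[m == 1] <- 4
  ls <- label_components(make_mask(m), tracer = "FDG")
  met <- lesion_metrics(ls, make_vol(pet))
  expect_equal(met$mtv_ml, 8.0)
  expect_equal(met$suv_mean, 4)
  expect_equal(met$suv_max, 4)
  expect_equal(met$tl_burden, 32.0)

  # single voxel, 4 mm isotropic, SUV 7
  m1 <- array(0, c(6, 6, 6)); m1[3, 3, 3] <- 1
  p1 <- array(0, c(6, 6, 6)); p1[3, 3, 3] <- 7
  met1 <- lesion_metrics(label_components(make_mask(m1, spacing = c(4, 4, 4))),
                         make_vol(p1, spacing = c(4, 4, 4)))
  expect_equal(met1$mtv_ml, 0.064)
  expect_equal(met1$tl_burden, 0.448)
})

test_that("SUV statistics equal the voxel-loop oracle on tapered blobs", {
  vol <- make_vol(array(0.5, c(24, 24, 24)))
  res <- plant_lesion(vol, c(24, 24, 24), radius_mm = 12, peak_suv = 6,
                      profile = "gaussian", background = 0.5)
  mask <- array(0, c(24, 24, 24)); mask[res$support] <- 1
  ls <- label_components(make_mask(mask))
  met <- lesion_metrics(ls, res$volume)
  acc_sum <- 0; acc_max <- -Inf; n <- 0
  for (v in which(mask == 1)) {
    acc_sum <- acc_sum + res$volume$values[v]
    acc_max <- max(acc_max, res$volume$values[v])
    n <- n + 1
  }
  expect_equal(met$suv_mean, acc_sum / n, tolerance = 1e-12)
  expect_equal(met$suv_max, acc_max)
  expect_gt(met$suv_max, met$suv_mean)
})

test_that("patient aggregation pools subsets correctly", {
  # two concordant medullary FDG lesions: 8 ml @ SUVmean 4, 2 ml @ SUVmean 9
  vox_ml <- 0.008   # 2 mm isotropic
  mk_met <- function(n_vox, suv_mean, suv_max) {
    data.frame(label = seq_along(n_vox), n_voxels = n_vox,
               volume_ml = n_vox * vox_ml, suv_mean = suv_mean,
               suv_max = suv_max, mtv_ml = n_vox * vox_ml,
               tl_burden = n_vox * vox_ml * suv_mean)
  }
  met_f <- mk_met(c(1000, 250), c(4, 9), c(5, 11))
  met_c <- mk_met(integer(0), numeric(0), numeric(0))
  feats <- aggregate_patient(met_f, met_c,
                             category_a = c("concordant", "concordant"),
                             category_b = character(0),
                             site_a = c("medullary", "medullary"),
                             site_b = character(0))
  expect_equal(feats[["MTV[FDG medullary concordant]"]], 10)
  expect_equal(feats[["SUVmean[FDG medullary concordant]"]], 5.0)  # (8*4+2*9)/10
  expect_equal(feats[["TLG[FDG medullary concordant]"]], 50.0)
  expect_equal(feats[["SUVmax[FDG medullary concordant]"]], 11)
  # empty strata: burden 0, intensity missing
  expect_equal(feats[["MTV[FDG extramedullary discordant]"]], 0)
  expect_true(is.na(feats[["SUVmean[FDG extramedullary discordant]"]]))
  expect_equal(feats[["TLC[CXCR4 medullary concordant]"]], 0)
  expect_true(is.na(feats[["SUVmax[CXCR4 medullary concordant]"]]))

  # single lesion: subset metrics equal lesion metrics
  met_1 <- mk_met(500, 3.5, 6)
  f1 <- aggregate_patient(met_1, met_c, "FDG_only", character(0),
                          "extramedullary", character(0))
  expect_equal(f1[["SUVmean[FDG extramedullary discordant]"]], 3.5)
  expect_equal(f1[["MTV[FDG extramedullary discordant]"]], 500 * vox_ml)

  # mean-of-means alternative
  fm <- aggregate_patient(met_f, met_c, c("concordant", "concordant"),
                          character(0), c("medullary", "medullary"),
                          character(0), pooled = FALSE)
  expect_equal(fm[["SUVmean[FDG medullary concordant]"]], 6.5)
})

test_that("burden metrics are additive over disjoint strata", {
  set.seed(21)
  n <- 12
  met <- data.frame(label = 1:n, n_voxels = sample(50:500, n),
                    suv_mean = runif(n, 2, 8), suv_max = runif(n, 8, 12))
  met$volume_ml <- met$n_voxels * 0.008
  met$mtv_ml <- met$volume_ml
  met$tl_burden <- met$volume_ml * met$suv_mean
  cat_a <- sample(c("concordant", "FDG_only"), n, replace = TRUE)
  site_a <- sample(c("medullary", "extramedullary"), n, replace = TRUE)
  feats <- aggregate_patient(met, met[0, ], cat_a, character(0), site_a,
                             character(0))
  mtv_cols <- grep("^MTV\\[FDG", names(feats), value = TRUE)
  tlg_cols <- grep("^TLG\\[FDG", names(feats), value = TRUE)
  expect_equal(sum(feats[mtv_cols]), sum(met$mtv_ml))
  expect_equal(sum(feats[tlg_cols]), sum(met$tl_burden))
  # SUVmax consistency: stratum max equals max over member lesions
  sel <- cat_a == "concordant" & site_a == "medullary"
  if (any(sel))
    expect_equal(feats[["SUVmax[FDG medullary concordant]"]],
                 max(met$suv_max[sel]))
})

test_that("scaling the PET scales intensity but not volume metrics", {
  set.seed(31)
  m <- array(0, c(12, 12, 12)); m[3:6, 3:6, 3:6] <- 1
  pet <- array(runif(12^3, 0.5, 1), c(12, 12, 12)); pet[m == 1] <- 5
  ls <- label_components(make_mask(m))
  met1 <- lesion_metrics(ls, make_vol(pet))
  met3 <- lesion_metrics(ls, make_vol(pet * 3))
  expect_equal(met3$suv_mean, 3 * met1$suv_mean)
  expect_equal(met3$suv_max, 3 * met1$suv_max)
  expect_equal(met3$tl_burden, 3 * met1$tl_burden)
  expect_equal(met3$mtv_ml, met1$mtv_ml)
})

test_that("sDmax follows the DuBois-standardized definition", {
  expect_equal(body_surface_area(180, 75),
               0.007184 * 180^0.725 * 75^0.425)
  expect_equal(body_surface_area(180, 75, "Mosteller"),
               sqrt(180 * 75 / 3600))

  # force BSA to exactly 2.0 m^2 by solving DuBois for weight at 180 cm
  w <- (2.0 / (0.007184 * 180^0.725))^(1 / 0.425)
  expect_equal(body_surface_area(180, w), 2.0)
  cents <- rbind(c(0, 0, 0), c(300, 0, 0))   # 30 cm apart
  expect_equal(sdmax(cents, 180, w), 15.0)

  # three collinear lesions: Dmax is the extreme pair
  cents3 <- rbind(c(0, 0, 0), c(100, 0, 0), c(250, 0, 0))
  expect_equal(sdmax(cents3, 180, w), 25 / 2)

  expect_true(is.na(sdmax(rbind(c(0, 0, 0)), 180, 75)))
  expect_error(sdmax(cents, -1, 75), "positive")

  # invariance under rigid rotation of the centroid cloud
  set.seed(41)
  cents_r <- matrix(rnorm(15, 0, 80), 5, 3)
  th <- 0.7
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(sdmax(cents_r %*% t(rot), 170, 70),
               sdmax(cents_r, 170, 70), tolerance = 1e-12)
})

test_that("spleen reference excludes lesion voxels", {
  spleen <- array(0, c(10, 10, 10)); spleen[3:8, 3:8, 3:8] <- 1
  pet <- array(1, c(10, 10, 10)); pet[spleen == 1] <- 2
  sm <- make_mask(spleen)
  expect_equal(spleen_reference(make_vol(pet), sm), 2.0)

  lesion <- array(0, c(10, 10, 10)); lesion[3:8, 3:5, 3:8] <- 1
  pet2 <- pet; pet2[lesion == 1] <- 10
  expect_equal(spleen_reference(make_vol(pet2), sm,
                                list(make_mask(lesion))), 2.0)

  # voxel-loop oracle on a random phantom
  set.seed(51)
  petr <- array(runif(10^3, 0, 4), c(10, 10, 10))
  lesr <- array(as.numeric(runif(10^3) < 0.3), c(10, 10, 10))
  got <- spleen_reference(make_vol(petr), sm, list(make_mask(lesr)))
  acc <- 0; n <- 0
  for (v in seq_along(petr))
    if (spleen[v] == 1 && lesr[v] == 0) { acc <- acc + petr[v]; n <- n + 1 }
  expect_equal(got, acc / n, tolerance = 1e-12)

  cover <- make_mask(array(1, c(10, 10, 10)))
  expect_warning(res <- spleen_reference(make_vol(pet), sm, list(cover)),
                 "covered")
  expect_true(is.na(res))
})
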