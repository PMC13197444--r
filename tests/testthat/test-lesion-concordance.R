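test_that("connected components: empty mask and corner connectivity", {
  empty <- make_mask(array(0, c(8, 8, 8)))
  ls <- label_components(empty)
  expect_equal(nrow(ls$lesions), 0)

  # two 3^3 cubes touching at a single corner
  m <- array(0, c(10, 10, 10))
  m[2:4, 2:4, 2:4] <- 1
  m[5:7, 5:7, 5:7] <- 1
  expect_equal(nrow(label_components(make_mask(m))$lesions), 1)
  expect_equal(nrow(label_components(make_mask(m),
                                     connectivity = 6)$lesions), 2)
})

test_that("labelling matches a flood-fill oracle on random masks", {
  for (s in 1:4) {
    set.seed(100 + s)
    m <- array(as.numeric(runif(30^3) < 0.18), c(30, 30, 30))
    ls <- label_components(make_mask(m))
    oracle <- oracle_flood_fill(m, connectivity = 26)
    expect_true(same_partition(ls$labels, oracle))
    expect_equal(nrow(ls$lesions), max(oracle))
    # volumes and centroids are consistent with voxel counts
    expect_equal(ls$lesions$volume_ml,
                 ls$lesions$n_voxels * 8 / 1000)
  }
  set.seed(7)
  m <- array(as.numeric(runif(20^3) < 0.1), c(20, 20, 20))
  ls6 <- label_components(make_mask(m), connectivity = 6)
  expect_true(same_partition(ls6$labels, oracle_flood_fill(m, 6)))
})

test_that("threshold segmentation respects body mask and bounds", {
  set.seed(2)
  pet <- make_vol(array(runif(8^3, 0, 5), c(8, 8, 8)))
  body <- make_mask(array(1, c(8, 8, 8)))
  expect_equal(threshold_segment(pet, 0, body)$values, body$values)
  expect_equal(sum(threshold_segment(pet, 10, body)$values), 0)
  blob <- array(1, c(8, 8, 8)); blob[3:5, 3:5, 3:5] <- 4
  seg <- threshold_segment(make_vol(blob), 2.5, body)
  expect_identical(which(seg$values == 1),
                   which(blob == 4))
})

test_that("overlap matrix equals brute-force voxel counts", {
  a0 <- array(0, c(10, 10, 10)); a0[2:4, 2:4, 2:4] <- 1
  b0 <- array(0, c(10, 10, 10)); b0[7:9, 7:9, 7:9] <- 1
  pairs0 <- overlap_matrix(label_components(make_mask(a0)),
                           label_components(make_mask(b0)))
  expect_equal(nrow(pairs0), 0)

  lsa <- label_components(make_mask(a0))
  expect_equal(overlap_matrix(lsa, lsa)$intersection_voxels, 27L)

  for (s in 1:5) {
    set.seed(300 + s)
    ph <- random_blob_phantom()
    lsa <- label_components(make_mask(ph$a, spacing = ph$spacing))
    lsb <- label_components(make_mask(ph$b, spacing = ph$spacing))
    pairs <- overlap_matrix(lsa, lsb)
    oc <- oracle_overlap_counts(lsa$labels, lsb$labels)
    expect_equal(nrow(pairs), length(oc))
    for (r in seq_len(nrow(pairs)))
      expect_equal(pairs$intersection_voxels[r],
                   oc[[paste(pairs$label_a[r], pairs$label_b[r])]])
  }
})

test_that("concordance is strict at the 10% overlap boundary", {
  # lesion A: 10 voxels in a row; lesion B: overlaps exactly 1 of them
  a <- array(0, c(20, 6, 6)); a[3:12, 3, 3] <- 1
  b <- array(0, c(20, 6, 6)); b[12:16, 2:3, 3] <- 1   # 10 voxels, 1 shared
  lsa <- label_components(make_mask(a), tracer = "FDG")
  lsb <- label_components(make_mask(b), tracer = "CXCR4")
  pairs <- overlap_matrix(lsa, lsb)
  expect_equal(pairs$intersection_voxels, 1L)
  ct <- adjudicate_concordance(pairs, lsa, lsb, threshold = 0.10)
  expect_equal(ct$pairs$overlap_fraction, 0.1)
  # fraction exactly 0.10 -> NOT concordant under strict ">"
  expect_equal(ct$category_a, "FDG_only")
  expect_equal(ct$category_b, "CXCR4_only")
  # inclusive rule flips it
  ct2 <- adjudicate_concordance(pairs, lsa, lsb, threshold = 0.10,
                                strict = FALSE)
  expect_equal(ct2$category_a, "concordant")

  # identical lesions: concordant with fraction 1
  ct3 <- adjudicate_concordance(overlap_matrix(lsa, lsa), lsa, lsa)
  expect_equal(ct3$pairs$overlap_fraction, 1.0)
  expect_equal(ct3$category_a, "concordant")
  expect_equal(ct3$counts$concordant_units, 1)

  expect_error(adjudicate_concordance(pairs, lsa, lsb, threshold = 0),
               "threshold")
  expect_error(adjudicate_concordance(pairs, lsa, lsb, threshold = 1),
               "threshold")
})

test_that("concordance categories match the voxel-loop oracle", {
  for (s in 1:20) {
    set.seed(400 + s)
    ph <- random_blob_phantom()
    lsa <- label_components(make_mask(ph$a, spacing = ph$spacing))
    lsb <- label_components(make_mask(ph$b, spacing = ph$spacing))
    pairs <- overlap_matrix(lsa, lsb)
    ct <- adjudicate_concordance(pairs, lsa, lsb)
    oc <- oracle_categories(lsa$labels, lsb$labels)
    expect_identical(ct$category_a == "concordant",
                     oc$cat_a == "concordant")
    expect_identical(ct$category_b == "concordant",
                     oc$cat_b == "concordant")
    # partition: concordant units + single-tracer lesions = unique total
    n_in_groups <- sum(!is.na(ct$pair_group_a)) + sum(!is.na(ct$pair_group_b))
    expect_equal(ct$counts$concordant_units + ct$counts$a_only +
                   ct$counts$b_only,
                 nrow(lsa$lesions) + nrow(lsb$lesions) -
                   (n_in_groups - ct$counts$concordant_units))
    # symmetry of the min denominator under tracer swap
    ct_sw <- adjudicate_concordance(
      data.frame(label_a = pairs$label_b, label_b = pairs$label_a,
                 intersection_voxels = pairs$intersection_voxels),
      lsb, lsa)
    expect_identical(ct_sw$category_a == "concordant",
                     ct$category_b == "concordant")
    expect_identical(ct_sw$category_b == "concordant",
                     ct$category_a == "concordant")
  }
})

test_that("lowering the concordance threshold never loses concordant lesions", {
  for (s in 1:5) {
    set.seed(500 + s)
    ph <- random_blob_phantom()
    lsa <- label_components(make_mask(ph$a, spacing = ph$spacing))
    lsb <- label_components(make_mask(ph$b, spacing = ph$spacing))
    pairs <- overlap_matrix(lsa, lsb)
    n_conc <- vapply(c(0.05, 0.10, 0.30, 0.60), function(thr) {
      ct <- adjudicate_concordance(pairs, lsa, lsb, threshold = thr)
      sum(ct$category_a == "concordant") + sum(ct$category_b == "concordant")
    }, numeric(1))
    expect_true(all(diff(n_conc) <= 0))
  }
})

test_that("site classification is inclusive at 10% bone overlap", {
  bone <- array(0, c(20, 6, 6)); bone[1:5, , ] <- 1
  bone_mask <- make_mask(bone)
  # 10-voxel lesion with exactly 1 voxel in bone
  m <- array(0, c(20, 6, 6)); m[5:14, 3, 3] <- 1
  ls <- label_components(make_mask(m))
  expect_equal(classify_site(ls, bone_mask), "medullary")
  expect_equal(classify_site(ls, bone_mask, strict = TRUE),
               "extramedullary")
  # fully inside bone / fully outside
  m2 <- array(0, c(20, 6, 6)); m2[2:4, 2:4, 2:4] <- 1
  expect_equal(classify_site(label_components(make_mask(m2)), bone_mask),
               "medullary")
  m3 <- array(0, c(20, 6, 6)); m3[10:12, 2:4, 2:4] <- 1
  expect_equal(classify_site(label_components(make_mask(m3)), bone_mask),
               "extramedullary")
  # oracle agreement on random phantoms
  for (s in 1:10) {
    set.seed(600 + s)
    ph <- random_blob_phantom()
    bone_r <- array(as.numeric(runif(20^3) < 0.3), c(20, 20, 20))
    ls <- label_components(make_mask(ph$a, spacing = ph$spacing))
    got <- classify_site(ls, make_mask(bone_r, spacing = ph$spacing))
    expect_identical(unname(got), oracle_sites(ls$labels, bone_r))
  }
})

test_that("spleen flagging triggers on a single shared voxel", {
  spleen <- array(0, c(10, 10, 10)); spleen[6:9, 6:9, 6:9] <- 1
  spleen_mask <- make_mask(spleen)
  inside <- array(0, c(10, 10, 10)); inside[7:8, 7:8, 7:8] <- 1
  expect_true(flag_spleen(label_components(make_mask(inside)), spleen_mask))
  disjoint <- array(0, c(10, 10, 10)); disjoint[2:3, 2:3, 2:3] <- 1
  expect_false(flag_spleen(label_components(make_mask(disjoint)),
                           spleen_mask))
  onevox <- array(0, c(10, 10, 10)); onevox[4:6, 6, 6] <- 1  # only (6,6,6) in
  expect_true(flag_spleen(label_components(make_mask(onevox)), spleen_mask))
})

test_that("grid mismatches raise errors", {
  a <- label_components(make_mask(array(1, c(4, 4, 4)), spacing = c(2, 2, 2)))
  b <- label_components(make_mask(array(1, c(4, 4, 4)), spacing = c(3, 3, 3)))
  expect_error(overlap_matrix(a, b), "grid")
  expect_error(label_components(make_mask(array(1, c(4, 4, 4))),
                                make_vol(array(1, c(5, 4, 4)))), "grid")
  expect_error(classify_site(a, make_mask(array(1, c(5, 5, 5)))), "grid")
})
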