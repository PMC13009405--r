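grid3 <- c(4L, 4L, 4L)

test_that("coverage filter is inclusive at the threshold", {
  # 10 subjects: voxel 1 lesioned once (1/10 >= 0.10 -> retained),
  # voxel 2 never lesioned
  vols <- c(list(toy_volume(grid3, c(1L, 5L))),
            replicate(9, toy_volume(grid3, 5L), simplify = FALSE))
  coh <- cohort_lesions(sprintf("s%02d", 1:10), vols)
  kept <- voxel_coverage_filter(coh, 0.10)
  expect_true(1L %in% kept)
  expect_true(5L %in% kept)
  expect_false(2L %in% kept)
  # 63 subjects: 6 lesioned is below 10%, 7 is enough
  vols63 <- lapply(1:63, function(i)
    toy_volume(grid3, c(if (i <= 6) 2L else integer(),
                        if (i <= 7) 3L else integer(), 9L)))
  coh63 <- cohort_lesions(sprintf("s%02d", 1:63), vols63)
  kept63 <- voxel_coverage_filter(coh63, 0.10)
  expect_false(2L %in% kept63)
  expect_true(3L %in% kept63)
  expect_error(voxel_coverage_filter(coh63, 0), "min_fraction")
  expect_error(voxel_coverage_filter(coh63, 1.2), "min_fraction")
})

test_that("cohort container verifies grids and sizes", {
  v1 <- toy_volume(grid3, 1:4)           # 4 voxels * 8 mm3 = 0.032 cc
  expect_equal(cohort_lesions("a", list(v1))$lesion_size_cc, 0.032)
  expect_error(cohort_lesions("a", list(v1), lesion_size_cc = 1), "inconsistent")
  v2 <- toy_volume(c(5L, 4L, 4L), 1:4)
  expect_error(cohort_lesions(c("a", "b"), list(v1, v2)), "share one grid")
})

test_that("regress_out produces mean-zero residuals orthogonal to the covariate", {
  set.seed(1)
  b <- rnorm(30); z <- rnorm(30)
  r <- regress_out(b, z)
  expect_lt(abs(mean(r)), 1e-10)
  expect_lt(abs(sum(r * z)), 1e-8)
  # orthogonal covariate leaves the centered behaviour unchanged
  zc <- z - mean(z)
  b_orth <- qr.resid(qr(cbind(1, zc)), b)
  expect_equal(regress_out(b_orth, z), b_orth - mean(b_orth), tolerance = 1e-10)
  expect_lt(max(abs(regress_out(z, z))), 1e-10)
  expect_error(regress_out(rep(1, 10), rnorm(10)), "constant behavior")
})

test_that("tract lesion percentage counts voxel overlaps", {
  atlas <- tract_atlas(list(t8 = 1:8, t4 = 9:12), grid3)
  expect_equal(tract_lesion_percentage(toy_volume(grid3, 20:30), atlas),
               c(t8 = 0, t4 = 0))
  expect_equal(tract_lesion_percentage(toy_volume(grid3, 1:16), atlas),
               c(t8 = 1, t4 = 1))
  expect_equal(tract_lesion_percentage(toy_volume(grid3, c(1L, 5L)), atlas),
               c(t8 = 0.25, t4 = 0))
  expect_error(tract_lesion_percentage(toy_volume(c(5L, 4L, 4L), 1L), atlas),
               "different grids")
  # monotone in added lesion voxels
  small <- tract_lesion_percentage(toy_volume(grid3, c(1L, 9L)), atlas)
  big <- tract_lesion_percentage(toy_volume(grid3, c(1L, 2L, 9L, 10L)), atlas)
  expect_true(all(big >= small))
})

test_that("disconnection maps count disconnected streamline traversals", {
  sl <- streamline_set(list(c(1L, 2L, 3L), c(3L, 7L), c(3L, 11L)), grid3)
  # lesion away from every streamline
  d0 <- disconnection_map(toy_volume(grid3, 60L), sl)
  expect_true(all(d0$fraction == 0) && all(d0$binary == 0))
  # lesion on voxel 1 disconnects only the first streamline:
  # voxel 3 is traversed by 3 streamlines, 1 disconnected -> 1/3, binary 0
  d1 <- disconnection_map(toy_volume(grid3, 1L), sl)
  expect_equal(d1$fraction[3], 1 / 3)
  expect_equal(d1$binary[3], 0L)
  expect_equal(d1$fraction[2], 1)
  expect_equal(d1$binary[2], 1L)
  # lesion intersecting every streamline
  d2 <- disconnection_map(toy_volume(grid3, 3L), sl)
  traversed <- unique(unlist(sl$streamlines))
  expect_true(all(d2$fraction[traversed] == 1))
  expect_true(all(d2$fraction >= 0 & d2$fraction <= 1))
  expect_true(all(which(d2$binary == 1) %in% traversed))
  expect_error(disconnection_map(toy_volume(grid3, 1L), sl, 0), "threshold")
})

test_that("sparse CCA LSM is deterministic and honours the sparsity cap", {
  set.seed(6)
  X <- matrix(rbinom(40 * 60, 1, 0.3), nrow = 40)
  colnames(X) <- as.character(seq_len(60))
  y <- rnorm(40)
  r1 <- sparse_cca_lsm(X, y, sparseness = -0.3, folds = 4, seed = 2,
                       stability_b = 5)
  r2 <- sparse_cca_lsm(X, y, sparseness = -0.3, folds = 4, seed = 2,
                       stability_b = 5)
  expect_identical(r1$weights, r2$weights)
  expect_identical(r1$displayed_voxels, r2$displayed_voxels)
  expect_identical(r1$cv_correlation, r2$cv_correlation)
  expect_lte(r1$retained / ncol(X), 0.3 + 1e-9)
  expect_true(all(names(r1$displayed_voxels) %in% names(r1$weights)))
  # sparseness magnitude 1: the hard cap is slack (projection is a no-op)
  w0 <- rnorm(10)
  expect_identical(discoursemap:::project_sparse(w0, 10L, TRUE), w0)
  rfull <- sparse_cca_lsm(X, y, sparseness = -1, folds = 4, seed = 2,
                          stability_b = 0)
  expect_gte(rfull$retained, 1L)
  expect_error(sparse_cca_lsm(X, rep(1, 40)), "constant behavior")
  expect_error(sparse_cca_lsm(X[, 0], y), "empty voxel set")
  expect_error(sparse_cca_lsm(X, y, sparseness = 0), "sparseness")
})

test_that("non-negative sparseness constrains weight signs", {
  set.seed(7)
  X <- matrix(rbinom(30 * 40, 1, 0.4), nrow = 30)
  y <- rowSums(X[, 1:5]) + rnorm(30, 0, 0.5)
  r <- sparse_cca_lsm(X, y, sparseness = 0.3, folds = 3, seed = 1,
                      stability_b = 0)
  expect_true(all(r$weights >= 0))
  expect_length(r$displayed_voxels, 0)   # no negative weights to display
})

test_that("label_weights reports region shares above the 10% floor", {
  atlas <- tract_atlas(list(big = 1:10, small = 11:20, other = 21:30), grid3)
  mk_result <- function(w) {
    structure(list(weights = w, displayed_voxels = names(w),
                   cv_correlation = 0.5, p = 0.01, sparseness = -0.3,
                   folds = 4, seed = 1, retained = length(w),
                   display_cut = 0.1), class = "lsm_result")
  }
  one <- label_weights(mk_result(c(`1` = -0.4, `2` = -0.6)), atlas)
  expect_equal(one$region, "big")
  expect_equal(one$share, 1)
  two <- label_weights(mk_result(c(`1` = -0.6, `11` = 0.4)), atlas)
  expect_equal(sort(two$region), c("big", "small"))
  expect_equal(two$share[two$region == "big"], 0.6)
  skew <- label_weights(mk_result(c(`1` = -0.95, `11` = 0.05)), atlas)
  expect_equal(skew$region, "big")
  empty <- label_weights(mk_result(stats::setNames(numeric(), character())), atlas)
  expect_equal(nrow(empty), 0L)
})

test_that("pvc verdict boundary sits exactly at an AIC difference of 100", {
  expect_equal(pvc_verdict(100), "single_map")
  expect_equal(pvc_verdict(100 + 1e-9), "two_maps")
  expect_equal(pvc_verdict(14), "single_map")
  expect_equal(pvc_verdict(-50), "single_map")
})

test_that("NIfTI and JSON round-trips preserve lesion data and voxel sets", {
  vol <- toy_volume(c(6L, 5L, 4L), c(1L, 7L, 30L), voxel_size = 3)
  f <- tempfile(fileext = ".nii.gz")
  write_lesion_nifti(vol, f)
  back <- read_lesion_nifti(f)
  expect_equal(back$data, vol$data)
  expect_equal(back$voxel_size_mm, c(3, 3, 3))

  atlas <- tract_atlas(list(a = c(1L, 2L), b = 5:9), grid3)
  fa <- tempfile(fileext = ".json")
  write_tract_atlas_json(atlas, fa)
  expect_equal(read_tract_atlas_json(fa)$tracts, atlas$tracts)

  sl <- streamline_set(list(c(1L, 2L), c(9L, 10L, 11L)), grid3)
  fs <- tempfile(fileext = ".json")
  write_streamlines_json(sl, fs)
  expect_equal(read_streamlines_json(fs)$streamlines, sl$streamlines)
  expect_error(streamline_set(list(c(1L, 999L)), grid3), "outside grid")
  expect_error(tract_atlas(list(a = integer()), grid3), "non-empty")
})
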