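small_config <- function(...) {
  cohort_config(grid_shape = c(24, 24, 24), k_true = 2,
                geometry = c("focal", "bilateral"),
                smoothness_fwhm_mm = 10, ...)
}

test_that("planted sources have the declared geometry and normalization", {
  anat <- make_synthetic_anatomy(c(32, 32, 32))
  S <- make_sources(anat$mask, k = 4,
                    geometry = c("mixed_sign", "bilateral", "focal",
                                 "medial"),
                    smoothness_fwhm_mm = 12, seed = 2,
                    allowed = anat$cerebrum, exclude = anat$reference)
  # unit population SD, zero mean over the mask
  expect_lt(max(abs(rowMeans(S))), 1e-10)
  expect_equal(sqrt(rowMeans(S^2)), rep(1, 4), tolerance = 1e-10)
  # pairwise decorrelation enforced
  R <- cor(t(S))
  expect_lte(max(abs(R[upper.tri(R)])), 0.2)
  # reference-region voxels identically zero
  in_ref <- anat$mask$flat_index %in% anat$reference$mask$flat_index
  expect_equal(max(abs(S[, in_ref])), 0)

  # focal: exactly one positive suprathreshold cluster
  zfoc <- zscale_source(S[3, ], anat$mask)
  tab <- extract_clusters(zfoc, anat$mask, 3, min_size = 1)
  expect_equal(sum(tab$sign == "positive"), 1)

  # mixed-sign: both a positive and a negative excursion
  zmix <- zscale_source(S[1, ], anat$mask)
  tmix <- extract_clusters(zmix, anat$mask, 3, min_size = 1)
  expect_true(all(c("positive", "negative") %in% tmix$sign))

  # bilateral: symmetric across the first-axis midline
  a <- array(0, dim = dim(anat$mask$included))
  a[anat$mask$flat_index] <- S[2, ]
  expect_lt(max(abs(a - a[dim(a)[1]:1, , ])), 1e-10)
})

test_that("cohort generation is seed-reproducible with DVR-scale structure", {
  cfg <- small_config()
  c1 <- make_cohort(cfg, c(5, 4, 6), seed = 7)
  c2 <- make_cohort(cfg, c(5, 4, 6), seed = 7)
  expect_identical(c1$volumes[[3]]$values, c2$volumes[[3]]$values)
  expect_identical(c1$metadata, c2$metadata)
  c3 <- make_cohort(cfg, c(5, 4, 6), seed = 8)
  expect_false(identical(c1$volumes[[3]]$values, c3$volumes[[3]]$values))

  # reference-region mean DVR stays at 1 up to noise
  anat <- c1$truth$anatomy
  ref_idx <- anat$reference$mask$flat_index
  tol <- 3 * cfg$noise_sd / sqrt(length(ref_idx))
  devs <- vapply(c1$volumes, function(v) abs(mean(v$values[ref_idx]) - 1),
                 0)
  expect_lt(median(devs), tol)
  expect_lt(max(devs), 2 * tol)

  # group sizes and score ranges
  expect_equal(as.vector(table(c1$metadata$group)), c(5, 4, 6))
  expect_true(all(c1$metadata$mmse >= 0 & c1$metadata$mmse <= 30))
  expect_true(all(c1$metadata$mmse == round(c1$metadata$mmse)))
  expect_true(all(c1$metadata$cdr_sb >= 0))
  expect_true(all(c1$metadata$cdr_sb * 2 == round(c1$metadata$cdr_sb * 2)))
})

test_that("noiseless cohorts are recovered nearly exactly by the pipeline", {
  cfg <- small_config(noise_sd = 0)
  coh <- make_cohort(cfg, c(5, 4, 6), seed = 3)
  run <- run_sbm_pipeline(coh, seed = 3, n_components = 2, fwhm_mm = 0,
                          mask = coh$truth$anatomy$mask,
                          min_cluster_voxels = 10)
  expect_lt(run$decomposition$reconstruction_rmse, 1e-10)
  mt <- match_sources(run$decomposition, coh$truth$sources_true,
                      coh$truth$loadings_true)
  expect_true(all(abs(mt$spatial_r) >= 0.99))
  expect_true(all(abs(mt$loading_r) >= 0.99))
})

test_that("recovery degrades monotonically with the noise level", {
  mean_recovery <- function(noise) {
    rs <- vapply(1:6, function(s) {
      coh <- make_cohort(small_config(noise_sd = noise), c(5, 4, 6),
                         seed = 40 + s)
      run <- run_sbm_pipeline(coh, seed = s, n_components = 3,
                              fwhm_mm = 6, mask = coh$truth$anatomy$mask,
                              min_cluster_voxels = 1e9)
      mean(abs(match_sources(run$decomposition,
                             coh$truth$sources_true)$spatial_r))
    }, 0)
    mean(rs)
  }
  r <- vapply(c(0.02, 0.12, 0.5), mean_recovery, 0)
  expect_true(all(diff(r) < 0))
})

test_that("score links are recovered in direction across seeds", {
  cfg <- small_config(score_links = list(
    mmse = list(source = 1, slope = 1, noise_sd = 0.5)))
  signs <- vapply(1:20, function(s) {
    coh <- make_cohort(cfg, c(5, 4, 6), seed = 100 + s)
    sign(cor(coh$metadata$mmse, coh$truth$loadings_true[, 1],
             method = "spearman"))
  }, 0)
  expect_gte(mean(signs == 1), 0.95)

  # zero group shift: Kruskal-Wallis on true loadings is calibrated
  cfg0 <- small_config(group_shifts = matrix(0, 2, 3))
  pvals <- unlist(lapply(1:60, function(s) {
    coh <- make_cohort(cfg0, c(7, 6, 7), seed = 300 + s)
    apply(coh$truth$loadings_true, 2, function(l) {
      kruskal_wallis(l, coh$metadata$group)$p_value
    })
  }))
  rate <- mean(pvals < 0.05)
  expect_gte(rate, 0.01)
  expect_lte(rate, 0.10)
})

test_that("cohorts round-trip through disk manifests", {
  tmp <- withr::local_tempdir()
  coh <- make_cohort(small_config(), c(3, 3, 3), seed = 5)
  write_cohort(coh, tmp)
  expect_true(file.exists(file.path(tmp, "manifest.tsv")))
  expect_true(file.exists(file.path(tmp, "truth.json")))
  back <- read_cohort_manifest(file.path(tmp, "manifest.tsv"))
  expect_equal(length(back$volumes), 9)
  expect_lt(max(abs(back$volumes[[4]]$values - coh$volumes[[4]]$values)),
            1e-6)
  expect_equal(back$metadata$subject_id, coh$metadata$subject_id)
  expect_equal(back$metadata$mmse, coh$metadata$mmse)
})
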