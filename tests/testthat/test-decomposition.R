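matrix_cohort <- function(X, ids = sprintf("s%02d", seq_len(nrow(X)))) {
  # wrap a bare matrix as a demeaned sbm_matrix (rows already centred)
  structure(
    list(data = X - rowMeans(X), row_means = rowMeans(X),
         subject_ids = ids, mask = NULL, demeaned = TRUE),
    class = "sbm_matrix"
  )
}

sparse_sources <- function(k, V, seed) {
  withr::with_seed(seed, {
    S <- matrix(rnorm(k * V, sd = 0.2), k, V)
    for (i in seq_len(k)) {
      hot <- sample.int(V, round(0.08 * V))
      S[i, hot] <- S[i, hot] + rnorm(length(hot), mean = 3)
    }
    t(scale(t(S)))
  })
}

test_that("PCA retains the top right-singular subspace with exact bookkeeping", {
  # exact rank-2 data: two planted sources, no noise
  withr::with_seed(1, {
    S <- matrix(rnorm(2 * 200), 2, 200)
    A <- matrix(rnorm(12 * 2), 12, 2)
  })
  X <- A %*% S
  p2 <- pca_reduce(matrix_cohort(X), 2)
  expect_equal(sum(p2$explained_variance_fraction), 1, tolerance = 1e-10)

  # random 20 x 300, K = 5: residual equals discarded singular energy
  withr::with_seed(2, X2 <- matrix(rnorm(20 * 300), 20, 300))
  m <- matrix_cohort(X2)
  p5 <- pca_reduce(m, 5)
  approx <- p5$projection %*% p5$component_images
  resid <- sum((m$data - approx)^2)
  d_or <- svd(m$data)$d        # independent full decomposition
  expect_equal(resid, sum(d_or[-(1:5)]^2), tolerance = 1e-8)
  expect_equal(p5$explained_variance_fraction,
               d_or[1:5]^2 / sum(d_or^2), tolerance = 1e-10)

  # orthogonality of the component images
  G <- tcrossprod(p5$component_images)
  expect_lt(max(abs(G - diag(5))), 1e-8)

  # row-demeaned rank bound: K = N must fail
  expect_error(pca_reduce(m, 20), "N - 1")
  expect_error(pca_reduce(m, 0), "N - 1")
})

test_that("whitened component images have identity covariance over voxels", {
  withr::with_seed(3, X <- matrix(rnorm(15 * 400), 15, 400))
  p <- pca_reduce(matrix_cohort(X), 6)
  Y <- sqrt(ncol(p$component_images)) * p$component_images
  expect_lt(max(abs(tcrossprod(Y) / ncol(Y) - diag(6))), 1e-8)
})

test_that("Infomax recovers planted super-Gaussian sources (logistic rule)", {
  V <- 3000
  S <- sparse_sources(3, V, seed = 10)
  withr::with_seed(11, A <- matrix(rnorm(12 * 3), 12, 3))
  d <- infomax_ica(pca_reduce(matrix_cohort(A %*% S), 3), seed = 21)
  mt <- match_sources(d, S, A)
  expect_true(all(abs(mt$spatial_r) >= 0.99))
  expect_true(all(abs(mt$loading_r) >= 0.99))
  expect_true(d$converged)
})

test_that("extended Infomax separates sub-Gaussian (uniform) sources", {
  V <- 3000
  withr::with_seed(12, {
    S <- matrix(runif(2 * V, -sqrt(3), sqrt(3)), 2, V)
    A <- matrix(rnorm(10 * 2), 10, 2)
  })
  d <- infomax_ica(pca_reduce(matrix_cohort(A %*% S), 2), seed = 22,
                   extended = TRUE)
  mt <- match_sources(d, S)
  expect_true(all(abs(mt$spatial_r) >= 0.99))
})

test_that("K = 1 returns the PCA component; same seed is bit-identical", {
  withr::with_seed(5, X <- matrix(rnorm(8 * 120), 8, 120))
  p <- pca_reduce(matrix_cohort(X), 1)
  d1 <- infomax_ica(p, seed = 1)
  expect_equal(abs(cor(as.vector(d1$sources),
                       as.vector(p$component_images))), 1)

  p3 <- pca_reduce(matrix_cohort(X), 3)
  da <- infomax_ica(p3, seed = 33)
  db <- infomax_ica(p3, seed = 33)
  expect_identical(da$mixing, db$mixing)
  expect_identical(da$sources, db$sources)
})

test_that("mixing %*% sources reproduces the demeaned data to the PCA residual", {
  withr::with_seed(6, X <- matrix(rnorm(14 * 500), 14, 500))
  m <- matrix_cohort(X)
  p <- pca_reduce(m, 5)
  d <- infomax_ica(p, seed = 2)
  resid_rmse <- sqrt(mean((m$data - d$mixing %*% d$sources)^2))
  expect_equal(resid_rmse, d$reconstruction_rmse, tolerance = 1e-8)

  # with K = true rank and no noise the reconstruction is exact
  S <- sparse_sources(3, 400, seed = 13)
  withr::with_seed(14, A <- matrix(rnorm(10 * 3), 10, 3))
  mx <- matrix_cohort(A %*% S)
  dx <- infomax_ica(pca_reduce(mx, 3), seed = 3)
  expect_lt(max(abs(mx$data - dx$mixing %*% dx$sources)), 1e-8)
  expect_lt(dx$reconstruction_rmse, 1e-6)
})

test_that("orientation flips sign pairs without changing the product", {
  withr::with_seed(7, X <- matrix(rnorm(10 * 300), 10, 300))
  d <- infomax_ica(pca_reduce(matrix_cohort(X), 4), seed = 4)
  before <- d$mixing %*% d$sources
  # force a negative-extreme source, then re-orient
  d$sources[2, ] <- -d$sources[2, ]
  d$mixing[, 2] <- -d$mixing[, 2]
  o <- orient_sources(d)
  for (k in 1:4) {
    expect_gt(o$sources[k, which.max(abs(o$sources[k, ]))], 0)
  }
  expect_lt(max(abs(o$mixing %*% o$sources - before)), 1e-12)
  # already-oriented decomposition is a fixed point
  expect_identical(orient_sources(o), o)
})

test_that("source matching reports permutation, sign, and cardinality", {
  S <- sparse_sources(3, 500, seed = 15)
  est <- fake_decomposition(matrix(rnorm(9 * 5), 9, 5))
  est$sources <- rbind(-S[2, ], S[3, ], S[1, ],
                       matrix(rnorm(2 * 500), 2, 500))
  mt <- match_sources(est, S)
  expect_equal(nrow(mt), 3)
  expect_equal(mt$estimate[mt$truth == 2], 1)
  expect_equal(mt$sign[mt$truth == 2], -1)
  expect_equal(abs(mt$spatial_r), rep(1, 3), tolerance = 1e-12)

  # unrelated noise stays near the sampling null ~ 1/sqrt(V)
  withr::with_seed(16, noise <- matrix(rnorm(3 * 2000), 3, 2000))
  est2 <- fake_decomposition(matrix(rnorm(9 * 3), 9, 3))
  withr::with_seed(17, est2$sources <- matrix(rnorm(3 * 2000), 3, 2000))
  mt2 <- match_sources(est2, noise)
  expect_true(all(abs(mt2$spatial_r) < 3 / sqrt(2000) * 1.8))

  expect_error(match_sources(est2, noise[, 1:100]), "mismatch")
  expect_error(match_sources(est2, matrix(rnorm(4 * 2000), 4, 2000)),
               "more true sources")
})

test_that("tidy/glance expose loadings and run diagnostics", {
  d <- fake_decomposition(matrix(rnorm(6 * 2), 6, 2))
  td <- tidy(d)
  expect_equal(nrow(td), 12)
  expect_equal(td$loading[td$component == 2], d$mixing[, 2])
  g <- glance(d)
  expect_equal(g$n_subjects, 6)
  expect_equal(g$n_components, 2)
  expect_true(g$converged)
})
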