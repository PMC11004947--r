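test_that("Kruskal-Wallis H matches the hand-ranked formula and is rank-invariant", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- kruskal_wallis(x, g)
  expect_equal(res$statistic, 7.2, tolerance = 1e-10)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, pchisq(7.2, 2, lower.tail = FALSE),
               tolerance = 1e-12)

  perm <- withr::with_seed(1, sample(9))
  res_p <- kruskal_wallis(x[perm], g[perm])
  expect_equal(res_p$statistic, res$statistic)
  # monotone transform of the values leaves H unchanged
  expect_equal(kruskal_wallis(exp(x), g)$statistic, res$statistic)

  # all-identical observations: degenerate, p = 1
  res_d <- kruskal_wallis(rep(5, 9), g)
  expect_true(res_d$degenerate)
  expect_equal(res_d$p_value, 1)
  expect_error(kruskal_wallis(x, rep("a", 9)), ">= 2 groups")
})

test_that("Dunn's z follows the pooled-rank formula with tie correction", {
  x <- c(1:10, 101:110, 201:210)
  g <- rep(c("a", "b", "c"), each = 10)
  ph <- pairwise_posthoc(x, g)
  expect_equal(nrow(ph), 3)
  # explicit evaluation: no ties, rank means 5.5 / 15.5 / 25.5
  se <- sqrt((30 * 31 / 12) * (2 / 10))
  expect_equal(ph$z[ph$group1 == "a" & ph$group2 == "b"], -10 / se,
               tolerance = 1e-12)
  expect_true(all(ph$p_value < 0.05))

  # identical groups: p ~ 1
  ph0 <- pairwise_posthoc(rep(c(1, 2, 3), times = 3),
                          rep(c("a", "b", "c"), each = 3))
  expect_true(all(ph0$p_value > 0.95))

  # label swap flips z, keeps p
  xs <- c(1, 2, 3, 10, 11, 12)
  gs <- rep(c("a", "b"), each = 3)
  z1 <- pairwise_posthoc(xs, gs)
  z2 <- pairwise_posthoc(xs, factor(gs, levels = c("b", "a")))
  expect_equal(z1$z, -z2$z)
  expect_equal(z1$p_value, z2$p_value)
})

test_that("BH step-up rejections and adjusted values match the rule", {
  p <- c(0.001, 0.01, 0.02, 0.03, 0.9)
  res <- bh_fdr(p, 0.05)
  expect_equal(res$rejected, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(res$adjusted, p.adjust(p, "BH"), tolerance = 1e-12)

  res1 <- bh_fdr(rep(1, 6), 0.05)
  expect_equal(sum(res1$rejected), 0)
  expect_equal(res1$adjusted, rep(1, 6))

  # brute-force over all cutoffs on random vectors; adjusted <= q coincides
  for (i in 1:25) {
    pv <- withr::with_seed(200 + i, runif(12)^2)
    r <- bh_fdr(pv, 0.05)
    m <- length(pv); o <- order(pv); ps <- pv[o]
    ok <- which(ps <= seq_len(m) / m * 0.05)
    brute <- rep(FALSE, m)
    if (length(ok)) brute[o[1:max(ok)]] <- TRUE
    expect_identical(r$rejected, brute)
    expect_identical(r$rejected, r$adjusted <= 0.05)
  }

  # monotonicity: appending a large p never removes a rejection
  pv <- c(0.004, 0.011, 0.02, 0.6)
  r1 <- bh_fdr(pv, 0.05)$rejected
  r2 <- bh_fdr(c(pv, 0.95), 0.05)$rejected[1:4]
  expect_true(all(r2[r1]))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("Spearman rho uses mid-ranks with the t approximation", {
  s <- spearman(1:5, c(3, 1, 2, 5, 4))
  expect_equal(s$rho, 0.6, tolerance = 1e-12)    # 1 - 6*8/(5*24)
  tt <- 0.6 * sqrt(3 / (1 - 0.36))
  expect_equal(s$p_value, 2 * pt(-tt, 3), tolerance = 1e-12)

  # agreement with the standard implementation on tied data
  withr::with_seed(3, { x <- round(rnorm(30), 1); y <- round(x + rnorm(30), 0) })
  s2 <- spearman(x, y)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  expect_equal(s2$rho, unname(ct$estimate), tolerance = 1e-10)

  # monotone invariance and reversal
  expect_equal(spearman(1:8, exp(1:8))$rho, 1)
  expect_equal(spearman(1:8, -(1:8)^3)$rho, -1)
  # pairwise deletion reports the effective n
  expect_equal(spearman(c(1:6, NA), c(2:7, 5))$n, 6)
  expect_error(spearman(1:3, 1:3), ">= 4")
  expect_error(spearman(rep(1, 5), 1:5), "zero variance")
})

test_that("group analysis: one row per component, planted shift is family minimum", {
  withr::with_seed(21, {
    L <- matrix(rnorm(57 * 5), 57, 5)
    grp <- rep(c("CN", "MCI", "AD"), c(19, 14, 24))
    L[, 3] <- L[, 3] + c(CN = 1.2, MCI = 0.6, AD = 0)[grp]
  })
  d <- fake_decomposition(L)
  meta <- tibble::tibble(subject_id = d$subject_ids, group = grp)
  res <- run_group_analysis(d, meta)
  expect_equal(nrow(res), 5)
  expect_equal(res$component, 1:5)
  expect_equal(which.min(res$p_value), 3)
  expect_true(all(res$p_adjusted >= res$p_value))
  expect_equal(nrow(res$posthoc[[3]]), 3)

  # permuted labels: BH rejections at or below the nominal rate on average
  rej <- withr::with_seed(31, replicate(60, {
    meta_p <- meta
    meta_p$group <- sample(meta_p$group)
    mean(run_group_analysis(d, meta_p)$significant)
  }))
  expect_lte(mean(rej), 0.05 + 0.03)
})

test_that("cognition analysis filters cohorts, reports n, and finds planted links", {
  withr::with_seed(22, {
    L <- matrix(rnorm(57 * 4), 57, 4)
    grp <- rep(c("CN", "MCI", "AD"), c(19, 14, 24))
    mmse <- round(pmin(30, 24 + 2.5 * (L[, 2] + rnorm(57, sd = 0.4))))
    lmii <- round(rnorm(57, 8, 4), 1)
    lmii[c(3, 40)] <- NA
  })
  d <- fake_decomposition(L)
  meta <- tibble::tibble(subject_id = d$subject_ids, group = grp,
                         mmse = mmse, lmii = lmii)
  sym <- run_cognition_analysis(d, meta, "symptomatic_only")
  expect_equal(nrow(sym), 8)                       # 4 components x 2 scores
  cell <- sym[sym$component == 2 & sym$score == "mmse", ]
  expect_gte(abs(cell$rho), 0.7)
  expect_true(cell$significant)
  expect_true(all(sym$n[sym$score == "mmse"] == 38))

  full <- run_cognition_analysis(d, meta, "full")
  n_cn_lmii <- sum(grp == "CN" & !is.na(lmii))
  expect_equal(full$n[full$score == "lmii"][1],
               sym$n[sym$score == "lmii"][1] + n_cn_lmii)
  expect_error(run_cognition_analysis(d, meta, scores = "ravlt_delay"),
               "not in metadata")
})
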