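#' Kruskal-Wallis omnibus test
#'
#' Tie-corrected Kruskal-Wallis H on mid-ranks with a chi-square upper-tail
#' p-value on `levels - 1` degrees of freedom (via [stats::kruskal.test()]).
#' When every observation is identical the statistic is degenerate; `H = 0`,
#' `p = 1` are returned with `degenerate = TRUE`.
#'
#' @param values Numeric vector.
#' @param groups Factor (or coercible) of group labels, >= 2 levels present.
#' @return A one-row tibble: `statistic` (H), `df`, `p_value`, `n`,
#'   `degenerate`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (length(values) != length(groups)) stop("length mismatch", call. = FALSE)
  if (any(table(groups) < 1L)) stop("a group has no observations",
                                    call. = FALSE)
  if (length(values) < 3L) stop("need total n >= 3", call. = FALSE)
  if (length(unique(values)) == 1L) {
    return(tibble::tibble(statistic = 0, df = nlevels(groups) - 1L,
                          p_value = 1, n = length(values),
                          degenerate = TRUE))
  }
  kt <- kruskal.test(values, groups)
  tibble::tibble(statistic = unname(kt$statistic),
                 df = unname(kt$parameter),
                 p_value = kt$p.value, n = length(values),
                 degenerate = FALSE)
}

#' Dunn's post hoc pairwise comparisons
#'
#' Pairwise z statistics from pooled mid-ranks with the tie correction
#' `z = (Rbar_a - Rbar_b) / sqrt((n(n+1)/12 - T) (1/n_a + 1/n_b))`, where
#' `T = sum(t^3 - t) / (12 (n - 1))` over tie groups; two-sided normal
#' p-values, unadjusted.
#'
#' @inheritParams kruskal_wallis
#' @param method Pairwise method; only `"dunn"` is implemented.
#' @return A tibble with one row per unordered pair: `group1`, `group2`,
#'   `z`, `p_value`.
#' @export
pairwise_posthoc <- function(values, groups, method = "dunn") {
  method <- match.arg(method, "dunn")
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  n <- length(values)
  r <- rank(values)
  tie_tab <- table(values)
  Tcorr <- sum(tie_tab^3 - tie_tab) / (12 * (n - 1))
  lv <- levels(groups)
  rbar <- tapply(r, groups, mean)
  ng <- tapply(r, groups, length)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(p) {
    se2 <- (n * (n + 1) / 12 - Tcorr) * (1 / ng[[p[1]]] + 1 / ng[[p[2]]])
    z <- if (se2 > 0) (rbar[[p[1]]] - rbar[[p[2]]]) / sqrt(se2) else 0
    tibble::tibble(group1 = p[1], group2 = p[2], z = z,
                   p_value = 2 * pnorm(-abs(z)))
  })
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up procedure: with the p-values sorted ascending, find the largest
#' rank `i` with `p_(i) <= (i/m) q` and reject ranks `1..i`.  Adjusted
#' values are `adjusted_(i) = min_{j >= i} m p_(j) / j`, clipped at 1,
#' returned in the input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param q Target FDR level in (0, 1).
#' @return A list with `adjusted` (numeric, input order) and `rejected`
#'   (logical, input order).
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  p <- as.numeric(p_values)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(q) || q <= 0 || q >= 1) stop("`q` must be in (0, 1)",
                                               call. = FALSE)
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj_sorted <- rev(cummin(rev(m * ps / seq_len(m))))
  adj_sorted <- pmin(adj_sorted, 1)
  adjusted <- numeric(m)
  adjusted[o] <- adj_sorted
  crossings <- which(ps <= seq_len(m) / m * q)
  rejected <- rep(FALSE, m)
  if (length(crossings) > 0) rejected[o[seq_len(max(crossings))]] <- TRUE
  list(adjusted = adjusted, rejected = rejected)
}

#' Spearman rank correlation
#'
#' `rho` is the Pearson correlation of mid-ranks; the two-sided p-value uses
#' the t approximation `t = rho sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom.  Incomplete pairs are dropped (pairwise deletion) and
#' the effective `n` is reported.
#'
#' @param x,y Numeric vectors of equal length; `NA`s dropped pairwise.
#' @return A one-row tibble: `rho`, `p_value`, `n`.
#' @export
spearman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need >= 4 complete pairs, got ", n, call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (var(rx) == 0 || var(ry) == 0) {
    stop("zero variance in a rank vector", call. = FALSE)
  }
  rho <- cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tt), df = n - 2)
  }
  tibble::tibble(rho = rho, p_value = p, n = n)
}

# align a metadata table to the decomposition's subject order
align_metadata <- function(d, metadata) {
  stopifnot(is.data.frame(metadata), "subject_id" %in% names(metadata),
            "group" %in% names(metadata))
  missing_ids <- setdiff(d$subject_ids, metadata$subject_id)
  if (length(missing_ids) > 0) {
    stop("metadata missing subjects: ",
         paste(head(missing_ids, 5), collapse = ", "), call. = FALSE)
  }
  metadata[match(d$subject_ids, metadata$subject_id), , drop = FALSE]
}

#' Group comparison of loading weights
#'
#' One omnibus Kruskal-Wallis test per component across the diagnostic
#' groups, Benjamini-Hochberg adjusted over the family of all K components;
#' Dunn's pairwise post hoc comparisons are reported unadjusted alongside.
#'
#' @param d An `sbm_decomposition`.
#' @param metadata Tibble with `subject_id` and `group` (e.g. CN/MCI/AD)
#'   covering every subject in `d`.
#' @param q FDR level (default 0.05).
#' @return A tibble with one row per component: `component`, `statistic`
#'   (H), `df`, `p_value`, `p_adjusted`, `significant`, `n`, and a
#'   list-column `posthoc` of pairwise tibbles.
#' @export
run_group_analysis <- function(d, metadata, q = 0.05) {
  stopifnot(inherits(d, "sbm_decomposition"))
  meta <- align_metadata(d, metadata)
  grp <- droplevels(factor(meta$group))
  if (nlevels(grp) < 2L) stop("need >= 2 diagnostic groups", call. = FALSE)
  K <- ncol(d$mixing)
  omnibus <- purrr::map_dfr(seq_len(K), function(k) {
    res <- kruskal_wallis(d$mixing[, k], grp)
    dplyr::mutate(res, component = k, .before = 1)
  })
  fdr <- bh_fdr(omnibus$p_value, q = q)
  omnibus$p_adjusted <- fdr$adjusted
  omnibus$significant <- fdr$rejected
  omnibus$posthoc <- purrr::map(seq_len(K), function(k) {
    pairwise_posthoc(d$mixing[, k], grp)
  })
  omnibus
}

#' Correlations between loading weights and cognitive scores
#'
#' Spearman correlation for every (component, score) pair, in either the
#' symptomatic-only cohort (CN excluded before ranking) or the full cohort;
#' Benjamini-Hochberg adjustment is applied within the family of all tested
#' pairs of that cohort run.  Missing scores are dropped pairwise and the
#' per-cell `n` is reported.
#'
#' @param d An `sbm_decomposition`.
#' @param metadata Tibble with `subject_id`, `group` and score columns.
#' @param cohort `"symptomatic_only"` (drop CN) or `"full"`.
#' @param scores Character vector of score column names (default the four
#'   standard measures present in `metadata`).
#' @param q FDR level.
#' @param cn_label Group label treated as cognitively normal (default
#'   `"CN"`).
#' @return A tibble: `component`, `score`, `rho`, `p_value`, `p_adjusted`,
#'   `significant`, `n`, `cohort`.
#' @export
run_cognition_analysis <- function(d, metadata,
                                   cohort = c("symptomatic_only", "full"),
                                   scores = NULL, q = 0.05,
                                   cn_label = "CN") {
  cohort <- match.arg(cohort)
  stopifnot(inherits(d, "sbm_decomposition"))
  meta <- align_metadata(d, metadata)
  default_scores <- intersect(c("cdr_sb", "mmse", "lmii", "ravlt_delay"),
                              names(meta))
  scores <- scores %||% default_scores
  missing_cols <- setdiff(scores, names(meta))
  if (length(missing_cols) > 0) {
    stop("score column(s) not in metadata: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  keep <- if (cohort == "symptomatic_only") meta$group != cn_label
          else rep(TRUE, nrow(meta))
  if (sum(keep) < 4L) stop("cohort empty (or < 4 subjects) after filtering",
                           call. = FALSE)
  K <- ncol(d$mixing)
  cells <- tidyr::expand_grid(component = seq_len(K), score = scores)
  res <- purrr::pmap_dfr(cells, function(component, score) {
    sc <- spearman(d$mixing[keep, component], meta[[score]][keep])
    tibble::tibble(component = component, score = score, rho = sc$rho,
                   p_value = sc$p_value, n = sc$n)
  })
  fdr <- bh_fdr(res$p_value, q = q)
  res$p_adjusted <- fdr$adjusted
  res$significant <- fdr$rejected
  res$cohort <- cohort
  res
}
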