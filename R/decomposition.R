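#' PCA reduction of the demeaned subjects-by-voxels matrix
#'
#' Reduces the row-demeaned data matrix to its top-`n_components`
#' right-singular subspace.  `component_images` are the orthonormal
#' right-singular vectors (K x V); `projection` holds the subject coordinates
#' (N x K) so that `projection %*% component_images` is the best rank-K
#' least-squares approximation of the data.
#'
#' @param m A demeaned `sbm_matrix` (see [demean_rows()]).
#' @param n_components Integer K, `1 <= K <= min(N - 1, V)` (row demeaning
#'   caps the rank at N - 1).
#' @return An object of class `sbm_pca` with `component_images`,
#'   `projection`, `singular_values` (all N - 1 of them),
#'   `explained_variance_fraction`, `total_ss`, plus the subject ids and mask
#'   carried through.
#' @export
pca_reduce <- function(m, n_components) {
  stopifnot(inherits(m, "sbm_matrix"))
  if (!isTRUE(m$demeaned)) {
    stop("matrix must be row-demeaned before PCA (see demean_rows())",
         call. = FALSE)
  }
  X <- m$data
  N <- nrow(X); V <- ncol(X)
  K <- as.integer(n_components)
  if (is.na(K) || K < 1L || K > min(N - 1L, V)) {
    stop("`n_components` must lie in [1, min(N - 1, V)] = [1, ",
         min(N - 1L, V), "]; a row-demeaned matrix has rank at most N - 1",
         call. = FALSE)
  }
  total_ss <- sum(X^2)
  if (total_ss == 0) stop("zero-variance data matrix", call. = FALSE)
  sv <- svd(X, nu = min(N, V), nv = 0)
  # right-singular vectors via X^T U / d (avoids the V x V decomposition)
  keep <- which(sv$d > max(sv$d) * 1e-12)
  d <- sv$d[keep]
  U <- sv$u[, keep, drop = FALSE]
  if (K > length(d)) {
    stop("`n_components` exceeds the numerical rank (", length(d), ")",
         call. = FALSE)
  }
  Vt <- crossprod(U[, seq_len(K), drop = FALSE], X) / d[seq_len(K)]  # K x V
  structure(
    list(
      n_components = K,
      component_images = Vt,
      projection = U[, seq_len(K), drop = FALSE] %*%
        diag(d[seq_len(K)], nrow = K),
      singular_values = d,
      explained_variance_fraction = d[seq_len(K)]^2 / total_ss,
      total_ss = total_ss,
      subject_ids = m$subject_ids,
      row_means = m$row_means,
      mask = m$mask,
      data = X
    ),
    class = "sbm_pca"
  )
}

#' @export
print.sbm_pca <- function(x, ...) {
  cat(sprintf("<sbm_pca> %d components, %.1f%% variance retained\n",
              x$n_components, 100 * sum(x$explained_variance_fraction)))
  invisible(x)
}

logistic <- function(u) 1 / (1 + exp(-u))

#' Infomax spatial ICA on the PCA-reduced matrix
#'
#' Unmixes the whitened PCA component images into maximally independent
#' spatial sources with the Bell-Sejnowski Infomax natural-gradient rule,
#' `dW = lr * (I + (1 - 2*g(U)) U^T) W` with the logistic nonlinearity
#' `g(u) = 1/(1 + exp(-u))`, trained over random voxel mini-batches with an
#' annealed learning rate.  Voxels are the samples of the spatial ICA;
#' subjects' loading weights (the mixing matrix) are recovered afterwards by
#' least-squares projection of the demeaned data onto the sources.
#'
#' The logistic-only rule assumes super-Gaussian (sparse, peaked) spatial
#' sources, the usual regime for focal PET covariance patterns.  Set
#' `extended = TRUE` to enable kurtosis-sign switching (extended Infomax),
#' which also separates sub-Gaussian sources.
#'
#' @param pca An [pca_reduce()] result.
#' @param seed Integer seed for the mini-batch shuffling (required; the run
#'   is bit-reproducible given the same seed).
#' @param learning_rate Initial learning rate; default `0.015 / log(K)`
#'   (for K >= 2).
#' @param max_iterations Maximum training passes over the voxels.
#' @param tolerance Convergence threshold on the squared Frobenius norm of
#'   the per-pass weight change.
#' @param extended Logical, use extended Infomax (kurtosis-sign switching).
#' @param batch_size Voxels per mini-batch; default `min(V, 256)`.
#' @return An object of class `sbm_decomposition`: `mixing` (N x K),
#'   `sources` (K x V), `unmixing` (K x K, applied to the whitened PCA
#'   images), `converged`, `n_iterations`, `seed`, `reconstruction_rmse`
#'   (root-mean-square of the discarded PCA residual), plus subject ids and
#'   mask.
#' @export
infomax_ica <- function(pca, seed, learning_rate = NULL,
                        max_iterations = 512L, tolerance = 1e-6,
                        extended = FALSE, batch_size = NULL) {
  stopifnot(inherits(pca, "sbm_pca"))
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L) {
    stop("`seed` is required (a single integer)", call. = FALSE)
  }
  seed <- as.integer(seed)
  K <- pca$n_components
  V <- ncol(pca$component_images)
  X <- pca$data
  discarded_ss <- pca$total_ss - sum(pca$singular_values[seq_len(K)]^2)
  recon_rmse <- sqrt(max(discarded_ss, 0) / length(X))

  if (K == 1L) {
    sources <- pca$component_images
    mixing <- pca$projection
    d <- structure(
      list(mixing = mixing, sources = sources,
           unmixing = matrix(1, 1, 1), converged = TRUE, n_iterations = 0L,
           seed = seed, reconstruction_rmse = recon_rmse,
           subject_ids = pca$subject_ids, row_means = pca$row_means,
           mask = pca$mask, extended = extended),
      class = "sbm_decomposition"
    )
    return(orient_sources(d))
  }

  # whitening: rows of component_images are orthonormal, so Y has identity
  # covariance over voxels after scaling by sqrt(V)
  Y <- sqrt(V) * pca$component_images
  lrate <- learning_rate %||% (0.015 / log(K))
  B <- as.integer(batch_size %||% min(V, 256L))
  I_K <- diag(K)
  blowup <- 1e9

  state <- withr::with_seed(seed, {
    W <- I_K
    dW_prev <- NULL
    converged <- FALSE
    iter <- 0L
    signs <- rep(1, K)
    while (iter < max_iterations) {
      iter <- iter + 1L
      W_old <- W
      if (extended) {
        # kurtosis-sign estimate on a voxel subsample, refreshed per pass
        sub <- sample.int(V, min(V, 4096L))
        Us <- W %*% Y[, sub, drop = FALSE]
        k4 <- rowMeans(Us^4) / rowMeans(Us^2)^2 - 3
        signs <- ifelse(k4 >= 0, 1, -1)
      }
      perm <- sample.int(V)
      nb <- ceiling(V / B)
      bad <- FALSE
      for (b in seq_len(nb)) {
        idx <- perm[((b - 1L) * B + 1L):min(b * B, V)]
        U <- W %*% Y[, idx, drop = FALSE]
        nB <- length(idx)
        G <- if (extended) {
          I_K - (signs * tanh(U)) %*% t(U) / nB - U %*% t(U) / nB
        } else {
          I_K + (1 - 2 * logistic(U)) %*% t(U) / nB
        }
        W <- W + lrate * G %*% W
        if (any(!is.finite(W)) || max(abs(W)) > blowup) { bad <- TRUE; break }
      }
      if (bad) {
        # divergence: restart from identity with a smaller rate
        W <- I_K
        dW_prev <- NULL
        lrate <- lrate * 0.5
        next
      }
      dW <- W - W_old
      wchange <- sum(dW^2)
      if (!is.null(dW_prev)) {
        denom <- sqrt(sum(dW^2) * sum(dW_prev^2))
        if (denom > 0) {
          ang <- sum(dW * dW_prev) / denom
          if (ang < 0.5) lrate <- lrate * 0.9  # oscillation: anneal
        }
      }
      dW_prev <- dW
      if (wchange < tolerance) { converged <- TRUE; break }
    }
    list(W = W, converged = converged, iter = iter)
  })

  sources <- state$W %*% Y                      # K x V
  # loading weights by least squares: A = X S^T (S S^T)^{-1}
  G <- tcrossprod(sources)
  mixing <- X %*% t(sources) %*% solve(G)
  d <- structure(
    list(mixing = mixing, sources = sources, unmixing = state$W,
         converged = state$converged, n_iterations = state$iter,
         seed = seed, reconstruction_rmse = recon_rmse,
         subject_ids = pca$subject_ids, row_means = pca$row_means,
         mask = pca$mask, extended = extended),
    class = "sbm_decomposition"
  )
  orient_sources(d)
}

#' @export
print.sbm_decomposition <- function(x, ...) {
  cat(sprintf(paste0("<sbm_decomposition> %d subjects x %d components, ",
                     "%s after %d passes (seed %d)\n"),
              nrow(x$mixing), nrow(x$sources),
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations, x$seed))
  invisible(x)
}

#' Canonical sign orientation of the sources
#'
#' ICA is sign-indeterminate; this fixes one representative by flipping each
#' source (negating the source row and its mixing column together, leaving
#' the product unchanged) so that the voxel of maximum absolute value is
#' positive.
#'
#' @param d An `sbm_decomposition`.
#' @return The decomposition with oriented sources.
#' @export
orient_sources <- function(d) {
  stopifnot(inherits(d, "sbm_decomposition"))
  for (k in seq_len(nrow(d$sources))) {
    i <- which.max(abs(d$sources[k, ]))
    if (d$sources[k, i] < 0) {
      d$sources[k, ] <- -d$sources[k, ]
      d$mixing[, k] <- -d$mixing[, k]
      if (!is.null(d$unmixing)) d$unmixing[k, ] <- -d$unmixing[k, ]
    }
  }
  d
}

#' Match estimated sources against planted ground truth
#'
#' Greedy assignment maximizing absolute spatial Pearson correlation: the
#' best-correlated (truth, estimate) pair is fixed first, then the next among
#' the remainder, until every true source is matched to a distinct estimated
#' source.
#'
#' @param estimated An `sbm_decomposition` (or a K x V source matrix).
#' @param truth_sources K_true x V matrix of planted spatial sources.
#' @param truth_loadings Optional N x K_true matrix of planted loadings.
#' @return A tibble with one row per true source: `truth`, `estimate`
#'   (component index), `spatial_r` (signed), `sign`, and `loading_r` when
#'   loadings are supplied.
#' @export
match_sources <- function(estimated, truth_sources, truth_loadings = NULL) {
  S <- if (inherits(estimated, "sbm_decomposition")) estimated$sources
       else as.matrix(estimated)
  A <- if (inherits(estimated, "sbm_decomposition")) estimated$mixing
       else NULL
  Tt <- as.matrix(truth_sources)
  if (ncol(S) != ncol(Tt)) stop("voxel dimension mismatch", call. = FALSE)
  if (nrow(Tt) > nrow(S)) {
    stop("more true sources than estimated components", call. = FALSE)
  }
  R <- suppressWarnings(cor(t(Tt), t(S)))   # K_true x K
  R[!is.finite(R)] <- 0
  res <- vector("list", nrow(Tt))
  free_t <- seq_len(nrow(Tt)); free_e <- seq_len(nrow(S))
  Rw <- abs(R)
  for (step in seq_len(nrow(Tt))) {
    sub <- Rw[free_t, free_e, drop = FALSE]
    pos <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    ti <- free_t[pos[1]]; ei <- free_e[pos[2]]
    lr <- if (!is.null(truth_loadings) && !is.null(A)) {
      cor(truth_loadings[, ti], A[, ei])
    } else NA_real_
    res[[step]] <- tibble::tibble(
      truth = ti, estimate = ei, spatial_r = R[ti, ei],
      sign = ifelse(R[ti, ei] >= 0, 1, -1), loading_r = lr
    )
    free_t <- setdiff(free_t, ti); free_e <- setdiff(free_e, ei)
  }
  dplyr::arrange(dplyr::bind_rows(res), .data$truth)
}

#' Tidy the loading weights of a decomposition
#'
#' One row per subject-component pair with columns `subject_id`,
#' `component`, `loading`.
#' @param x An `sbm_decomposition`.
#' @param ... Unused.
#' @return A tibble of loading weights in long form.
#' @exportS3Method generics::tidy
tidy.sbm_decomposition <- function(x, ...) {
  K <- ncol(x$mixing)
  tibble::tibble(
    subject_id = rep(x$subject_ids, times = K),
    component = rep(seq_len(K), each = nrow(x$mixing)),
    loading = as.vector(x$mixing)
  )
}

#' One-row summary of a decomposition
#'
#' Subjects, components, voxels, convergence and reconstruction RMSE.
#' @param x An `sbm_decomposition`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @exportS3Method generics::glance
glance.sbm_decomposition <- function(x, ...) {
  tibble::tibble(
    n_subjects = nrow(x$mixing),
    n_components = ncol(x$mixing),
    n_voxels = ncol(x$sources),
    converged = x$converged,
    n_iterations = x$n_iterations,
    reconstruction_rmse = x$reconstruction_rmse,
    seed = x$seed
  )
}

#' Boxplots of loading weights per component
#'
#' For group-wise plots see [plot_loadings()].
#' @param object An `sbm_decomposition`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sbm_decomposition <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$component),
                                   y = .data$loading)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = "Component", y = "Loading weight") +
    ggplot2::theme_minimal()
}

#' Loading weights grouped by diagnosis
#'
#' @param d An `sbm_decomposition`.
#' @param metadata Cohort metadata tibble with `subject_id` and `group`.
#' @param components Components to show (default all).
#' @return A ggplot object.
#' @export
plot_loadings <- function(d, metadata, components = NULL) {
  df <- dplyr::inner_join(tidy(d), metadata, by = "subject_id")
  if (!is.null(components)) {
    df <- dplyr::filter(df, .data$component %in% components)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$loading,
                                   colour = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, size = 0.8, alpha = 0.7) +
    ggplot2::facet_wrap(~component, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "Loading weight") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
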