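# Shared fixtures and independent oracles (kept free of the package's own
# labelling / decomposition code paths).

random_volume <- function(dims = c(8, 8, 8), seed = 1, voxel = c(2, 2, 2),
                          quantity = "arbitrary") {
  withr::with_seed(seed, {
    pet_volume(array(rnorm(prod(dims)), dim = dims), voxel_size = voxel,
               subject_id = sprintf("rand%d", seed), quantity = quantity)
  })
}

full_mask <- function(dims = c(8, 8, 8)) {
  voxel_mask(array(TRUE, dim = dims))
}

# Independent connected-component oracle: iterative minimum-label
# propagation over shifted copies of the label array (no graph library, no
# shared code with the package's labeller).
flood_fill_oracle <- function(bin, connectivity) {
  d <- dim(bin)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nz <- rowSums(abs(offs))
  offs <- switch(as.character(connectivity),
                 "6"  = offs[nz == 1, , drop = FALSE],
                 "18" = offs[nz >= 1 & nz <= 2, , drop = FALSE],
                 "26" = offs[nz >= 1, , drop = FALSE])
  lab <- array(Inf, d)
  lab[bin] <- seq_len(sum(bin))
  shift_arr <- function(a, o) {
    out <- array(Inf, d)
    src_i <- max(1, 1 - o[1]):min(d[1], d[1] - o[1])
    src_j <- max(1, 1 - o[2]):min(d[2], d[2] - o[2])
    src_k <- max(1, 1 - o[3]):min(d[3], d[3] - o[3])
    out[src_i + o[1], src_j + o[2], src_k + o[3]] <-
      a[src_i, src_j, src_k]
    out
  }
  repeat {
    new <- lab
    for (r in seq_len(nrow(offs))) {
      new <- pmin(new, shift_arr(lab, offs[r, ]))
    }
    new[!bin] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  # membership vector over which(bin), renumbered 1..n_components
  m <- lab[bin]
  as.integer(factor(m))
}

# partition of voxel indices by component label
cluster_sets <- function(idx, labels) {
  unname(lapply(split(idx, labels), sort))
}

# a small fake decomposition carrying given loading weights, for testing the
# statistics layer in isolation
fake_decomposition <- function(mixing, subject_ids = NULL) {
  K <- ncol(mixing)
  structure(
    list(mixing = mixing,
         sources = matrix(rnorm(K * 50), nrow = K),
         unmixing = diag(K), converged = TRUE, n_iterations = 1L,
         seed = 0L, reconstruction_rmse = 0,
         subject_ids = subject_ids %||% sprintf("s%03d", seq_len(nrow(mixing))),
         row_means = rep(0, nrow(mixing)), mask = NULL, extended = FALSE),
    class = "sbm_decomposition"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
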