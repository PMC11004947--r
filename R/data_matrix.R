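#' Vectorize a cohort of masked volumes into a subjects-by-voxels matrix
#'
#' Row `i` of the result holds subject `i`'s voxel values at the mask's
#' included voxels, column `j` corresponding to `mask$flat_index[j]`
#' (column-major voxel order).  Subjects enter in list order, which is
#' recorded via `subject_ids` so that mixing-matrix rows stay attributable.
#'
#' @param volumes List of [pet_volume()]s on the mask's grid.
#' @param mask A [voxel_mask()].
#' @return An object of class `sbm_matrix`: `data` (N x V matrix),
#'   `row_means` (numeric N, zero until demeaned), `subject_ids`, `mask`,
#'   `demeaned` flag.
#' @export
vectorize_cohort <- function(volumes, mask) {
  stopifnot(inherits(mask, "voxel_mask"), length(volumes) >= 1L)
  ids <- vapply(seq_along(volumes), function(i) {
    v <- volumes[[i]]
    if (inherits(v, "pet_volume")) v$subject_id else paste0("S", i)
  }, "")
  V <- mask$n_voxels
  X <- matrix(NA_real_, nrow = length(volumes), ncol = V)
  for (i in seq_along(volumes)) {
    a <- vol_values(volumes[[i]])
    if (!identical(dim(a), dim(mask$included))) {
      stop("subject '", ids[i], "': volume grid does not match the mask",
           call. = FALSE)
    }
    row <- a[mask$flat_index]
    n_bad <- sum(!is.finite(row))
    if (n_bad > 0L) {
      stop("subject '", ids[i], "': ", n_bad,
           " non-finite value(s) inside the mask", call. = FALSE)
    }
    X[i, ] <- row
  }
  structure(
    list(data = X, row_means = rep(0, length(volumes)), subject_ids = ids,
         mask = mask, demeaned = FALSE),
    class = "sbm_matrix"
  )
}

#' @export
print.sbm_matrix <- function(x, ...) {
  cat(sprintf("<sbm_matrix> %d subjects x %d voxels, %sdemeaned\n",
              nrow(x$data), ncol(x$data), if (x$demeaned) "" else "not "))
  invisible(x)
}

#' Remove the per-subject mean from each row
#'
#' Subtracts the mean of each subject's row (the global masked mean value,
#' in the image's units) and stores the removed means in `row_means` so the
#' original matrix can be reconstructed exactly.
#'
#' @param m An [vectorize_cohort()] result with `demeaned = FALSE`.
#' @return The demeaned `sbm_matrix`.
#' @export
demean_rows <- function(m) {
  stopifnot(inherits(m, "sbm_matrix"))
  if (isTRUE(m$demeaned)) {
    stop("matrix is already demeaned; refusing to demean twice",
         call. = FALSE)
  }
  mu <- rowMeans(m$data)
  m$data <- m$data - mu
  m$row_means <- mu
  m$demeaned <- TRUE
  m
}

#' Restore masked volumes from a subjects-by-voxels matrix
#'
#' Inverts [vectorize_cohort()] (adding back `row_means` if the matrix was
#' demeaned).  Outside-mask voxels are set to `fill`.
#'
#' @param m An `sbm_matrix`.
#' @param fill Value for voxels outside the mask (default `NA`).
#' @param voxel_size Voxel spacing for the restored volumes.
#' @return A list of [pet_volume()]s in subject order.
#' @export
devectorize_cohort <- function(m, fill = NA_real_, voxel_size = c(2, 2, 2)) {
  stopifnot(inherits(m, "sbm_matrix"))
  d <- dim(m$mask$included)
  lapply(seq_len(nrow(m$data)), function(i) {
    a <- array(fill, dim = d)
    a[m$mask$flat_index] <- m$data[i, ] +
      if (isTRUE(m$demeaned)) m$row_means[i] else 0
    pet_volume(a, voxel_size = voxel_size, subject_id = m$subject_ids[i])
  })
}
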