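#' Parametric PET volume
#'
#' A lightweight container for one subject's 3-D scalar field on a fixed grid:
#' a numeric array plus voxel spacing in millimetres, a subject identifier,
#' and the physical quantity the voxel values represent (`"BP_ND"`, `"DVR"`,
#' or `"arbitrary"`).
#'
#' @param values Numeric 3-D array.
#' @param voxel_size Positive numeric length-3 vector, voxel edge lengths (mm).
#' @param subject_id Character scalar identifier.
#' @param quantity One of `"BP_ND"`, `"DVR"`, `"arbitrary"`.
#' @return An object of class `pet_volume`.
#' @export
pet_volume <- function(values, voxel_size = c(2, 2, 2),
                       subject_id = "unknown",
                       quantity = c("arbitrary", "BP_ND", "DVR")) {
  quantity <- match.arg(quantity)
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a 3-D array", call. = FALSE)
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0)) {
    stop("`voxel_size` must be three positive finite numbers", call. = FALSE)
  }
  structure(
    list(values = values, voxel_size = voxel_size,
         subject_id = as.character(subject_id), quantity = quantity),
    class = "pet_volume"
  )
}

#' @export
print.pet_volume <- function(x, ...) {
  cat(sprintf("<pet_volume> subject '%s', %s, grid %s, voxel %s mm\n",
              x$subject_id, x$quantity,
              paste(dim(x$values), collapse = "x"),
              paste(format(x$voxel_size), collapse = "x")))
  invisible(x)
}

#' @export
dim.pet_volume <- function(x) dim(x$values)

# Accept either a pet_volume or a bare 3-D array.
vol_values <- function(x) {
  if (inherits(x, "pet_volume")) x$values
  else if (is.array(x) && length(dim(x)) == 3L) x
  else stop("expected a `pet_volume` or 3-D array", call. = FALSE)
}

#' Voxel mask
#'
#' A boolean 3-D field defining the analysis support, together with the fixed
#' enumeration of included voxels used to map matrix columns to voxels.  The
#' flattening order is R's native column-major order (first axis fastest),
#' i.e. `flat_index = which(included)`; this order is fixed so that column
#' `j` of a subjects-by-voxels matrix always refers to the same voxel.
#'
#' @param included Logical 3-D array (or numeric, nonzero taken as included).
#' @return An object of class `voxel_mask` with fields `included` (logical
#'   array), `flat_index` (integer vector of linear indices), `n_voxels`.
#' @export
voxel_mask <- function(included) {
  if (inherits(included, "pet_volume")) included <- included$values
  if (!is.array(included) || length(dim(included)) != 3L) {
    stop("`included` must be a 3-D array", call. = FALSE)
  }
  inc <- array(as.logical(included != 0), dim = dim(included))
  inc[is.na(inc)] <- FALSE
  flat <- which(inc)
  if (length(flat) < 1L) stop("empty mask: no voxels included", call. = FALSE)
  structure(
    list(included = inc, flat_index = flat, n_voxels = length(flat)),
    class = "voxel_mask"
  )
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("<voxel_mask> grid %s, %d voxels included\n",
              paste(dim(x$included), collapse = "x"), x$n_voxels))
  invisible(x)
}

#' @export
dim.voxel_mask <- function(x) dim(x$included)

mask_coords <- function(mask) {
  # i/j/k coordinates of the included voxels, in flat_index order
  arrayInd(mask$flat_index, dim(mask$included))
}

#' Read a 3-D volume from a NIfTI file
#'
#' Loads a single-volume NIfTI image; 4-D images with a singleton fourth axis
#' are squeezed to 3-D.  Grid shape and voxel spacing are taken from the
#' header.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param subject_id Identifier to attach (defaults to the file name).
#' @param quantity Quantity label, see [pet_volume()].
#' @return A [pet_volume()].
#' @export
read_volume <- function(path, subject_id = NULL,
                        quantity = c("arbitrary", "BP_ND", "DVR")) {
  quantity <- match.arg(quantity)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- img[, , , 1L, drop = TRUE]
    d <- dim(img)
  }
  if (length(d) != 3L) {
    stop("not a single 3-D volume: ", path, " has dimensions ",
         paste(d, collapse = "x"), call. = FALSE)
  }
  pd <- RNifti::pixdim(img)[seq_len(3)]
  if (any(!is.finite(pd)) || any(pd <= 0)) {
    stop("non-finite or non-positive voxel spacing in header of ", path,
         call. = FALSE)
  }
  pet_volume(array(as.numeric(img), dim = d), voxel_size = pd,
             subject_id = subject_id %||% basename(path),
             quantity = quantity)
}

#' Write a volume to a NIfTI file
#'
#' @param vol A [pet_volume()] (or 3-D array, written with the given spacing).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size Spacing override when `vol` is a bare array.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, voxel_size = c(2, 2, 2)) {
  if (inherits(vol, "pet_volume")) {
    values <- vol$values
    voxel_size <- vol$voxel_size
  } else {
    values <- vol_values(vol)
  }
  if (!dir.exists(dirname(path))) {
    stop("parent directory does not exist: ", dirname(path), call. = FALSE)
  }
  arr <- array(as.numeric(values), dim = dim(values))
  attr(arr, "pixdim") <- voxel_size
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "double"), path)
  invisible(path)
}

# Discrete normalized Gaussian kernel; radius chosen so that the truncated
# mass is negligible (4 sigma).
gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  x <- seq(-r, r)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# n x n convolution matrix with mirror (half-sample symmetric) boundaries:
# out-of-range index i maps to 1-i below and 2n+1-i above, applied
# repeatedly.  Rows sum to exactly 1, so constant fields are preserved.
conv_matrix_reflect <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  reflect <- function(i) {
    while (any(bad <- (i < 1L | i > n))) {
      i[i < 1L] <- 1L - i[i < 1L]
      i[i > n] <- 2L * n + 1L - i[i > n]
    }
    i
  }
  C <- matrix(0, n, n)
  for (t in seq_along(kernel)) {
    j <- reflect(seq_len(n) + (t - 1L - r))
    C[cbind(seq_len(n), j)] <- C[cbind(seq_len(n), j)] + kernel[t]
  }
  C
}

#' Gaussian smoothing of a volume
#'
#' Separable per-axis Gaussian filtering with mirror (reflective) boundary
#' handling, so constant fields are preserved exactly.  The per-axis kernel
#' width is `sigma_voxels = fwhm_mm / (voxel_size * 2*sqrt(2*log(2)))`;
#' `fwhm_mm = 0` returns the input unchanged.
#'
#' @param vol A [pet_volume()].
#' @param fwhm_mm Non-negative full width at half maximum, millimetres.
#' @return A smoothed [pet_volume()].
#' @export
gaussian_smooth <- function(vol, fwhm_mm) {
  stopifnot(inherits(vol, "pet_volume"))
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || is.na(fwhm_mm) ||
      fwhm_mm < 0) {
    stop("`fwhm_mm` must be a single non-negative number", call. = FALSE)
  }
  if (fwhm_mm == 0) return(vol)
  fwhm_to_sigma <- 2 * sqrt(2 * log(2))
  a <- vol$values
  d <- dim(a)
  for (axis in 1:3) {
    sigma <- fwhm_mm / (vol$voxel_size[axis] * fwhm_to_sigma)
    C <- conv_matrix_reflect(d[axis], gaussian_kernel_1d(sigma))
    if (axis == 1L) {
      a <- array(C %*% matrix(a, nrow = d[1]), dim = d)
    } else {
      perm <- seq_len(3)
      perm[c(1, axis)] <- perm[c(axis, 1)]
      ap <- aperm(a, perm)
      dp <- dim(ap)
      ap <- array(C %*% matrix(ap, nrow = dp[1]), dim = dp)
      a <- aperm(ap, perm)
    }
  }
  pet_volume(a, voxel_size = vol$voxel_size, subject_id = vol$subject_id,
             quantity = vol$quantity)
}

#' Build or validate the analysis mask
#'
#' With `mode = "supplied"` the given mask is validated against the volumes'
#' grid and returned.  With `mode = "relative_mean"` (the default when no
#' mask is available) a voxel is included when the cross-subject mean
#' intensity exceeds `fraction` times the mean over voxels whose
#' cross-subject mean is positive -- a simple intensity rule standing in for
#' a template-derived whole-brain mask.
#'
#' @param volumes List of [pet_volume()]s on a common grid.
#' @param mode `"relative_mean"` or `"supplied"`.
#' @param supplied A [voxel_mask()] (required for `mode = "supplied"`).
#' @param fraction Threshold fraction in (0, 1) for `relative_mean`.
#' @return A [voxel_mask()].
#' @export
build_mask <- function(volumes, mode = c("relative_mean", "supplied"),
                       supplied = NULL, fraction = 0.3) {
  mode <- match.arg(mode)
  stopifnot(length(volumes) >= 1L)
  grids <- vapply(volumes, function(v) paste(dim(vol_values(v)),
                                             collapse = "x"), "")
  if (length(unique(grids)) != 1L) {
    stop("volumes are not on a common grid: ",
         paste(unique(grids), collapse = ", "), call. = FALSE)
  }
  if (mode == "supplied") {
    if (is.null(supplied)) stop("mode = 'supplied' requires `supplied`",
                                call. = FALSE)
    if (!inherits(supplied, "voxel_mask")) supplied <- voxel_mask(supplied)
    if (!identical(dim(supplied$included), dim(vol_values(volumes[[1]])))) {
      stop("supplied mask grid does not match the volumes", call. = FALSE)
    }
    return(supplied)
  }
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop("`fraction` must lie in (0, 1)", call. = FALSE)
  }
  acc <- vol_values(volumes[[1]]) * 0
  for (v in volumes) acc <- acc + vol_values(v)
  mean_vol <- acc / length(volumes)
  pos <- mean_vol[mean_vol > 0]
  if (length(pos) == 0L) stop("empty mask: no positive-mean voxels",
                              call. = FALSE)
  inc <- mean_vol > fraction * mean(pos)
  if (!any(inc)) stop("empty mask: threshold excluded every voxel",
                      call. = FALSE)
  voxel_mask(array(inc, dim = dim(mean_vol)))
}
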