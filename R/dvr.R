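#' Reference region for DVR normalization
#'
#' Wraps a voxel mask (typically the whole cerebellum) whose arithmetic mean
#' binding potential serves as the scalar reference for the DVR transform.
#'
#' @param mask A [voxel_mask()] of reference-region voxels.
#' @return An object of class `reference_region`.
#' @export
reference_region <- function(mask) {
  if (!inherits(mask, "voxel_mask")) mask <- voxel_mask(mask)
  structure(list(mask = mask, summary = "mean"), class = "reference_region")
}

#' Convert a binding-potential map to a DVR map
#'
#' Computes the distribution volume ratio referenced to a region-mean
#' binding potential: `DVR(v) = (BP_ND(v) + 1) / (mean BP_ND over reference
#' + 1)`.  By construction the mean DVR over the reference region is exactly
#' 1.  Nonphysical voxels (`BP_ND <= -1`) pass through arithmetically but are
#' counted and reported via a warning, since they indicate noise problems in
#' the parametric map.
#'
#' @param bp A [pet_volume()] with `quantity = "BP_ND"`.
#' @param reference A [reference_region()] (or [voxel_mask()]) on the same
#'   grid.
#' @return A [pet_volume()] with `quantity = "DVR"`; the number of
#'   nonphysical input voxels is attached as attribute `n_nonphysical`.
#' @export
bp_to_dvr <- function(bp, reference) {
  stopifnot(inherits(bp, "pet_volume"))
  if (bp$quantity != "BP_ND") {
    stop("input volume quantity must be 'BP_ND', got '", bp$quantity, "'",
         call. = FALSE)
  }
  if (inherits(reference, "voxel_mask")) reference <- reference_region(reference)
  stopifnot(inherits(reference, "reference_region"))
  rmask <- reference$mask
  if (!identical(dim(rmask$included), dim(bp$values))) {
    stop("reference mask grid does not match the volume", call. = FALSE)
  }
  ref_mean <- mean(bp$values[rmask$flat_index])
  if (!is.finite(ref_mean) || ref_mean <= -1) {
    stop("reference-region mean BP_ND is ", format(ref_mean),
         " (must exceed -1)", call. = FALSE)
  }
  n_bad <- sum(bp$values <= -1, na.rm = TRUE)
  if (n_bad > 0L) {
    warning(n_bad, " voxel(s) with nonphysical BP_ND <= -1 passed through",
            call. = FALSE)
  }
  out <- pet_volume((bp$values + 1) / (ref_mean + 1),
                    voxel_size = bp$voxel_size, subject_id = bp$subject_id,
                    quantity = "DVR")
  attr(out, "n_nonphysical") <- n_bad
  attr(out, "reference_mean_bp") <- ref_mean
  out
}
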