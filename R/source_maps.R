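#' Scale a source to a unit-SD Z map
#'
#' Standardizes a source row to mean 0, population SD 1 (divide by V, not
#' V - 1; fixed for bit-reproducibility) over the masked voxels and places
#' the values into the mask's voxels of a full-grid volume; outside-mask
#' voxels are 0.
#'
#' @param source_row Numeric vector of length `mask$n_voxels`.
#' @param mask A [voxel_mask()].
#' @param voxel_size Voxel spacing for the output volume.
#' @param subject_id Label attached to the output volume.
#' @return A [pet_volume()] Z map.
#' @export
zscale_source <- function(source_row, mask, voxel_size = c(2, 2, 2),
                          subject_id = "source") {
  stopifnot(inherits(mask, "voxel_mask"))
  x <- as.numeric(source_row)
  if (length(x) != mask$n_voxels) {
    stop("source length ", length(x), " does not match mask voxel count ",
         mask$n_voxels, call. = FALSE)
  }
  mu <- mean(x)
  sd_pop <- sqrt(mean((x - mu)^2))
  if (sd_pop == 0) stop("zero-variance source cannot be Z-scaled",
                        call. = FALSE)
  a <- array(0, dim = dim(mask$included))
  a[mask$flat_index] <- (x - mu) / sd_pop
  pet_volume(a, voxel_size = voxel_size, subject_id = subject_id)
}

# neighbourhood offsets for 6/18/26-connectivity (all, both directions)
connectivity_offsets <- function(connectivity) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L)) {
    stop("connectivity must be 6, 18 or 26", call. = FALSE)
  }
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  nz <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6" = nz == 1, "18" = nz >= 1 & nz <= 2, "26" = nz >= 1)
  off[keep, , drop = FALSE]
}

# label connected components among the voxels with linear indices `idx`
# (on grid `grid_shape`); returns an integer label per voxel of `idx`
label_components <- function(idx, grid_shape, connectivity = 26) {
  n <- length(idx)
  if (n == 0L) return(integer(0))
  off <- connectivity_offsets(connectivity)
  # keep one direction per offset pair; undirected edges cover both
  off <- off[seq_len(nrow(off) / 2), , drop = FALSE]
  pos <- integer(prod(grid_shape))
  pos[idx] <- seq_len(n)
  co <- arrayInd(idx, grid_shape)
  edges <- list()
  for (r in seq_len(nrow(off))) {
    ni <- co[, 1] + off[r, 1]; nj <- co[, 2] + off[r, 2]
    nk <- co[, 3] + off[r, 3]
    ok <- ni >= 1 & ni <= grid_shape[1] & nj >= 1 & nj <= grid_shape[2] &
      nk >= 1 & nk <= grid_shape[3]
    if (!any(ok)) next
    lin <- ni[ok] + (nj[ok] - 1L) * grid_shape[1] +
      (nk[ok] - 1L) * grid_shape[1] * grid_shape[2]
    nb <- pos[lin]
    hit <- nb > 0L
    if (any(hit)) {
      edges[[length(edges) + 1L]] <-
        cbind(which(ok)[hit], nb[hit])
    }
  }
  if (length(edges) == 0L) return(seq_len(n))
  g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::components(g)$membership[seq_len(n)]
}

#' Label connected components of a binary 3-D field
#'
#' Connected-component labelling under 6-, 18- or 26-connectivity (face,
#' edge, vertex adjacency).  Exposed directly so the labelling underlying
#' [extract_clusters()] can be validated against independent references.
#'
#' @param bin Logical (or numeric, nonzero = foreground) 3-D array.
#' @param connectivity 6, 18 or 26.
#' @return An integer 3-D array: 0 for background, component labels
#'   numbered from 1 elsewhere.
#' @export
label_clusters <- function(bin, connectivity = 26) {
  bin <- vol_values(bin) != 0
  idx <- which(bin)
  lab <- array(0L, dim = dim(bin))
  lab[idx] <- as.integer(label_components(idx, dim(bin), connectivity))
  lab
}

#' Extract suprathreshold connected clusters from a Z map
#'
#' The positive excursion set `{Z > z_threshold}` and the negative set
#' `{Z < -z_threshold}` are labelled separately into connected components
#' under the declared connectivity; components smaller than `min_size`
#' voxels are dropped, and rows are ordered by descending absolute peak Z.
#'
#' @param zmap A [pet_volume()] (or 3-D array) of Z values.
#' @param mask A [voxel_mask()]; only masked voxels are considered.
#' @param z_threshold Positive threshold (default 3).
#' @param min_size Minimum cluster size in voxels (default 500).
#' @param connectivity 6, 18 or 26 (default 26, vertex adjacency).
#' @param atlas Optional integer/character labelled 3-D array on the same
#'   grid; when given, each cluster is annotated with the atlas label at its
#'   peak voxel.
#' @return A tibble with columns `cluster`, `sign`, `peak_z`,
#'   `size_voxels`, `peak_i`, `peak_j`, `peak_k` (and `label` if an atlas is
#'   supplied); zero rows when nothing survives.
#' @export
extract_clusters <- function(zmap, mask, z_threshold = 3, min_size = 500,
                             connectivity = 26, atlas = NULL) {
  stopifnot(inherits(mask, "voxel_mask"))
  z <- vol_values(zmap)
  if (!identical(dim(z), dim(mask$included))) {
    stop("Z map grid does not match the mask", call. = FALSE)
  }
  if (!is.numeric(z_threshold) || z_threshold <= 0) {
    stop("`z_threshold` must be positive", call. = FALSE)
  }
  grid_shape <- dim(z)
  out <- list()
  for (sgn in c("positive", "negative")) {
    sel <- if (sgn == "positive") z > z_threshold else z < -z_threshold
    sel <- sel & mask$included
    idx <- which(sel)
    if (length(idx) == 0L) next
    lab <- label_components(idx, grid_shape, connectivity)
    for (l in unique(lab)) {
      vox <- idx[lab == l]
      if (length(vox) < min_size) next
      zv <- z[vox]
      pk <- vox[which.max(abs(zv))]
      pc <- arrayInd(pk, grid_shape)
      row <- tibble::tibble(
        sign = sgn, peak_z = z[pk], size_voxels = length(vox),
        peak_i = pc[1], peak_j = pc[2], peak_k = pc[3]
      )
      if (!is.null(atlas)) row$label <- as.character(atlas[pk])
      out[[length(out) + 1L]] <- row
    }
  }
  if (length(out) == 0L) {
    res <- tibble::tibble(
      cluster = integer(0), sign = character(0), peak_z = numeric(0),
      size_voxels = integer(0), peak_i = integer(0), peak_j = integer(0),
      peak_k = integer(0)
    )
    if (!is.null(atlas)) res$label <- character(0)
    return(res)
  }
  res <- dplyr::arrange(dplyr::bind_rows(out), dplyr::desc(abs(.data$peak_z)))
  dplyr::mutate(res, cluster = dplyr::row_number(), .before = 1)
}

#' Z maps and cluster tables for every component
#'
#' Scales each source to a unit-SD Z map, extracts suprathreshold clusters,
#' and assembles the per-source report.  When `output_dir` is given, the Z
#' maps are written as NIfTI files and the combined cluster table as
#' tab-separated text.
#'
#' @param d An `sbm_decomposition`.
#' @param mask A [voxel_mask()] (defaults to the one stored in `d`).
#' @inheritParams extract_clusters
#' @param voxel_size Voxel spacing for the Z maps.
#' @param output_dir Optional directory for NIfTI/TSV outputs.
#' @return A list with `clusters` (tibble over all sources, column `source`
#'   first) and `zmaps` (list of [pet_volume()], one per component).
#' @export
report_components <- function(d, mask = NULL, z_threshold = 3,
                              min_size = 500, connectivity = 26,
                              atlas = NULL, voxel_size = c(2, 2, 2),
                              output_dir = NULL) {
  stopifnot(inherits(d, "sbm_decomposition"))
  mask <- mask %||% d$mask
  K <- nrow(d$sources)
  zmaps <- vector("list", K)
  tabs <- vector("list", K)
  for (k in seq_len(K)) {
    zmaps[[k]] <- zscale_source(d$sources[k, ], mask,
                                voxel_size = voxel_size,
                                subject_id = sprintf("source_%02d", k))
    tk <- extract_clusters(zmaps[[k]], mask, z_threshold = z_threshold,
                           min_size = min_size, connectivity = connectivity,
                           atlas = atlas)
    if (nrow(tk) > 0) tk <- dplyr::mutate(tk, source = k, .before = 1)
    tabs[[k]] <- tk
  }
  clusters <- dplyr::bind_rows(tabs)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    for (k in seq_len(K)) {
      write_volume(zmaps[[k]],
                   file.path(output_dir, sprintf("source_%02d_z.nii.gz", k)))
    }
    write.table(clusters, file.path(output_dir, "clusters.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  list(clusters = clusters, zmaps = zmaps)
}

#' Plot one axial slice of a Z map
#'
#' @param zmap A [pet_volume()] Z map.
#' @param slice Index along the third axis (default: middle slice).
#' @param z_threshold Values with `|Z|` below this are blanked (default 3).
#' @return A ggplot object.
#' @export
plot_source_slice <- function(zmap, slice = NULL, z_threshold = 3) {
  a <- vol_values(zmap)
  slice <- slice %||% (dim(a)[3] %/% 2L)
  sl <- a[, , slice]
  df <- expand.grid(i = seq_len(nrow(sl)), j = seq_len(ncol(sl)))
  df$z <- as.vector(sl)
  df$z[abs(df$z) < z_threshold] <- NA
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "grey90",
                                  high = "red", na.value = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "Z") +
    ggplot2::theme_void()
}
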