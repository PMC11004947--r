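#' Synthetic brain anatomy for simulation
#'
#' Builds an ellipsoidal "brain" voxel mask with a spherical
#' "cerebellum" sub-region (inferior-posterior) that serves as the DVR
#' reference region.  Both are symmetric across the first-axis midline so
#' that bilateral sources can be planted by mirroring.  This is a synthetic
#' stand-in geometry, not an anatomical template.
#'
#' @param grid_shape Integer triple (default `c(32, 32, 32)`).
#' @param voxel_size Voxel spacing in mm (default 2 mm isotropic).
#' @return A list: `mask` ([voxel_mask()], brain incl. cerebellum),
#'   `reference` ([reference_region()], cerebellum), `cerebrum` (logical
#'   array, brain excluding a guard zone around the cerebellum — where
#'   sources may be planted), `grid_shape`, `voxel_size`.
#' @export
make_synthetic_anatomy <- function(grid_shape = c(32, 32, 32),
                                   voxel_size = c(2, 2, 2)) {
  g <- as.integer(grid_shape)
  stopifnot(length(g) == 3L, all(g >= 12L))
  ctr <- (g + 1) / 2
  co <- arrayInd(seq_len(prod(g)), g)
  # brain: ellipsoid, slightly superior
  br <- ((co[, 1] - ctr[1]) / (0.42 * g[1]))^2 +
    ((co[, 2] - ctr[2]) / (0.45 * g[2]))^2 +
    ((co[, 3] - (ctr[3] + 0.06 * g[3])) / (0.40 * g[3]))^2 <= 1
  # cerebellum: posterior-inferior sphere
  cb_ctr <- c(ctr[1], ctr[2] + 0.26 * g[2], ctr[3] - 0.26 * g[3])
  dist_cb <- sqrt((co[, 1] - cb_ctr[1])^2 + (co[, 2] - cb_ctr[2])^2 +
                    (co[, 3] - cb_ctr[3])^2)
  cb <- dist_cb <= 0.14 * max(g)
  brain <- array(br | cb, dim = g)
  cereb <- array(cb, dim = g)
  guard <- array(dist_cb <= 0.26 * max(g), dim = g)
  list(mask = voxel_mask(brain),
       reference = reference_region(voxel_mask(cereb)),
       cerebrum = brain & !guard,
       grid_shape = g, voxel_size = as.numeric(voxel_size))
}

gauss_blob <- function(co, center, sigma_vox, mirror_axis1 = NULL) {
  d2 <- ((co[, 1] - center[1])^2 + (co[, 2] - center[2])^2 +
           (co[, 3] - center[3])^2)
  b <- exp(-d2 / (2 * sigma_vox^2))
  if (!is.null(mirror_axis1)) {
    cm <- center
    cm[1] <- mirror_axis1 + 1 - center[1]
    d2m <- ((co[, 1] - cm[1])^2 + (co[, 2] - cm[2])^2 +
              (co[, 3] - cm[3])^2)
    b <- b + exp(-d2m / (2 * sigma_vox^2))
  }
  b
}

#' Plant smooth spatial sources inside a mask
#'
#' Each source is a sum of Gaussian-profile blobs: `"focal"` one unilateral
#' blob; `"bilateral"` a blob mirrored across the first-axis midline;
#' `"mixed_sign"` a positive and a distant negative blob; `"medial"` a blob
#' centred on the midline.  Sources are zeroed on `exclude` voxels (e.g. the
#' reference region), masked, and standardized to mean 0, unit SD over the
#' mask.  Placement is rejected and retried until all pairwise spatial
#' correlations satisfy `|r| <= max_abs_corr`.
#'
#' @param mask A [voxel_mask()].
#' @param k Number of sources.
#' @param geometry Character vector (length 1 or `k`) of
#'   `"focal"`, `"bilateral"`, `"mixed_sign"`, `"medial"`.
#' @param smoothness_fwhm_mm Blob full width at half maximum, mm
#'   (default 12).
#' @param seed Integer seed.
#' @param voxel_size Voxel spacing, mm.
#' @param allowed Optional logical array of voxels where blob centres may
#'   fall (default: anywhere in the mask).
#' @param exclude Optional [voxel_mask()] whose voxels are forced to 0
#'   (e.g. the reference region).
#' @param max_abs_corr Pairwise decorrelation bound (default 0.2).
#' @param max_tries Placement retries per source before erroring.
#' @return A `k x V` matrix over the mask's flat index, with attributes
#'   `geometry` and `centers`.
#' @export
make_sources <- function(mask, k, geometry = "focal",
                         smoothness_fwhm_mm = 12, seed = 1,
                         voxel_size = c(2, 2, 2), allowed = NULL,
                         exclude = NULL, max_abs_corr = 0.2,
                         max_tries = 200L) {
  stopifnot(inherits(mask, "voxel_mask"), k >= 1L)
  geometry <- rep_len(match.arg(geometry,
                                c("focal", "bilateral", "mixed_sign",
                                  "medial"), several.ok = TRUE),
                      k)
  g <- dim(mask$included)
  sigma_vox <- smoothness_fwhm_mm / (mean(voxel_size) * 2 * sqrt(2 * log(2)))
  allowed_arr <- allowed %||% mask$included
  if (!is.null(exclude)) {
    excl_idx <- if (inherits(exclude, "reference_region"))
      exclude$mask$flat_index else voxel_mask(exclude)$flat_index
  } else excl_idx <- integer(0)
  cand <- which(allowed_arr)
  stopifnot(length(cand) > 0)
  cand_co <- arrayInd(cand, g)
  co_mask <- mask_coords(mask)
  mid <- g[1] / 2

  withr::with_seed(seed, {
    S <- matrix(NA_real_, nrow = k, ncol = mask$n_voxels)
    centers <- vector("list", k)
    for (s in seq_len(k)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        pick <- function(medial = FALSE) {
          i <- sample.int(length(cand), 1L)
          ctr <- cand_co[i, ]
          if (medial) ctr[1] <- (g[1] + 1) / 2
          ctr
        }
        geom <- geometry[s]
        c1 <- pick(medial = geom == "medial")
        v <- gauss_blob(co_mask, c1, sigma_vox,
                        mirror_axis1 = if (geom == "bilateral") g[1] else NULL)
        ctrs <- list(c1)
        if (geom == "mixed_sign") {
          repeat {
            c2 <- pick()
            if (sqrt(sum((c2 - c1)^2)) > 4 * sigma_vox) break
          }
          v <- v - gauss_blob(co_mask, c2, sigma_vox)
          ctrs <- list(c1, c2)
        }
        # zero on excluded (reference) voxels, then standardize over mask
        # Zero the reference voxels, then centre by shifting the non-zeroed
        # voxels only (so the reference stays exactly 0 while the masked
        # mean is 0), and scale to unit population SD over the whole mask.
        if (length(excl_idx) > 0) {
          in_excl <- mask$flat_index %in% excl_idx
          v[in_excl] <- 0
          v[!in_excl] <- v[!in_excl] - sum(v) / sum(!in_excl)
        } else {
          v <- v - mean(v)
        }
        sdv <- sqrt(mean(v^2))
        if (sdv == 0) next
        v <- v / sdv
        if (s > 1L) {
          rr <- abs(cor(v, t(S[seq_len(s - 1L), , drop = FALSE])))
          if (any(rr > max_abs_corr)) next
        }
        S[s, ] <- v
        centers[[s]] <- ctrs
        placed <- TRUE
        break
      }
      if (!placed) {
        stop("could not place source ", s, " satisfying |r| <= ",
             max_abs_corr, " after ", max_tries, " tries", call. = FALSE)
      }
    }
    attr(S, "geometry") <- geometry
    attr(S, "centers") <- centers
    S
  })
}

#' Synthetic cohort configuration
#'
#' Bundles the generator's study conditions.  Defaults emulate a
#' three-group synaptic-density PET cohort: DVR-scale baselines of 1 inside
#' the brain, four planted covariance sources with distinct geometries
#' (one unilateral mixed-sign, one bilateral, one focal, one medial), source
#' amplitude 0.05 DVR units per loading-SD, voxel noise SD 0.03 DVR units, a
#' graded CN > MCI > AD loading shift of 1.0 / 0.5 / 0 loading-SD on source
#' 1, and MMSE-like / CDR-like scores monotonically linked to source 1's
#' loadings (slope +-1 loading-SD per score-SD, score noise SD 0.5); the
#' remaining scores are pure noise.
#'
#' @param grid_shape,voxel_size Grid geometry (default 32^3 at 2 mm).
#' @param k_true Number of planted sources.
#' @param geometry Geometry per source, see [make_sources()].
#' @param amplitude DVR units per loading-SD.
#' @param noise_sd Additive voxel noise SD, DVR units.
#' @param smoothness_fwhm_mm Blob FWHM, mm.
#' @param group_shifts `k_true x 3` matrix of mean loading offsets
#'   (columns CN, MCI, AD, in loading-SD units).
#' @param score_links Named list: per score, `list(source, slope, noise_sd)`.
#' @return A list of class `sbm_cohort_config`.
#' @export
cohort_config <- function(grid_shape = c(32, 32, 32),
                          voxel_size = c(2, 2, 2),
                          k_true = 4,
                          geometry = c("mixed_sign", "bilateral", "focal",
                                       "medial"),
                          amplitude = 0.05,
                          noise_sd = 0.03,
                          smoothness_fwhm_mm = 12,
                          group_shifts = NULL,
                          score_links = list(
                            mmse = list(source = 1, slope = 1,
                                        noise_sd = 0.5),
                            cdr_sb = list(source = 1, slope = -1,
                                          noise_sd = 0.5)
                          )) {
  if (is.null(group_shifts)) {
    group_shifts <- matrix(0, nrow = k_true, ncol = 3,
                           dimnames = list(NULL, c("CN", "MCI", "AD")))
    group_shifts[1, ] <- c(1, 0.5, 0)
  }
  stopifnot(nrow(group_shifts) == k_true, ncol(group_shifts) == 3)
  colnames(group_shifts) <- c("CN", "MCI", "AD")
  structure(
    list(grid_shape = grid_shape, voxel_size = voxel_size, k_true = k_true,
         geometry = geometry, amplitude = amplitude, noise_sd = noise_sd,
         smoothness_fwhm_mm = smoothness_fwhm_mm,
         group_shifts = group_shifts, score_links = score_links),
    class = "sbm_cohort_config"
  )
}

# map a raw linked score onto each measure's natural range (monotone, so
# rank statistics are preserved up to clipping/rounding ties)
score_to_natural <- function(score, raw) {
  switch(score,
    mmse = round(pmin(30, pmax(0, 24 + 2.5 * raw))),
    cdr_sb = pmax(0, round(2 * (3 + 1.5 * raw)) / 2),
    lmii = pmax(0, round(8 + 4 * raw, 1)),
    ravlt_delay = pmax(0, round(6 + 3 * raw)),
    raw
  )
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Draws per-subject loading weights as `group_shift[group] + N(0, 1)`,
#' builds each subject's volume as
#' `baseline + amplitude * (loadings %*% sources) + noise` inside the brain
#' mask (baseline 1, reference-region sources forced to 0 so the
#' reference-region mean DVR stays 1 up to noise), and generates cognitive
#' scores from the configured monotone links.  Fully reproducible from the
#' single seed.
#'
#' @param config A [cohort_config()].
#' @param n_per_group Integer triple `c(CN, MCI, AD)`; default
#'   `c(19, 14, 24)`, a typical early-AD SV2A-PET cohort split.
#' @param seed Integer seed.
#' @return A list: `volumes` (list of [pet_volume()], quantity DVR),
#'   `metadata` (tibble: subject_id, group, cdr_sb, mmse, lmii,
#'   ravlt_delay), `truth` (list: sources_true, loadings_true, group_shifts,
#'   amplitude, noise_sd, score_links, anatomy, seed).
#' @export
make_cohort <- function(config = cohort_config(),
                        n_per_group = c(19, 14, 24), seed = 1) {
  stopifnot(inherits(config, "sbm_cohort_config"))
  n_per_group <- as.integer(n_per_group)
  if (length(n_per_group) != 3L || any(n_per_group < 1L)) {
    stop("`n_per_group` must be three positive integers (CN, MCI, AD)",
         call. = FALSE)
  }
  seed <- as.integer(seed)
  anat <- make_synthetic_anatomy(config$grid_shape, config$voxel_size)
  S <- make_sources(anat$mask, k = config$k_true,
                    geometry = config$geometry,
                    smoothness_fwhm_mm = config$smoothness_fwhm_mm,
                    seed = seed, voxel_size = config$voxel_size,
                    allowed = anat$cerebrum, exclude = anat$reference)
  N <- sum(n_per_group)
  groups <- factor(rep(c("CN", "MCI", "AD"), times = n_per_group),
                   levels = c("CN", "MCI", "AD"))
  withr::with_seed(seed + 1L, {
    shift <- t(config$group_shifts[, as.character(groups), drop = FALSE])
    loadings <- shift + matrix(rnorm(N * config$k_true), nrow = N)
    mask_idx <- anat$mask$flat_index
    baseline <- array(0, dim = anat$grid_shape)
    baseline[mask_idx] <- 1
    signal <- loadings %*% S * config$amplitude   # N x V
    volumes <- vector("list", N)
    ids <- sprintf("sub-%03d", seq_len(N))
    for (i in seq_len(N)) {
      a <- baseline
      a[mask_idx] <- a[mask_idx] + signal[i, ] +
        rnorm(length(mask_idx), sd = config$noise_sd)
      volumes[[i]] <- pet_volume(a, voxel_size = config$voxel_size,
                                 subject_id = ids[i], quantity = "DVR")
    }
    score_names <- c("cdr_sb", "mmse", "lmii", "ravlt_delay")
    scores <- lapply(score_names, function(sc) {
      link <- config$score_links[[sc]]
      raw <- if (is.null(link)) rnorm(N) else {
        link$slope * loadings[, link$source] + rnorm(N, sd = link$noise_sd)
      }
      score_to_natural(sc, raw)
    })
    names(scores) <- score_names
    metadata <- tibble::tibble(subject_id = ids, group = groups, !!!scores)
    list(
      volumes = volumes,
      metadata = metadata,
      truth = list(sources_true = S, loadings_true = loadings,
                   group_shifts = config$group_shifts,
                   amplitude = config$amplitude, noise_sd = config$noise_sd,
                   score_links = config$score_links, anatomy = anat,
                   seed = seed)
    )
  })
}

#' Write a synthetic cohort to disk
#'
#' Writes per-subject NIfTI volumes, a tab-separated cohort manifest
#' (subject_id, path, group, scores), the brain and reference masks, the
#' planted source maps as NIfTI, and a JSON truth manifest.
#'
#' @param cohort A [make_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  anat <- cohort$truth$anatomy
  paths <- vapply(cohort$volumes, function(v) {
    p <- file.path(dir, paste0(v$subject_id, "_dvr.nii.gz"))
    write_volume(v, p)
    basename(p)
  }, "")
  manifest <- dplyr::mutate(cohort$metadata, path = paths,
                            .after = "subject_id")
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write_volume(pet_volume(array(as.numeric(anat$mask$included),
                                dim = dim(anat$mask$included)),
                          voxel_size = anat$voxel_size),
               file.path(dir, "brain_mask.nii.gz"))
  write_volume(pet_volume(array(as.numeric(anat$reference$mask$included),
                                dim = dim(anat$reference$mask$included)),
                          voxel_size = anat$voxel_size),
               file.path(dir, "cerebellum_mask.nii.gz"))
  for (k in seq_len(nrow(cohort$truth$sources_true))) {
    a <- array(0, dim = dim(anat$mask$included))
    a[anat$mask$flat_index] <- cohort$truth$sources_true[k, ]
    write_volume(pet_volume(a, voxel_size = anat$voxel_size),
                 file.path(dir, sprintf("truth_source_%02d.nii.gz", k)))
  }
  truth_meta <- list(
    seed = cohort$truth$seed,
    amplitude = cohort$truth$amplitude,
    noise_sd = cohort$truth$noise_sd,
    group_shifts = cohort$truth$group_shifts,
    score_links = cohort$truth$score_links,
    loadings_true = cohort$truth$loadings_true
  )
  jsonlite::write_json(truth_meta, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort manifest
#'
#' Reads a delimited manifest (TSV or CSV by extension) with columns
#' `subject_id`, `path`, `group` and optional score columns; volume paths
#' are resolved relative to the manifest's directory.
#'
#' @param path Manifest file path.
#' @param quantity Quantity label for the loaded volumes.
#' @return A list: `volumes` (list of [pet_volume()]), `metadata` (tibble).
#' @export
read_cohort_manifest <- function(path,
                                 quantity = c("DVR", "BP_ND", "arbitrary")) {
  quantity <- match.arg(quantity)
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("subject_id", "path", "group")
  if (!all(need %in% names(tab))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  volumes <- lapply(seq_len(nrow(tab)), function(i) {
    p <- tab$path[i]
    if (!file.exists(p)) p <- file.path(dirname(path), p)
    read_volume(p, subject_id = tab$subject_id[i], quantity = quantity)
  })
  list(volumes = volumes,
       metadata = tibble::as_tibble(tab[, setdiff(names(tab), "path")]))
}
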