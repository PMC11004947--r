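#' Run the full source-based morphometry pipeline
#'
#' End-to-end chain: optional BP_ND-to-DVR conversion, Gaussian smoothing,
#' mask construction, vectorization into the subjects-by-voxels matrix,
#' per-subject mean removal, PCA reduction, Infomax spatial ICA with sign
#' orientation, unit-SD Z maps with connected-cluster tables, and (when
#' metadata is supplied) the Kruskal-Wallis / Dunn / FDR group comparison
#' plus Spearman cognition correlations in the symptomatic-only and full
#' cohorts.  The run is deterministic given the inputs, the configuration
#' and the seed.
#'
#' Defaults follow the standard analysis choices for this method: 8 mm
#' smoothing, 18 components, `|Z| > 3` with 500-voxel minimum clusters, and
#' FDR level 0.05.
#'
#' @param volumes List of [pet_volume()]s, or a [make_cohort()] /
#'   [read_cohort_manifest()] result (its `volumes` and `metadata` are
#'   used).
#' @param metadata Optional tibble with `subject_id`, `group` and score
#'   columns.
#' @param seed Integer seed for the ICA (required).
#' @param mask Optional [voxel_mask()]; when absent, built with the
#'   relative-mean rule at `mask_fraction`.
#' @param convert_dvr Convert BP_ND inputs to DVR first (requires
#'   `cerebellum_mask`).
#' @param cerebellum_mask [voxel_mask()] of the reference region.
#' @param fwhm_mm Smoothing kernel FWHM, mm (default 8; 0 disables).
#' @param n_components Number of components K (default 18; must be
#'   `<= N - 1`).
#' @param z_threshold,min_cluster_voxels,connectivity Cluster reporting
#'   parameters (defaults 3.0, 500, 26).
#' @param q FDR level (default 0.05).
#' @param mask_fraction Relative-mean mask threshold fraction (default 0.3).
#' @param extended Use extended Infomax (default FALSE).
#' @param max_iterations,tolerance ICA training controls.
#' @param output_dir Optional directory; when given, Z maps, the mixing
#'   table, cluster and statistics tables, and a JSON run log are written.
#' @return An object of class `sbm_run`: list with `decomposition`,
#'   `mask`, `clusters`, `zmaps`, `group_stats`, `cognition_symptomatic`,
#'   `cognition_full`, `metadata`, `config`.
#' @export
run_sbm_pipeline <- function(volumes, metadata = NULL, seed,
                             mask = NULL, convert_dvr = FALSE,
                             cerebellum_mask = NULL, fwhm_mm = 8,
                             n_components = 18, z_threshold = 3,
                             min_cluster_voxels = 500, connectivity = 26,
                             q = 0.05, mask_fraction = 0.3,
                             extended = FALSE, max_iterations = 512L,
                             tolerance = 1e-6, output_dir = NULL) {
  if (is.list(volumes) && !is.null(volumes$volumes)) {
    metadata <- metadata %||% volumes$metadata
    volumes <- volumes$volumes
  }
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  N <- length(volumes)
  if (N < 3L) stop("need at least 3 subjects", call. = FALSE)
  if (n_components > N - 1L) {
    stop("`n_components` (", n_components, ") must not exceed N - 1 = ",
         N - 1L, " for a row-demeaned matrix", call. = FALSE)
  }
  config <- list(
    n_subjects = N, seed = as.integer(seed), fwhm_mm = fwhm_mm,
    n_components = n_components, z_threshold = z_threshold,
    min_cluster_voxels = min_cluster_voxels, connectivity = connectivity,
    q = q, mask_fraction = mask_fraction, convert_dvr = convert_dvr,
    extended = extended
  )
  if (convert_dvr) {
    if (is.null(cerebellum_mask)) {
      stop("`convert_dvr = TRUE` requires `cerebellum_mask`", call. = FALSE)
    }
    ref <- reference_region(cerebellum_mask)
    volumes <- lapply(volumes, bp_to_dvr, reference = ref)
  }
  voxel_size <- if (inherits(volumes[[1]], "pet_volume"))
    volumes[[1]]$voxel_size else c(2, 2, 2)
  if (fwhm_mm > 0) {
    volumes <- lapply(volumes, gaussian_smooth, fwhm_mm = fwhm_mm)
  }
  mask <- if (is.null(mask)) {
    build_mask(volumes, mode = "relative_mean", fraction = mask_fraction)
  } else {
    build_mask(volumes, mode = "supplied", supplied = mask)
  }
  m <- vectorize_cohort(volumes, mask)
  m <- demean_rows(m)
  pca <- pca_reduce(m, n_components)
  dec <- infomax_ica(pca, seed = seed, extended = extended,
                     max_iterations = max_iterations,
                     tolerance = tolerance)
  maps <- report_components(dec, mask, z_threshold = z_threshold,
                            min_size = min_cluster_voxels,
                            connectivity = connectivity,
                            voxel_size = voxel_size,
                            output_dir = if (is.null(output_dir)) NULL
                                         else file.path(output_dir, "maps"))
  group_stats <- NULL
  cog_sym <- NULL
  cog_full <- NULL
  if (!is.null(metadata)) {
    group_stats <- run_group_analysis(dec, metadata, q = q)
    score_cols <- intersect(c("cdr_sb", "mmse", "lmii", "ravlt_delay"),
                            names(metadata))
    if (length(score_cols) > 0) {
      cog_sym <- run_cognition_analysis(dec, metadata,
                                        cohort = "symptomatic_only",
                                        scores = score_cols, q = q)
      cog_full <- run_cognition_analysis(dec, metadata, cohort = "full",
                                         scores = score_cols, q = q)
    }
  }
  run <- structure(
    list(decomposition = dec, mask = mask, clusters = maps$clusters,
         zmaps = maps$zmaps, group_stats = group_stats,
         cognition_symptomatic = cog_sym, cognition_full = cog_full,
         metadata = metadata, config = config),
    class = "sbm_run"
  )
  if (!is.null(output_dir)) write_run(run, output_dir)
  run
}

#' @export
print.sbm_run <- function(x, ...) {
  cat(sprintf("<sbm_run> %d subjects, %d components (seed %d)\n",
              x$config$n_subjects, x$config$n_components, x$config$seed))
  cat(sprintf("  ICA %s after %d passes; reconstruction RMSE %.3g\n",
              if (x$decomposition$converged) "converged" else
                "did NOT converge",
              x$decomposition$n_iterations,
              x$decomposition$reconstruction_rmse))
  cat(sprintf("  %d suprathreshold cluster(s) across %d source(s)\n",
              nrow(x$clusters),
              length(unique(x$clusters$source))))
  if (!is.null(x$group_stats)) {
    sig <- sum(x$group_stats$significant)
    cat(sprintf("  group differences: %d/%d components FDR-significant\n",
                sig, nrow(x$group_stats)))
  }
  invisible(x)
}

# write tables, mixing matrix and the machine-readable run log
write_run <- function(run, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  d <- run$decomposition
  mixing <- data.frame(subject_id = d$subject_ids, d$mixing)
  names(mixing)[-1] <- sprintf("IC%02d", seq_len(ncol(d$mixing)))
  write.table(mixing, file.path(output_dir, "mixing.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(run$clusters, file.path(output_dir, "clusters.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(run$group_stats)) {
    gs <- dplyr::select(run$group_stats, -"posthoc")
    write.table(gs, file.path(output_dir, "group_stats.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    ph <- dplyr::bind_rows(
      purrr::map2(run$group_stats$component, run$group_stats$posthoc,
                  ~dplyr::mutate(.y, component = .x, .before = 1)))
    write.table(ph, file.path(output_dir, "posthoc.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  for (nm in c("cognition_symptomatic", "cognition_full")) {
    if (!is.null(run[[nm]])) {
      write.table(run[[nm]], file.path(output_dir, paste0(nm, ".tsv")),
                  sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  log <- c(run$config,
           list(converged = d$converged, n_iterations = d$n_iterations,
                reconstruction_rmse = d$reconstruction_rmse,
                n_mask_voxels = run$mask$n_voxels,
                subject_ids = d$subject_ids))
  jsonlite::write_json(log, file.path(output_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(output_dir)
}
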