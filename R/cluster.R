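#' Density-based clustering of segmented ePVS voxels
#'
#' Groups mask voxels by density-reachability in physical (mm) coordinates:
#' voxels whose centres lie within `linkage_mm` of each other belong to the
#' same cluster. Each cluster receives a unique positive label; clusters
#' smaller than `min_voxels` are dropped as noise. The default linkage of
#' 1.5 x the largest voxel dimension connects diagonal tube voxels while
#' keeping distinct tubes separate.
#'
#' @param filtered Binary candidate mask `image_volume`.
#' @param linkage_mm Density-reachability distance (mm); default
#'   `1.5 * max(spacing)`.
#' @param min_voxels Minimum cluster size (default 3).
#' @return An `epvs_report` with `labels` (label `image_volume`) and a
#'   `clusters` data frame (id, n_voxels); quantification fields are filled
#'   by [classify_and_quantify()]. An empty mask yields count 0, not an
#'   error.
#' @export
cluster_epvs <- function(filtered, linkage_mm = NULL, min_voxels = 3L) {
  stopifnot(inherits(filtered, "image_volume"))
  sp <- filtered$spacing
  if (is.null(linkage_mm)) linkage_mm <- 1.5 * max(sp)
  off <- stencil_offsets(sp, linkage_mm)
  comp <- label_mask_components(filtered$data, off)
  lab <- array(0L, dim(filtered$data))
  rows <- list()
  new_id <- 0L
  if (comp$n > 0L) {
    sizes <- tabulate(comp$labels, comp$n)
    for (g in seq_len(comp$n)) {
      if (sizes[g] < min_voxels) next
      new_id <- new_id + 1L
      lab[comp$idx[comp$labels == g]] <- new_id
      rows[[new_id]] <- data.frame(id = new_id, n_voxels = sizes[g])
    }
  }
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(0), n_voxels = integer(0))
  structure(list(labels = image_volume(lab, sp, "label"),
                 clusters = clusters,
                 params = list(linkage_mm = linkage_mm,
                               min_voxels = min_voxels)),
            class = "epvs_report")
}

#' @export
print.epvs_report <- function(x, ...) {
  n <- if (!is.null(x$clusters$class)) sum(x$clusters$class == "ePVS") else
    nrow(x$clusters)
  cat(sprintf("<epvs_report> %d clusters", nrow(x$clusters)))
  if (!is.null(x$totals)) {
    cat(sprintf("; ePVS count %d, total ePVS volume %.1f mm^3",
                x$totals$epvs_count, x$totals$epvs_volume_mm3))
  }
  cat("\n")
  invisible(x)
}

# Maximal-inscribed-sphere diameter of one cluster, via the Euclidean
# distance transform on its padded bounding box. Centre-to-centre distances
# overestimate the continuous inscribed radius by about half a voxel per
# side, so one mean voxel dimension is subtracted from the diameter.
cluster_diameter_mm <- function(lab_arr, id, spacing) {
  idx <- which(lab_arr == id)
  co <- arrayInd(idx, dim(lab_arr))
  mn <- apply(co, 2, min)
  mx <- apply(co, 2, max)
  dims <- mx - mn + 3L  # one background pad voxel on every side
  sub <- array(FALSE, dims)
  sub[cbind(co[, 1] - mn[1], co[, 2] - mn[2], co[, 3] - mn[3]) + 2L] <- TRUE
  d2 <- edt_sq(sub, spacing)
  max(2 * sqrt(max(d2[sub])) - mean(spacing), min(spacing))
}

#' Classify clusters by the STRIVE size rule and quantify volumes
#'
#' Per cluster: volume = voxel count x voxel volume (mm^3) and estimated
#' diameter = maximal inscribed-sphere diameter from the in-cluster distance
#' transform (robust for curved tubes). Clusters with diameter <= 3 mm are
#' classed `ePVS`; larger ones `perforated/lacune`. Totals aggregate the
#' ePVS class only.
#'
#' @param report An `epvs_report` from [cluster_epvs()].
#' @param size_cut_mm Class boundary (default 3 mm; the boundary itself is
#'   assigned to ePVS).
#' @return The report with per-cluster `volume_mm3`, `diameter_mm`, `class`,
#'   and a `totals` list (`epvs_count`, `epvs_volume_mm3`).
#' @export
classify_and_quantify <- function(report, size_cut_mm = 3.0) {
  stopifnot(inherits(report, "epvs_report"))
  sp <- report$labels$spacing
  vv <- prod(sp)
  cl <- report$clusters
  if (nrow(cl)) {
    cl$volume_mm3 <- cl$n_voxels * vv
    cl$diameter_mm <- vapply(cl$id, function(id)
      cluster_diameter_mm(report$labels$data, id, sp), 0)
    cl$class <- ifelse(cl$diameter_mm <= size_cut_mm, "ePVS", "perforated/lacune")
  } else {
    cl$volume_mm3 <- numeric(0); cl$diameter_mm <- numeric(0)
    cl$class <- character(0)
  }
  report$clusters <- cl
  is_e <- cl$class == "ePVS"
  report$totals <- list(epvs_count = sum(is_e),
                        epvs_volume_mm3 = sum(cl$volume_mm3[is_e]))
  report$params$size_cut_mm <- size_cut_mm
  report
}

#' Remove clusters overlapping an exclusion mask
#'
#' Programmatic analogue of manual false-positive review: clusters whose
#' overlap fraction with the exclusion mask exceeds `overlap_frac` are
#' removed and the totals recomputed.
#'
#' @param report A quantified `epvs_report`.
#' @param exclusion_mask Mask `image_volume`, co-registered, or `NULL`.
#' @param overlap_frac Removal threshold on the overlapped fraction of a
#'   cluster (default 0.5; strictly-greater comparison).
#' @return The pruned report.
#' @export
apply_exclusions <- function(report, exclusion_mask, overlap_frac = 0.5) {
  stopifnot(inherits(report, "epvs_report"))
  if (is.null(exclusion_mask)) return(report)
  assert_coregistered(list(report$labels, exclusion_mask))
  cl <- report$clusters
  if (nrow(cl) == 0L) return(report)
  drop_ids <- integer(0)
  for (id in cl$id) {
    vox <- which(report$labels$data == id)
    frac <- mean(exclusion_mask$data[vox] != 0)
    if (frac > overlap_frac) drop_ids <- c(drop_ids, id)
  }
  if (length(drop_ids)) {
    report$labels$data[report$labels$data %in% drop_ids] <- 0L
    cl <- cl[!cl$id %in% drop_ids, , drop = FALSE]
  }
  report$clusters <- cl
  is_e <- cl$class == "ePVS"
  report$totals <- list(epvs_count = sum(is_e),
                        epvs_volume_mm3 = sum(cl$volume_mm3[is_e]))
  report$params$overlap_frac <- overlap_frac
  report
}

#' Pipeline configuration
#'
#' All thresholds and scales of the segmentation pipeline in one place; every
#' run records the resolved configuration in its provenance.
#'
#' @param wm_threshold WM probability binarization cut (inclusive).
#' @param k1,k2 CSF-likeness cuts relative to WM means (see
#'   [detect_candidates()]).
#' @param min_corr Component correlation cut ([correlation_filter()]).
#' @param max_rel_dist Single-voxel pass distance ([correlation_filter()]).
#' @param scales_mm Vesselness scales ([vesselness()]).
#' @param min_vesselness Component tubularity cut ([tubularity_filter()]).
#' @param linkage_mm,min_voxels Clustering parameters ([cluster_epvs()]).
#' @param size_cut_mm STRIVE class boundary ([classify_and_quantify()]).
#' @param overlap_frac Exclusion overlap threshold ([apply_exclusions()]).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(wm_threshold = 0.90, k1 = 0.7, k2 = 1.3,
                            min_corr = 0.5, max_rel_dist = 0.25,
                            scales_mm = c(0.5, 1.0, 1.5),
                            min_vesselness = 0.15,
                            linkage_mm = NULL, min_voxels = 3L,
                            size_cut_mm = 3.0, overlap_frac = 0.5) {
  structure(list(wm_threshold = wm_threshold, k1 = k1, k2 = k2,
                 min_corr = min_corr, max_rel_dist = max_rel_dist,
                 scales_mm = scales_mm, min_vesselness = min_vesselness,
                 linkage_mm = linkage_mm, min_voxels = min_voxels,
                 size_cut_mm = size_cut_mm, overlap_frac = overlap_frac),
            class = "pipeline_config")
}

#' Run the full ePVS quantification pipeline
#'
#' Composition: WM-mask binarization, tissue intensity model, CSF-like
#' candidate detection, component correlation filtering, multiscale Sato
#' tubularity filtering, density-based clustering, STRIVE size
#' classification/volumetrics, and optional exclusion-mask pruning. The
#' returned report carries full provenance (all thresholds and scales).
#'
#' @param t1,t2 Intensity `image_volume`s, co-registered.
#' @param tissue_probs List of probability `image_volume`s `gm`, `wm`, `csf`.
#' @param config A [pipeline_config()].
#' @param exclusion_mask Optional mask `image_volume`.
#' @param keep_intermediates Keep stage outputs in the result (for
#'   diagnostics); default `FALSE`.
#' @return A quantified `epvs_report`; `$provenance` holds the resolved
#'   configuration, `$intermediates` the stage outputs when requested.
#' @export
run_pipeline <- function(t1, t2, tissue_probs, config = pipeline_config(),
                         exclusion_mask = NULL, keep_intermediates = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  vols <- list(t1, t2, tissue_probs$gm, tissue_probs$wm, tissue_probs$csf)
  if (!is.null(exclusion_mask)) vols <- c(vols, list(exclusion_mask))
  assert_coregistered(vols)
  wm <- binarize_wm(tissue_probs$wm, config$wm_threshold)
  model <- fit_intensity_model(t1, t2, tissue_probs)
  cand <- detect_candidates(t1, t2, wm, model, k1 = config$k1, k2 = config$k2)
  corr <- correlation_filter(cand, t1, t2, model, min_corr = config$min_corr,
                             max_rel_dist = config$max_rel_dist)
  vmap <- vesselness(t1, scales_mm = config$scales_mm, polarity = "dark")
  tub <- tubularity_filter(corr, vmap, min_vesselness = config$min_vesselness)
  report <- cluster_epvs(tub, linkage_mm = config$linkage_mm,
                         min_voxels = config$min_voxels)
  report <- classify_and_quantify(report, size_cut_mm = config$size_cut_mm)
  report <- apply_exclusions(report, exclusion_mask,
                             overlap_frac = config$overlap_frac)
  resolved <- unclass(config)
  resolved$linkage_mm <- report$params$linkage_mm
  report$provenance <- resolved
  report$intensity_model <- model
  if (keep_intermediates) {
    report$intermediates <- list(wm = wm, candidates = cand,
                                 correlation_filtered = corr,
                                 vesselness = vmap, tubularity_filtered = tub)
  }
  report
}

#' Write an ePVS report to disk
#'
#' Label map as NIfTI-1, per-cluster table as CSV, and a summary + provenance
#' JSON.
#'
#' @param report A quantified `epvs_report`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_epvs_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(report$labels, file.path(dir, "epvs_labels.nii.gz"))
  utils::write.csv(report$clusters, file.path(dir, "epvs_clusters.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(totals = report$totals,
                            provenance = report$provenance),
                       file.path(dir, "epvs_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
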