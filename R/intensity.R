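#' Binarize a white-matter probability map
#'
#' The working mask for all ePVS detection: voxels whose WM probability is at
#' or above the threshold (inclusive boundary; 0.90 by convention).
#'
#' @param wm_probability Probability `image_volume`.
#' @param threshold Probability cut, default 0.90.
#' @return A mask `image_volume` with attribute `threshold`.
#' @export
binarize_wm <- function(wm_probability, threshold = 0.90) {
  stopifnot(inherits(wm_probability, "image_volume"))
  m <- array(as.numeric(wm_probability$data >= threshold),
             dim(wm_probability$data))
  if (sum(m) == 0) stop("empty WM mask at threshold ", threshold)
  out <- image_volume(m, wm_probability$spacing, "mask")
  attr(out, "threshold") <- threshold
  out
}

#' Fit the multimodal tissue intensity model
#'
#' Computes per-modality WM/GM/CSF mean intensities over each tissue's
#' binarized probability map, the WM-mean-normalized tissue profiles used as
#' the CSF "signature" downstream, and linear coefficients regressing each
#' modality's WM-normalized intensity on the CSF probability (predictor) with
#' GM probability as nuisance, over the union of the tissue compartments.
#'
#' @param t1,t2 Intensity `image_volume`s, co-registered.
#' @param tissue_probs List with probability `image_volume`s `gm`, `wm`, `csf`.
#' @param prob_threshold Binarization cut for tissue means (default 0.5).
#' @param max_fit_voxels Subsample cap for the regression fit.
#' @return An `intensity_model`: `means` (2x3 matrix, modality x tissue),
#'   `profiles` (WM-normalized means; WM column is (1,1)), `coefficients`
#'   (per-modality lm coefficients), `prob_threshold`.
#' @export
fit_intensity_model <- function(t1, t2, tissue_probs, prob_threshold = 0.5,
                                max_fit_voxels = 50000L) {
  assert_coregistered(list(t1, t2, tissue_probs$gm, tissue_probs$wm,
                           tissue_probs$csf))
  masks <- lapply(tissue_probs[c("wm", "gm", "csf")],
                  function(p) p$data >= prob_threshold)
  for (nm in names(masks)) {
    if (sum(masks[[nm]]) == 0) stop("empty tissue compartment: ", nm)
  }
  means <- rbind(
    T1 = vapply(masks, function(m) mean(t1$data[m]), 0),
    T2 = vapply(masks, function(m) mean(t2$data[m]), 0)
  )
  colnames(means) <- toupper(colnames(means))
  if (any(means[, "WM"] <= 0)) stop("degenerate intensity model: WM mean <= 0")
  profiles <- means / means[, "WM"]

  # regression of WM-normalized intensities on CSF (predictor) and GM
  # (nuisance) probabilities over the labelled compartments
  all_idx <- which(masks$wm | masks$gm | masks$csf)
  if (length(all_idx) > max_fit_voxels) {
    all_idx <- all_idx[round(seq(1, length(all_idx), length.out = max_fit_voxels))]
  }
  df <- data.frame(
    nT1 = t1$data[all_idx] / means["T1", "WM"],
    nT2 = t2$data[all_idx] / means["T2", "WM"],
    csf = tissue_probs$csf$data[all_idx],
    gm = tissue_probs$gm$data[all_idx]
  )
  coefs <- list(
    T1 = stats::coef(stats::lm(nT1 ~ csf + gm, data = df)),
    T2 = stats::coef(stats::lm(nT2 ~ csf + gm, data = df))
  )
  structure(list(means = means, profiles = profiles, coefficients = coefs,
                 prob_threshold = prob_threshold),
            class = "intensity_model")
}

#' @export
print.intensity_model <- function(x, ...) {
  cat("<intensity_model> tissue means (modality x tissue):\n")
  print(round(x$means, 2))
  invisible(x)
}

#' Detect CSF-like candidate voxels within the WM mask
#'
#' A WM voxel is a candidate when its (T1, T2) pair looks like CSF relative
#' to the WM reference: T1 below `k1` times the WM T1 mean and T2 above `k2`
#' times the WM T2 mean. The cuts are relative, so the detection is invariant
#' to global intensity scaling. A per-voxel score (1 at the CSF profile,
#' falling off with normalized distance) is attached.
#'
#' @param t1,t2 Intensity `image_volume`s.
#' @param wm A WM mask from [binarize_wm()].
#' @param model An `intensity_model`.
#' @param k1 T1 low cut as a fraction of the WM T1 mean (default 0.7).
#' @param k2 T2 high cut as a multiple of the WM T2 mean (default 1.3).
#' @return A mask `image_volume` (the candidate map) with attribute `score`
#'   (numeric vector over candidate voxels, parallel to `which(data == 1)`).
#' @export
detect_candidates <- function(t1, t2, wm, model, k1 = 0.7, k2 = 1.3) {
  assert_coregistered(list(t1, t2, wm))
  if (any(model$means[, "WM"] <= 0)) stop("degenerate intensity model: WM mean <= 0")
  wm_t1 <- model$means["T1", "WM"]; wm_t2 <- model$means["T2", "WM"]
  cand <- wm$data == 1 & t1$data < wm_t1 * k1 & t2$data > wm_t2 * k2
  out <- image_volume(array(as.numeric(cand), dim(wm$data)), wm$spacing, "mask")
  idx <- which(cand)
  csf <- model$profiles[, "CSF"]
  d <- sqrt(((t1$data[idx] / wm_t1 - csf["T1"]) / csf["T1"])^2 +
              ((t2$data[idx] / wm_t2 - csf["T2"]) / csf["T2"])^2)
  attr(out, "score") <- as.numeric(1 / (1 + d))
  out
}

#' Correlation-filter candidate components against the CSF profile
#'
#' For each connected candidate component (26-connectivity), the observed
#' WM-normalized (T1, T2) intensities of its voxels are correlated with the
#' model-predicted CSF profile; components whose correlation reaches
#' `min_corr` are retained as true ePVS representations. Components of a
#' single voxel, where correlation is undefined, pass when their normalized
#' distance to the CSF profile is within `max_rel_dist` (they are assigned
#' pseudo-correlation `1 - distance`), so small ePVS are not silently lost.
#'
#' @param candidates Candidate mask from [detect_candidates()].
#' @param t1,t2 Intensity `image_volume`s.
#' @param model An `intensity_model`.
#' @param min_corr Minimum component correlation (default 0.5); `-1` disables
#'   filtering.
#' @param max_rel_dist Relative-distance pass for single-voxel components.
#' @return Filtered candidate mask; attribute `component_corr` holds the
#'   per-component correlations.
#' @export
correlation_filter <- function(candidates, t1, t2, model, min_corr = 0.5,
                               max_rel_dist = 0.25) {
  assert_coregistered(list(candidates, t1, t2))
  comp <- label_mask_components(candidates$data, offsets_26())
  keep <- array(0, dim(candidates$data))
  if (comp$n == 0L) {
    out <- image_volume(keep, candidates$spacing, "mask")
    attr(out, "component_corr") <- numeric(0)
    return(out)
  }
  wm_t1 <- model$means["T1", "WM"]; wm_t2 <- model$means["T2", "WM"]
  csf <- model$profiles[, "CSF"]
  corrs <- numeric(comp$n)
  for (g in seq_len(comp$n)) {
    vox <- comp$idx[comp$labels == g]
    o1 <- t1$data[vox] / wm_t1
    o2 <- t2$data[vox] / wm_t2
    if (length(vox) == 1L) {
      d <- sqrt(((o1 - csf["T1"]) / csf["T1"])^2 + ((o2 - csf["T2"]) / csf["T2"])^2)
      corrs[g] <- 1 - d
      ok <- d <= max_rel_dist
    } else {
      obs <- c(o1, o2)
      pred <- rep(c(csf["T1"], csf["T2"]), times = c(length(vox), length(vox)))
      corrs[g] <- if (stats::sd(obs) < 1e-12) 0 else stats::cor(obs, pred)
      ok <- corrs[g] >= min_corr
    }
    if (min_corr <= -1) ok <- TRUE
    if (ok) keep[vox] <- 1
  }
  out <- image_volume(keep, candidates$spacing, "mask")
  attr(out, "component_corr") <- corrs
  out
}
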