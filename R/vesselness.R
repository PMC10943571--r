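#' Multiscale Hessian (Sato) tubularity map
#'
#' At each scale the volume is Gaussian-smoothed, the 3x3 Hessian is formed
#' from finite differences in physical (mm) units and scale-normalized by
#' sigma^2, and its eigenvalues l1 >= l2 >= l3 are computed analytically per
#' voxel. The Sato line measure responds when two eigenvalues are large and
#' negative (the tube cross-section) while the eigenvalue along the principal
#' direction stays near zero:
#'
#'   s = |l3| (l2/l3)^g23 * (1 + l1/|l2|)^g12         for l2 <= l1 <= 0
#'   s = |l3| (l2/l3)^g23 * (1 - a l1/|l2|)^g12        for 0 < l1 < |l2|/a
#'
#' and 0 otherwise. Dark tubes (CSF on T1) are handled by negating the input
#' (`polarity = "dark"`). The per-voxel maximum over scales is normalized to
#' \[0, 1\] over the volume, making the map invariant to global intensity
#' scaling; a constant volume maps to all zeros.
#'
#' @param intensity Intensity `image_volume`.
#' @param scales_mm Gaussian scales (sigma, mm); defaults `c(0.5, 1, 1.5)`
#'   bracket sub-3-mm tubes.
#' @param polarity `"dark"` for CSF-dark tubes on T1, `"bright"` otherwise.
#' @param alpha Asymmetry penalty for l1 > 0 (default 0.25).
#' @param gamma12,gamma23 Sharpness exponents (default 1).
#' @return Scalar `image_volume` in \[0, 1\]; attribute `scales_mm`.
#' @export
vesselness <- function(intensity, scales_mm = c(0.5, 1.0, 1.5),
                       polarity = c("dark", "bright"), alpha = 0.25,
                       gamma12 = 1, gamma23 = 1) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(intensity, "image_volume"), length(scales_mm) >= 1L,
            all(scales_mm > 0))
  sp <- intensity$spacing
  if (any(scales_mm < min(sp) / 2)) {
    stop("scale smaller than half the minimum voxel spacing")
  }
  a <- intensity$data
  if (polarity == "dark") a <- -a
  best <- array(0, dim(a))
  for (s in scales_mm) {
    g <- gaussian_smooth(a, s, sp)
    gx <- deriv1(g, 1L, sp[1]); gy <- deriv1(g, 2L, sp[2]); gz <- deriv1(g, 3L, sp[3])
    h11 <- deriv2(g, 1L, sp[1]) * s^2
    h22 <- deriv2(g, 2L, sp[2]) * s^2
    h33 <- deriv2(g, 3L, sp[3]) * s^2
    h12 <- deriv1(gx, 2L, sp[2]) * s^2
    h13 <- deriv1(gx, 3L, sp[3]) * s^2
    h23 <- deriv1(gy, 3L, sp[3]) * s^2
    rm(gx, gy, gz)
    ev <- sym3_eigenvalues(h11, h12, h13, h22, h23, h33)
    l1 <- ev$e1; l2 <- ev$e2; l3 <- ev$e3
    rm(ev, h11, h12, h13, h22, h23, h33)
    tube <- l2 < 0 & l3 < 0
    sc <- array(0, dim(a))
    al2 <- abs(l2[tube])
    pen <- ifelse(l1[tube] <= 0,
                  pmax(0, 1 + l1[tube] / al2),
                  pmax(0, 1 - alpha * l1[tube] / al2))
    sc[tube] <- abs(l3[tube]) * (l2[tube] / l3[tube])^gamma23 * pen^gamma12
    best <- pmax(best, sc)
  }
  # floor at rounding-noise level relative to the data scale, so constant
  # volumes map to exact zeros rather than normalized numerical dust
  mx <- max(best)
  if (mx > 1e-9 * max(abs(a), 1)) best <- best / mx else best[] <- 0
  out <- image_volume(best, sp, "probability")
  attr(out, "scales_mm") <- scales_mm
  out
}

#' Filter candidate components by tubularity
#'
#' Retains candidate components that look like tortuous tubes rather than
#' ovoid cavities, on two complementary criteria:
#'
#' * the per-component vesselness summary (90th percentile of member-voxel
#'   Sato scores) must reach `min_vesselness`, and
#' * a scale-free shape index, component volume divided by the cube of its
#'   maximal inscribed-sphere diameter, must reach `min_shape_index`. A
#'   sphere scores pi/6 (about 0.52) whatever its size; a thin tube of
#'   length L and radius r scores (pi/8)(L/r), which is large even when the
#'   tube is strongly curved.
#'
#' The shape index is what separates ovoid lacune-like cavities from tubes:
#' boundary-shell voxels of a dark sphere carry genuinely tube-like Hessian
#' signatures, so a vesselness quantile alone cannot make the distinction.
#' Components that fail either test are routed to a lacune-candidate mask,
#' not discarded silently. `min_vesselness = 0` disables the filter entirely
#' (output equals input).
#'
#' @param candidates Candidate mask `image_volume`.
#' @param vmap Vesselness map from [vesselness()], same grid.
#' @param min_vesselness Minimum component vesselness summary (default 0.15);
#'   `0` disables filtering.
#' @param summary_prob Quantile used as the component summary (default 0.9).
#' @param min_shape_index Minimum volume / inscribed-diameter^3 (default 4).
#' @return Filtered candidate mask with attributes `lacune_candidates`
#'   (mask `image_volume` of removed components), `component_vesselness`
#'   and `component_shape_index`.
#' @export
tubularity_filter <- function(candidates, vmap, min_vesselness = 0.15,
                              summary_prob = 0.9, min_shape_index = 4) {
  assert_coregistered(list(candidates, vmap))
  comp <- label_mask_components(candidates$data, offsets_26())
  keep <- array(0, dim(candidates$data))
  lac <- array(0, dim(candidates$data))
  vsum <- numeric(comp$n)
  shp <- numeric(comp$n)
  if (comp$n > 0L) {
    lab <- array(0L, dim(candidates$data))
    lab[comp$idx] <- comp$labels
    vv <- prod(candidates$spacing)
    for (g in seq_len(comp$n)) {
      vox <- comp$idx[comp$labels == g]
      vsum[g] <- stats::quantile(vmap$data[vox], probs = summary_prob,
                                 names = FALSE)
      d <- cluster_diameter_mm(lab, g, candidates$spacing)
      shp[g] <- length(vox) * vv / d^3
      ok <- min_vesselness <= 0 ||
        (vsum[g] >= min_vesselness && shp[g] >= min_shape_index)
      if (ok) keep[vox] <- 1 else lac[vox] <- 1
    }
  }
  out <- image_volume(keep, candidates$spacing, "mask")
  attr(out, "lacune_candidates") <- image_volume(lac, candidates$spacing, "mask")
  attr(out, "component_vesselness") <- vsum
  attr(out, "component_shape_index") <- shp
  out
}
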