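#' Brain parenchymal fraction
#'
#' BPF = (GM volume + WM volume) / TIV with TIV = GM + WM + CSF volume.
#' Tissue volumes are probability-weighted voxel sums times the voxel volume
#' (the standard treatment for SPM-style probability maps); `binarize = TRUE`
#' counts voxels at or above 0.5 instead. BPF is a ratio of volumes, hence
#' invariant to isotropic rescaling of the voxel spacing.
#'
#' @param tissue_probs List of probability `image_volume`s `gm`, `wm`, `csf`.
#' @param binarize Use binarized (>= 0.5) maps instead of probability sums.
#' @return A `morphometry_summary` list: `gm_mm3`, `wm_mm3`, `csf_mm3`,
#'   `parenchymal_mm3`, `tiv_mm3`, `bpf`.
#' @export
bpf <- function(tissue_probs, binarize = FALSE) {
  assert_coregistered(tissue_probs[c("gm", "wm", "csf")])
  vv <- voxel_volume(tissue_probs$gm)
  vol <- function(p) {
    d <- p$data
    if (binarize) sum(d >= 0.5) * vv else sum(d) * vv
  }
  gm <- vol(tissue_probs$gm); wm <- vol(tissue_probs$wm)
  csf <- vol(tissue_probs$csf)
  tiv <- gm + wm + csf
  if (tiv <= 0) stop("TIV is zero: all tissue maps empty")
  structure(list(gm_mm3 = gm, wm_mm3 = wm, csf_mm3 = csf,
                 parenchymal_mm3 = gm + wm, tiv_mm3 = tiv,
                 bpf = (gm + wm) / tiv),
            class = "morphometry_summary")
}

#' @export
print.morphometry_summary <- function(x, ...) {
  cat(sprintf("<morphometry> BPF %.3f (parenchyma %.0f mm^3 / TIV %.0f mm^3)\n",
              x$bpf, x$parenchymal_mm3, x$tiv_mm3))
  invisible(x)
}

#' Volume of a binary mask in mm^3
#'
#' @param mask Binary mask `image_volume` (WMH masks and the like enter the
#'   models as volumes through this).
#' @return Voxel count times voxel volume, mm^3.
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "image_volume"))
  if (!all(mask$data %in% c(0, 1))) stop("mask_volume: non-binary input")
  sum(mask$data) * voxel_volume(mask)
}
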