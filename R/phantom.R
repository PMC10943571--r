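#' Configuration for the synthetic multimodal phantom
#'
#' The phantom emulates the inputs the segmentation pipeline consumes:
#' co-registered T1/T2 volumes with WM/GM/CSF contrast, tubular CSF-isointense
#' structures of sub-3-mm diameter (perivascular spaces), ovoid lacune-like
#' cavities with minor axis above 3 mm, WMH-like patches, and additive
#' Gaussian noise, together with exact ground-truth labels.
#'
#' Tissue layout is concentric (CSF shell, GM ribbon, WM core) rather than
#' anatomical: it is cheap, and the shell/ribbon interfaces exercise the same
#' boundary false-positive handling that sulci do in real data.
#'
#' @param grid Integer length-3 grid shape (default 128^3).
#' @param spacing Voxel size mm (default 1 mm isotropic).
#' @param t1_means,t2_means Named tissue mean intensities (WM, GM, CSF, WMH).
#'   Defaults give the conventional contrast: CSF darkest on T1, brightest on
#'   T2; WMH T2-bright but not CSF-like.
#' @param noise_sd Named per-modality additive Gaussian noise SD (T1, T2).
#' @param n_tubes Number of tubular ePVS-like objects (default 20).
#' @param tube_diameter_mm Diameter range, strictly below 3 mm by default.
#' @param tube_length_mm Centreline length range.
#' @param tube_step_sd_deg Angular jitter SD per 0.5 mm centreline step
#'   (bounded-curvature random walk).
#' @param n_ovoids Number of lacune-like ellipsoids (default 3).
#' @param ovoid_axes_mm Axis-diameter range; minimum above 3 mm by default so
#'   truth classes align with the STRIVE size rule.
#' @param n_wmh Number of WMH-like spherical patches.
#' @param wmh_radius_mm WMH radius range.
#' @param seed RNG seed (base R Mersenne-Twister); identical seeds give
#'   bit-identical phantoms.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(grid = c(128L, 128L, 128L),
                           spacing = c(1, 1, 1),
                           t1_means = c(WM = 600, GM = 450, CSF = 150, WMH = 540),
                           t2_means = c(WM = 300, GM = 400, CSF = 900, WMH = 550),
                           noise_sd = c(T1 = 15, T2 = 15),
                           n_tubes = 20L,
                           tube_diameter_mm = c(1.2, 2.4),
                           tube_length_mm = c(10, 22),
                           tube_step_sd_deg = 12,
                           n_ovoids = 3L,
                           ovoid_axes_mm = c(4, 6),
                           n_wmh = 2L,
                           wmh_radius_mm = c(3, 5),
                           seed = 42L) {
  stopifnot(length(grid) == 3L, all(grid >= 16),
            all(spacing > 0),
            all(c("WM", "GM", "CSF") %in% names(t1_means)),
            all(c("WM", "GM", "CSF") %in% names(t2_means)),
            tube_diameter_mm[1] <= tube_diameter_mm[2],
            ovoid_axes_mm[1] <= ovoid_axes_mm[2])
  structure(list(grid = as.integer(grid), spacing = as.numeric(spacing),
                 t1_means = t1_means, t2_means = t2_means,
                 noise_sd = noise_sd,
                 n_tubes = as.integer(n_tubes),
                 tube_diameter_mm = tube_diameter_mm,
                 tube_length_mm = tube_length_mm,
                 tube_step_sd_deg = tube_step_sd_deg,
                 n_ovoids = as.integer(n_ovoids),
                 ovoid_axes_mm = ovoid_axes_mm,
                 n_wmh = as.integer(n_wmh),
                 wmh_radius_mm = wmh_radius_mm,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Physical coordinates (mm) of all voxel centres, as three arrays.
voxel_coords <- function(grid, spacing) {
  list(x = (seq_len(grid[1]) - 0.5) * spacing[1],
       y = (seq_len(grid[2]) - 0.5) * spacing[2],
       z = (seq_len(grid[3]) - 0.5) * spacing[3])
}

# Random unit vector.
runif_dir <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# Bounded-curvature random-walk centreline: constant step, small angular
# perturbation per step, reflected back when approaching the WM boundary.
tube_centreline <- function(start, length_mm, step_mm, jitter_deg, centre, r_wm) {
  n_steps <- max(2L, ceiling(length_mm / step_mm))
  pts <- matrix(NA_real_, n_steps + 1L, 3L)
  pts[1, ] <- start
  dirv <- runif_dir()
  sd_rad <- jitter_deg * pi / 180
  for (i in seq_len(n_steps)) {
    dirv <- dirv + stats::rnorm(3, sd = sd_rad)
    dirv <- dirv / sqrt(sum(dirv^2))
    nxt <- pts[i, ] + dirv * step_mm
    # steer back towards the centre if leaving the safe WM core
    if (sqrt(sum(((nxt - centre) / r_wm)^2)) > 0.62) {
      inward <- (centre - pts[i, ])
      dirv <- inward / sqrt(sum(inward^2))
      nxt <- pts[i, ] + dirv * step_mm
    }
    pts[i + 1L, ] <- nxt
  }
  pts
}

# Voxels (linear indices) within radius_mm of a polyline sampled at pts.
rasterize_tube <- function(pts, radius_mm, grid, spacing) {
  lo <- pmax(floor((apply(pts, 2, min) - radius_mm) / spacing), 1)
  hi <- pmin(ceiling((apply(pts, 2, max) + radius_mm) / spacing) + 1, grid)
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  cx <- (ix - 0.5) * spacing[1]; cy <- (iy - 0.5) * spacing[2]; cz <- (iz - 0.5) * spacing[3]
  nb <- length(ix) * length(iy) * length(iz)
  mind2 <- rep(Inf, nb)
  gx <- rep(cx, times = length(iy) * length(iz))
  gy <- rep(rep(cy, each = length(ix)), times = length(iz))
  gz <- rep(cz, each = length(ix) * length(iy))
  for (i in seq_len(nrow(pts))) {
    d2 <- (gx - pts[i, 1])^2 + (gy - pts[i, 2])^2 + (gz - pts[i, 3])^2
    mind2 <- pmin(mind2, d2)
  }
  sel <- which(mind2 <= radius_mm^2)
  if (length(sel) == 0L) return(integer(0))
  b <- sel - 1L
  vx <- ix[b %% length(ix) + 1L]
  vy <- iy[(b %/% length(ix)) %% length(iy) + 1L]
  vz <- iz[b %/% (length(ix) * length(iy)) + 1L]
  vx + (vy - 1L) * grid[1] + (vz - 1L) * grid[1] * grid[2]
}

# Voxels within an axis-aligned ellipsoid (semi-axes mm).
rasterize_ellipsoid <- function(centre, semi_mm, grid, spacing) {
  lo <- pmax(floor((centre - semi_mm) / spacing), 1)
  hi <- pmin(ceiling((centre + semi_mm) / spacing) + 1, grid)
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  cx <- (ix - 0.5) * spacing[1]; cy <- (iy - 0.5) * spacing[2]; cz <- (iz - 0.5) * spacing[3]
  gx <- rep(cx, times = length(iy) * length(iz))
  gy <- rep(rep(cy, each = length(ix)), times = length(iz))
  gz <- rep(cz, each = length(ix) * length(iy))
  v <- ((gx - centre[1]) / semi_mm[1])^2 + ((gy - centre[2]) / semi_mm[2])^2 +
    ((gz - centre[3]) / semi_mm[3])^2
  sel <- which(v <= 1)
  if (length(sel) == 0L) return(integer(0))
  b <- sel - 1L
  vx <- ix[b %% length(ix) + 1L]
  vy <- iy[(b %/% length(ix)) %% length(iy) + 1L]
  vz <- iz[b %/% (length(ix) * length(iy)) + 1L]
  vx + (vy - 1L) * grid[1] + (vz - 1L) * grid[1] * grid[2]
}

#' Generate the synthetic multimodal phantom
#'
#' Builds co-registered T1/T2 volumes, crisp WM/GM/CSF probability maps and a
#' ground-truth label volume with one unique positive label per planted
#' object. Planted tube voxels take the configured CSF mean intensities
#' (plus noise), so with zero noise every tube voxel equals the CSF mean
#' exactly. Deterministic given `config$seed`.
#'
#' @param config A [phantom_config()].
#' @return List with elements `t1`, `t2` (`image_volume`), `tissue` (list of
#'   probability `image_volume`s `gm`, `wm`, `csf`), `truth` (list: `labels`
#'   label `image_volume`, `objects` data frame with columns id, class,
#'   diameter_mm, n_voxels, volume_mm3, and `centrelines` list of matrices),
#'   and `config`.
#' @export
generate_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  grid <- config$grid; spacing <- config$spacing
  vv <- prod(spacing)
  co <- voxel_coords(grid, spacing)
  centre <- grid * spacing / 2
  rmax <- centre - 2 * spacing  # ellipsoid radii of the head
  # normalized radial coordinate
  rx <- (co$x - centre[1]) / rmax[1]
  ry <- (co$y - centre[2]) / rmax[2]
  rz <- (co$z - centre[3]) / rmax[3]
  r2 <- outer(outer(rx^2, ry^2, `+`), rz^2, `+`)
  r <- sqrt(r2)
  wm <- r <= 0.70
  gm <- r > 0.70 & r <= 0.85
  csf <- r > 0.85 & r <= 1.0

  labels <- array(0L, dim = grid)
  t1 <- array(0, dim = grid)
  t2 <- array(0, dim = grid)
  t1[wm] <- config$t1_means[["WM"]]; t2[wm] <- config$t2_means[["WM"]]
  t1[gm] <- config$t1_means[["GM"]]; t2[gm] <- config$t2_means[["GM"]]
  t1[csf] <- config$t1_means[["CSF"]]; t2[csf] <- config$t2_means[["CSF"]]

  wm_idx <- which(wm & r < 0.60)  # interior margin for object seeding
  objects <- list()
  centrelines <- list()
  next_id <- 1L

  place <- function(rasterize_fn, max_tries = 50L) {
    for (try in seq_len(max_tries)) {
      res <- rasterize_fn()
      vox <- res$vox
      if (length(vox) >= 2L && all(wm[vox]) && all(labels[vox] == 0L)) {
        return(res)
      }
    }
    stop("could not place phantom object without overlap after ", max_tries,
         " retries; reduce object count or size")
  }

  step_mm <- 0.5
  for (i in seq_len(config$n_tubes)) {
    res <- place(function() {
      d <- stats::runif(1, config$tube_diameter_mm[1], config$tube_diameter_mm[2])
      len <- stats::runif(1, config$tube_length_mm[1], config$tube_length_mm[2])
      s <- wm_idx[sample.int(length(wm_idx), 1L)]
      s3 <- arrayInd(s, grid)
      start <- (as.numeric(s3) - 0.5) * spacing
      pts <- tube_centreline(start, len, step_mm, config$tube_step_sd_deg,
                             centre, rmax)
      list(vox = rasterize_tube(pts, d / 2, grid, spacing),
           diameter = d, pts = pts)
    })
    labels[res$vox] <- next_id
    t1[res$vox] <- config$t1_means[["CSF"]]
    t2[res$vox] <- config$t2_means[["CSF"]]
    objects[[next_id]] <- data.frame(id = next_id, class = "tube",
                                     diameter_mm = res$diameter,
                                     n_voxels = length(res$vox))
    centrelines[[next_id]] <- res$pts
    next_id <- next_id + 1L
  }

  for (i in seq_len(config$n_ovoids)) {
    res <- place(function() {
      ax <- stats::runif(3, config$ovoid_axes_mm[1], config$ovoid_axes_mm[2])
      s <- wm_idx[sample.int(length(wm_idx), 1L)]
      s3 <- arrayInd(s, grid)
      ctr <- (as.numeric(s3) - 0.5) * spacing
      list(vox = rasterize_ellipsoid(ctr, ax / 2, grid, spacing),
           diameter = min(ax), pts = matrix(ctr, 1L))
    })
    labels[res$vox] <- next_id
    t1[res$vox] <- config$t1_means[["CSF"]]
    t2[res$vox] <- config$t2_means[["CSF"]]
    objects[[next_id]] <- data.frame(id = next_id, class = "ovoid",
                                     diameter_mm = res$diameter,
                                     n_voxels = length(res$vox))
    centrelines[[next_id]] <- res$pts
    next_id <- next_id + 1L
  }

  for (i in seq_len(config$n_wmh)) {
    res <- place(function() {
      rad <- stats::runif(1, config$wmh_radius_mm[1], config$wmh_radius_mm[2])
      s <- wm_idx[sample.int(length(wm_idx), 1L)]
      s3 <- arrayInd(s, grid)
      ctr <- (as.numeric(s3) - 0.5) * spacing
      list(vox = rasterize_ellipsoid(ctr, rep(rad, 3), grid, spacing),
           diameter = 2 * rad, pts = matrix(ctr, 1L))
    })
    labels[res$vox] <- next_id
    t1[res$vox] <- config$t1_means[["WMH"]]
    t2[res$vox] <- config$t2_means[["WMH"]]
    objects[[next_id]] <- data.frame(id = next_id, class = "wmh",
                                     diameter_mm = res$diameter,
                                     n_voxels = length(res$vox))
    centrelines[[next_id]] <- res$pts
    next_id <- next_id + 1L
  }

  if (config$noise_sd[["T1"]] > 0) {
    t1 <- t1 + array(stats::rnorm(prod(grid), sd = config$noise_sd[["T1"]]), grid)
  }
  if (config$noise_sd[["T2"]] > 0) {
    t2 <- t2 + array(stats::rnorm(prod(grid), sd = config$noise_sd[["T2"]]), grid)
  }

  obj <- if (length(objects)) do.call(rbind, objects) else
    data.frame(id = integer(0), class = character(0), diameter_mm = numeric(0),
               n_voxels = integer(0))
  obj$volume_mm3 <- obj$n_voxels * vv

  list(
    t1 = image_volume(t1, spacing, "T1"),
    t2 = image_volume(t2, spacing, "T2"),
    tissue = list(
      gm = image_volume(array(as.numeric(gm), grid), spacing, "probability"),
      wm = image_volume(array(as.numeric(wm), grid), spacing, "probability"),
      csf = image_volume(array(as.numeric(csf), grid), spacing, "probability")
    ),
    truth = list(labels = image_volume(labels, spacing, "label"),
                 objects = obj, centrelines = centrelines),
    config = config
  )
}

#' Write a phantom set to disk
#'
#' NIfTI-1 volumes plus a truth-table CSV and a JSON sidecar recording the
#' full configuration (including the seed) for reproducibility.
#'
#' @param phantom Result of [generate_phantom()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(phantom$t1, file.path(dir, "t1.nii.gz"))
  write_volume(phantom$t2, file.path(dir, "t2.nii.gz"))
  write_volume(phantom$tissue$gm, file.path(dir, "gm_prob.nii.gz"))
  write_volume(phantom$tissue$wm, file.path(dir, "wm_prob.nii.gz"))
  write_volume(phantom$tissue$csf, file.path(dir, "csf_prob.nii.gz"))
  write_volume(phantom$truth$labels, file.path(dir, "truth_labels.nii.gz"))
  utils::write.csv(phantom$truth$objects, file.path(dir, "truth_objects.csv"),
                   row.names = FALSE)
  jsonlite::write_json(unclass(phantom$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
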