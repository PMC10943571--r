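# Low-level 3D array operators shared by the segmentation stages.
# All operate in voxel index space; callers convert to mm via spacing.

# Integer neighbourhood stencil: all nonzero voxel offsets whose physical
# length is <= linkage_mm under the given spacing.
stencil_offsets <- function(spacing, linkage_mm) {
  r <- pmax(1L, floor(linkage_mm / spacing))
  g <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
  d <- sqrt((g$dx * spacing[1])^2 + (g$dy * spacing[2])^2 + (g$dz * spacing[3])^2)
  keep <- d <= linkage_mm + 1e-9 & d > 0
  as.matrix(g[keep, , drop = FALSE])
}

# Connected components of a binary array under an arbitrary offset stencil.
# Iterative minimum-label propagation; converges in at most the longest
# within-component path length, which is small for the structures handled
# here. Returns idx (linear indices of foreground) and 1-based labels.
label_mask_components <- function(mask, offsets) {
  dims <- dim(mask)
  idx <- which(mask != 0)
  if (length(idx) == 0L) {
    return(list(idx = integer(0), labels = integer(0), n = 0L))
  }
  n1 <- dims[1]; n2 <- dims[2]; n3 <- dims[3]
  i0 <- idx - 1L
  x <- i0 %% n1
  y <- (i0 %/% n1) %% n2
  z <- i0 %/% (n1 * n2)
  pos <- integer(prod(dims))
  pos[idx] <- seq_along(idx)
  K <- nrow(offsets)
  nb <- matrix(0L, length(idx), K)
  for (k in seq_len(K)) {
    nx <- x + offsets[k, 1]; ny <- y + offsets[k, 2]; nz <- z + offsets[k, 3]
    ok <- nx >= 0 & nx < n1 & ny >= 0 & ny < n2 & nz >= 0 & nz < n3
    lin <- nx + ny * n1 + nz * (n1 * n2) + 1
    p <- integer(length(idx))
    p[ok] <- pos[lin[ok]]
    nb[, k] <- p
  }
  lab <- seq_along(idx)
  repeat {
    m <- lab
    for (k in seq_len(K)) {
      p <- nb[, k]
      has <- p > 0L
      m[has] <- pmin(m[has], lab[p[has]])
    }
    if (identical(m, lab)) break
    lab <- m
  }
  lab <- match(lab, sort(unique(lab)))
  list(idx = idx, labels = lab, n = max(lab))
}

offsets_26 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

# 1D lower-envelope squared distance transform (parabola envelope method)
# with physical sample spacing w. f holds squared distances; +Inf entries
# (no source on this line yet) contribute no parabola.
dt1d_sq <- function(f, w) {
  n <- length(f)
  fin <- which(is.finite(f))
  if (n == 1L || length(fin) == 0L) return(f)
  xs <- (seq_len(n) - 1) * w
  v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1] <- fin[1]; z[1] <- -Inf; z[2] <- Inf
  for (q in fin[-1]) {
    repeat {
      p <- v[k]
      s <- ((f[q] + xs[q]^2) - (f[p] + xs[p]^2)) / (2 * (xs[q] - xs[p]))
      if (k > 1L && s <= z[k]) k <- k - 1L else break
    }
    k <- k + 1L
    v[k] <- q; z[k] <- s; z[k + 1L] <- Inf
  }
  d <- numeric(n)
  j <- 1L
  for (q in seq_len(n)) {
    while (z[j + 1L] < xs[q]) j <- j + 1L
    p <- v[j]
    d[q] <- (xs[q] - xs[p])^2 + f[p]
  }
  d
}

# Squared Euclidean distance transform of a binary 3D array: for each
# foreground voxel, squared distance (mm^2) to the nearest background voxel
# centre. Anisotropic spacing supported; separable, three axis passes.
edt_sq <- function(mask, spacing) {
  dims <- dim(mask)
  d <- array(ifelse(mask != 0, Inf, 0), dim = dims)
  for (axis in 1:3) {
    w <- spacing[axis]
    perm <- c(axis, setdiff(1:3, axis))
    a <- aperm(d, perm)
    m <- matrix(a, nrow = dims[axis])
    for (j in seq_len(ncol(m))) {
      col <- m[, j]
      if (any(is.finite(col)) && any(col > 0)) m[, j] <- dt1d_sq(col, w)
    }
    d <- aperm(array(m, dim = dims[perm]), order(perm))
  }
  d
}

# Separable convolution along one axis with replicate (nearest) boundary,
# implemented as a banded-matrix multiply so BLAS does the work.
conv_axis <- function(a, kernel, axis) {
  dims <- dim(a)
  n <- dims[axis]
  r <- (length(kernel) - 1L) %/% 2L
  K <- matrix(0, n, n)
  i <- seq_len(n)
  for (o in -r:r) {
    j <- pmin(pmax(i + o, 1L), n)
    idx <- cbind(i, j)
    K[idx] <- K[idx] + kernel[o + r + 1L]
  }
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  out <- K %*% matrix(ap, nrow = n)
  aperm(array(out, dim = dims[perm]), order(perm))
}

gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox < 1e-3) return(1)
  r <- max(1L, ceiling(3 * sigma_vox))
  w <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  w / sum(w)
}

# Gaussian smoothing at one physical scale (mm); anisotropic voxels handled
# by per-axis sigma in voxel units.
gaussian_smooth <- function(a, sigma_mm, spacing) {
  for (axis in 1:3) {
    k <- gaussian_kernel_1d(sigma_mm / spacing[axis])
    if (length(k) > 1L) a <- conv_axis(a, k, axis)
  }
  a
}

# Shift an array by s voxels along axis with replicate boundary.
shift_axis <- function(a, s, axis) {
  dims <- dim(a)
  idx <- list(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]))
  idx[[axis]] <- pmin(pmax(idx[[axis]] + s, 1L), dims[axis])
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

deriv1 <- function(a, axis, h) (shift_axis(a, 1L, axis) - shift_axis(a, -1L, axis)) / (2 * h)
deriv2 <- function(a, axis, h) (shift_axis(a, 1L, axis) - 2 * a + shift_axis(a, -1L, axis)) / h^2

# Eigenvalues of a field of symmetric 3x3 matrices (vectorized analytic
# solution via the trigonometric method). Returns list(e1, e2, e3) with
# e1 >= e2 >= e3 elementwise.
sym3_eigenvalues <- function(a11, a12, a13, a22, a23, a33) {
  p1 <- a12^2 + a13^2 + a23^2
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  ok <- p > 1e-30
  ps <- ifelse(ok, p, 1)
  b11 <- (a11 - q) / ps; b22 <- (a22 - q) / ps; b33 <- (a33 - q) / ps
  b12 <- a12 / ps; b13 <- a13 / ps; b23 <- a23 / ps
  detb <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
    b13 * (b12 * b23 - b22 * b13)
  r <- pmin(pmax(detb / 2, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  e1[!ok] <- q[!ok]; e2[!ok] <- q[!ok]; e3[!ok] <- q[!ok]
  list(e1 = e1, e2 = e2, e3 = e3)
}
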