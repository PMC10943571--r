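#' In-memory 3D image volume
#'
#' Lightweight container for a 3D scalar grid with voxel spacing in mm and a
#' modality tag. All downstream operators (candidate detection, Hessian
#' filtering, clustering, volumetrics) consume this type; physical volumes are
#' always voxel count (or probability sum) times `prod(spacing)` mm^3.
#'
#' @param data Numeric 3D array.
#' @param spacing Numeric length-3, voxel size in mm per axis; all > 0.
#' @param modality One of `"T1"`, `"T2"`, `"probability"`, `"mask"`, `"label"`.
#' @return An object of class `image_volume`.
#' @details Modality-specific invariants are enforced: probability volumes must
#'   lie in \[0, 1\]; masks must be binary (0/1); label volumes must contain
#'   only non-negative integers.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1),
                         modality = c("T1", "T2", "probability", "mask", "label")) {
  modality <- match.arg(modality)
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("expected 3D volume")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be three positive finite values (mm)")
  }
  storage.mode(data) <- "double"
  if (modality == "probability") {
    rng <- range(data, na.rm = TRUE)
    if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9) {
      stop("probability volume must lie in [0, 1]")
    }
    data[] <- pmin(pmax(data, 0), 1)
  } else if (modality == "mask") {
    if (!all(data %in% c(0, 1))) stop("mask volume must be binary {0, 1}")
  } else if (modality == "label") {
    if (any(data < 0) || any(data != round(data))) {
      stop("label volume must contain non-negative integers")
    }
  }
  structure(list(data = data, spacing = spacing, modality = modality),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s  %s voxels @ %s mm\n", x$modality,
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' Voxel volume in mm^3
#' @param x An `image_volume` or a numeric spacing triple.
#' @return Scalar voxel volume, mm^3.
#' @export
voxel_volume <- function(x) {
  sp <- if (inherits(x, "image_volume")) x$spacing else as.numeric(x)
  prod(sp)
}

#' Read a NIfTI-1 volume
#'
#' Reads `.nii`/`.nii.gz`, reorients to the canonical RAS axis convention when
#' orientation metadata are present, and extracts voxel spacing from the
#' header. Fails on non-3D data or degenerate spacing rather than guessing.
#'
#' @param path Path to a NIfTI-1 file.
#' @param modality Modality tag to attach (see [image_volume()]).
#' @return An `image_volume`.
#' @export
read_volume <- function(path, modality = "T1") {
  if (!file.exists(path)) stop("unreadable file: ", path)
  img <- RNifti::readNifti(path)
  # Canonicalize axis order so neighbourhood/Hessian operators see one
  # convention regardless of on-disk storage order.
  ort <- tryCatch(RNifti::orientation(img), error = function(e) NULL)
  if (!is.null(ort) && nzchar(ort) && ort != "RAS") {
    RNifti::orientation(img) <- "RAS"
  }
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- img[, , , 1, drop = TRUE]
    d <- dim(img)
  }
  if (length(d) != 3L) stop("expected 3D volume, got ", length(d), "D")
  sp <- RNifti::pixdim(img)[seq_len(3)]
  if (any(!is.finite(sp)) || any(sp <= 0)) {
    stop("zero or negative voxel spacing in header")
  }
  image_volume(array(as.numeric(img), dim = d), spacing = sp,
               modality = modality)
}

#' Write an `image_volume` as NIfTI-1
#'
#' @param volume An `image_volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "image_volume"))
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Assert that volumes share one grid
#'
#' Registration itself is upstream of this package; this check enforces its
#' outcome: identical array shape and voxel spacing (within a relative
#' tolerance absorbing header rounding) across all supplied volumes.
#'
#' @param volumes List of `image_volume`s (length >= 2).
#' @param tol Relative spacing tolerance (default 1e-3).
#' @return Invisibly `TRUE`; stops on mismatch.
#' @export
assert_coregistered <- function(volumes, tol = 1e-3) {
  stopifnot(is.list(volumes), length(volumes) >= 2L)
  ref <- volumes[[1]]
  for (v in volumes[-1]) {
    if (!identical(dim(v$data), dim(ref$data))) {
      stop("co-registration failure: grid shape mismatch (",
           paste(dim(v$data), collapse = "x"), " vs ",
           paste(dim(ref$data), collapse = "x"), ")")
    }
    if (any(abs(v$spacing - ref$spacing) > tol * ref$spacing)) {
      stop("co-registration failure: voxel spacing mismatch beyond tolerance")
    }
  }
  invisible(TRUE)
}
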