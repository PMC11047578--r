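#' Binary voxel volume
#'
#' Container for a segmented vascular volume: a 3D logical array plus voxel
#' spacing (mm per axis) and the world coordinate (mm) of the centre of voxel
#' (1,1,1).  Voxel index `(i,j,k)` (1-based) maps to world position
#' `origin + (i-1, j-1, k-1) * spacing`.
#'
#' @param data 3D logical (or coercible) array; `TRUE` marks vessel voxels.
#' @param spacing numeric length-3, voxel edge lengths in mm (all > 0).
#' @param origin numeric length-3, world coordinate (mm) of voxel (1,1,1).
#' @return an object of class `voxel_volume`.
#' @examples
#' v <- voxel_volume(array(TRUE, c(3, 3, 3)), spacing = c(1, 1, 1))
#' dim(v$data)
#' @export
voxel_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array")
  storage.mode(data) <- "logical"
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive voxel edge lengths (mm)")
  if (length(origin) != 3L) stop("`origin` must have length 3")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat("voxel_volume:", paste(dim(x$data), collapse = " x "),
      "voxels, spacing", paste(signif(x$spacing, 4), collapse = " x "),
      "mm,", sum(x$data), "foreground\n")
  invisible(x)
}

#' Read a volume from file
#'
#' Accepts a NIfTI file (via the RNifti package, if installed) or a raw binary
#' volume accompanied by a JSON header `{"dim": [nx,ny,nz], "spacing": [...],
#' "origin": [...], "threshold": t}`.  NIfTI voxel dimensions become the
#' spacing; intensities are binarised at `threshold` (default > 0).
#'
#' @param path path to a `.nii`/`.nii.gz` file or to a raw `.bin` file whose
#'   header sits next to it as `<path>.json`.
#' @param threshold intensity threshold; voxels strictly above it are vessel.
#' @return a [voxel_volume()].
#' @export
read_volume <- function(path, threshold = 0) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("reading NIfTI volumes requires the RNifti package")
    img <- RNifti::readNifti(path)
    spacing <- attr(img, "pixdim")[1:3]
    voxel_volume(array(img > threshold, dim(img)), spacing = spacing)
  } else {
    hdr_path <- paste0(path, ".json")
    if (!file.exists(hdr_path)) stop("raw volume header not found: ", hdr_path)
    hdr <- jsonlite::read_json(hdr_path, simplifyVector = TRUE)
    n <- prod(hdr$dim)
    raw <- readBin(path, what = "numeric", n = n, size = 8)
    thr <- if (!is.null(hdr$threshold)) hdr$threshold else threshold
    voxel_volume(array(raw > thr, hdr$dim),
                 spacing = if (!is.null(hdr$spacing)) hdr$spacing else c(1, 1, 1),
                 origin = if (!is.null(hdr$origin)) hdr$origin else c(0, 0, 0))
  }
}

#' Count 26-connected foreground components of a volume
#'
#' @param volume a [voxel_volume()].
#' @param connectivity 26 (default) or 6.
#' @return integer component count.
#' @export
count_components <- function(volume, connectivity = 26) {
  stopifnot(inherits(volume, "voxel_volume"), connectivity %in% c(6, 26))
  .count_components_cpp(volume$data, dim(volume$data), as.integer(connectivity))
}

# world <-> index helpers (1-based indices at voxel centres)
voxel_to_world <- function(idx, volume) {
  sweep(sweep(idx - 1, 2, volume$spacing, "*"), 2, volume$origin, "+")
}

world_to_voxel <- function(pos, volume) {
  round(sweep(sweep(pos, 2, volume$origin, "-"), 2, volume$spacing, "/")) + 1
}
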