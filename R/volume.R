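#' 3D scalar image grid
#'
#' The basic unit of exchange for volumetric images: a 3D array with voxel
#' spacing and world origin. The first array axis is sagittal (left-right),
#' the second coronal, the third axial (slice axis). World coordinates are
#' `origin + (index - 1) * spacing` (0-based voxel index `index - 1`).
#'
#' @param data 3D numeric array.
#' @param spacing_mm voxel spacing per axis, mm (3 positive numbers).
#' @param origin_mm world origin, mm.
#' @param kind intensity flavour: `"HU"` (calibrated CT numbers) or
#'   `"normalized"` (values in \[0, 1\] after display windowing).
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(data, spacing_mm = c(0.5, 0.5, 0.625),
                        origin_mm = c(0, 0, 0),
                        kind = c("HU", "normalized")) {
  kind <- match.arg(kind)
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 positive numbers")
  if (kind == "normalized") {
    rng <- range(data)
    if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
      stop("normalized volume has values outside [0, 1]")
  }
  structure(list(data = data, spacing_mm = spacing_mm,
                 origin_mm = as.numeric(origin_mm), kind = kind),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_grid> %d x %d x %d voxels, spacing %s mm, %s\n",
              d[1], d[2], d[3],
              paste(format(x$spacing_mm, digits = 4), collapse = " x "),
              x$kind))
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$data)

#' Binary vessel (or region) mask aligned to a volume grid
#'
#' @param data 3D logical (or 0/1) array.
#' @param spacing_mm voxel spacing per axis, mm.
#' @return An object of class `vessel_mask` (a logical 3D array with a
#'   `spacing_mm` attribute).
#' @export
vessel_mask <- function(data, spacing_mm = c(0.5, 0.5, 0.625)) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array")
  m <- array(as.logical(data), dim(data))
  attr(m, "spacing_mm") <- as.numeric(spacing_mm)
  class(m) <- c("vessel_mask", class(m))
  m
}

mask_spacing <- function(m) attr(m, "spacing_mm")

#' Read a volume or mask from NIfTI
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param mask if `TRUE`, return a [vessel_mask()] (voxels > 0.5).
#' @param kind intensity flavour recorded on the returned [volume_grid()].
#' @return A `volume_grid` or `vessel_mask`.
#' @export
read_volume <- function(path, mask = FALSE, kind = "HU") {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  arr <- array(as.numeric(img), dim(img)[1:3])
  if (mask) return(vessel_mask(arr > 0.5, spacing_mm = sp))
  volume_grid(arr, spacing_mm = sp, kind = kind)
}

#' Write a volume or mask as NIfTI
#'
#' Voxel spacing is recorded in the header. Masks are written as uint8.
#'
#' @param x a [volume_grid()] or [vessel_mask()].
#' @param path output path (`.nii.gz` recommended).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "volume_grid")) {
    img <- RNifti::asNifti(x$data)
    RNifti::pixdim(img) <- x$spacing_mm
    RNifti::writeNifti(img, path)
  } else if (inherits(x, "vessel_mask")) {
    img <- RNifti::asNifti(array(as.integer(x), dim(x)))
    RNifti::pixdim(img) <- mask_spacing(x)
    RNifti::writeNifti(img, path, datatype = "uint8")
  } else {
    stop("`x` must be a volume_grid or vessel_mask")
  }
  invisible(path)
}
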