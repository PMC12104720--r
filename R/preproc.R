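#' Normalize a CT volume to a display window
#'
#' Maps the HU interval `[level - width/2, level + width/2]` linearly onto
#' \[0, 1\], clipping values outside. The defaults reproduce the uniform
#' annotation window of width 600 HU at level 100 HU, i.e. \[-200, 400\] HU.
#' Shape and spacing are preserved.
#'
#' @param vol a [volume_grid()] in HU.
#' @param level window level (center), HU.
#' @param width window width, HU; must be positive.
#' @return A [volume_grid()] of kind `"normalized"`.
#' @export
normalize_window <- function(vol, level = 100, width = 600) {
  stopifnot(inherits(vol, "volume_grid"))
  if (width <= 0) stop("window `width` must be positive")
  lo <- level - width / 2
  out <- pmin(pmax((vol$data - lo) / width, 0), 1)
  volume_grid(out, spacing_mm = vol$spacing_mm, origin_mm = vol$origin_mm,
              kind = "normalized")
}

#' Re-express a windowed volume in HU
#'
#' Inverse of [normalize_window()] on the non-clipped range.
#' @inheritParams normalize_window
#' @export
denormalize_window <- function(vol, level = 100, width = 600) {
  stopifnot(inherits(vol, "volume_grid"), vol$kind == "normalized")
  volume_grid(vol$data * width + (level - width / 2),
              spacing_mm = vol$spacing_mm, origin_mm = vol$origin_mm,
              kind = "HU")
}

# Apply a rigid motion (3 rotations rad, 3 translations voxel units) to the
# image content, resampling trilinearly. `theta` describes the motion of the
# content about the grid center; sampling uses its inverse.
apply_rigid <- function(arr, theta, spacing = c(1, 1, 1)) {
  dims <- dim(arr)
  ctr <- (dims + 1) / 2
  rx <- theta[1]; ry <- theta[2]; rz <- theta[3]
  Rx <- rbind(c(1, 0, 0), c(0, cos(rx), -sin(rx)), c(0, sin(rx), cos(rx)))
  Ry <- rbind(c(cos(ry), 0, sin(ry)), c(0, 1, 0), c(-sin(ry), 0, cos(ry)))
  Rz <- rbind(c(cos(rz), -sin(rz), 0), c(sin(rz), cos(rz), 0), c(0, 0, 1))
  R <- Rz %*% Ry %*% Rx
  g <- as.matrix(expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                             z = seq_len(dims[3])))
  # inverse mapping: source = c + Rinv %*% ((p - t - c) scaled), in mm space
  p <- sweep(g, 2, ctr + theta[4:6])
  p <- sweep(p, 2, spacing, `*`)
  src <- p %*% R  # R is orthonormal: %*% R == t(Rinv %*% t(p))
  src <- sweep(src, 2, spacing, `/`)
  src <- sweep(src, 2, ctr, `+`)
  trilinear_sample(arr, src)
}

# Vectorized trilinear sampling at continuous voxel coordinates (n x 3).
# Out-of-grid coordinates clamp to the boundary.
trilinear_sample <- function(arr, src) {
  dims <- dim(arr)
  cl <- function(v, n) pmin(pmax(v, 1), n)
  x <- cl(src[, 1], dims[1]); y <- cl(src[, 2], dims[2])
  z <- cl(src[, 3], dims[3])
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  x1 <- cl(x0 + 1, dims[1]); y1 <- cl(y0 + 1, dims[2]); z1 <- cl(z0 + 1, dims[3])
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  at <- function(i, j, k) arr[cbind(i, j, k)]
  v <- (1 - fx) * (1 - fy) * (1 - fz) * at(x0, y0, z0) +
    fx * (1 - fy) * (1 - fz) * at(x1, y0, z0) +
    (1 - fx) * fy * (1 - fz) * at(x0, y1, z0) +
    fx * fy * (1 - fz) * at(x1, y1, z0) +
    (1 - fx) * (1 - fy) * fz * at(x0, y0, z1) +
    fx * (1 - fy) * fz * at(x1, y0, z1) +
    (1 - fx) * fy * fz * at(x0, y1, z1) +
    fx * fy * fz * at(x1, y1, z1)
  array(v, dims)
}

mirror_sagittal <- function(arr) arr[dim(arr)[1]:1, , , drop = FALSE]

# Separable 3^3 box smoothing with edge replication; used to damp voxel
# noise before evaluating the mirror-correlation objective, so subvoxel
# interpolation smoothing cannot masquerade as symmetry improvement.
box_smooth3 <- function(arr) {
  for (ax in 1:3) {
    n <- dim(arr)[ax]
    lo <- c(1, seq_len(n - 1)); hi <- c(seq_len(n - 1) + 1, n)
    arr <- switch(ax,
      (arr[lo, , , drop = FALSE] + arr + arr[hi, , , drop = FALSE]) / 3,
      (arr[, lo, , drop = FALSE] + arr + arr[, hi, , drop = FALSE]) / 3,
      (arr[, , lo, drop = FALSE] + arr + arr[, , hi, drop = FALSE]) / 3)
  }
  arr
}

#' Align a volume to a midline-symmetric frame
#'
#' Hemisphere comparison only requires a consistent midsagittal plane, so
#' the registration target is the volume's own sagittal mirror image: the
#' rigid transform maximizing the Pearson correlation between the
#' transformed volume and its mirror is found by a coarse sagittal
#' translation search followed by Nelder-Mead refinement, and applied with
#' trilinear resampling.
#'
#' Only three of the six rigid parameters move the midsagittal plane
#' (sagittal translation and the rotations about the coronal and axial
#' axes); the remaining three commute with the mirror and are therefore
#' unidentifiable from this objective. They are fixed at zero (the
#' minimum-norm maximizer), so for a volume generated in the symmetric
#' frame the recovered transform is the identity. The objective is
#' evaluated on a box-smoothed copy of the volume and the identity is kept
#' unless the search improves the mirror correlation by more than
#' `min_gain`.
#'
#' @param vol a [volume_grid()].
#' @param max_shift_vox half-width of the coarse translation search, voxels.
#' @param maxit Nelder-Mead iteration budget.
#' @param min_gain minimum correlation improvement over the identity for a
#'   non-identity transform to be accepted.
#' @return A list of class `midline_alignment`: `volume` (aligned copy),
#'   `transform` (rx, ry, rz in radians; tx, ty, tz in voxels, the motion
#'   applied to the content), `correlation_before`, `correlation_after`.
#' @export
align_midline <- function(vol, max_shift_vox = 5L, maxit = 150L,
                          min_gain = 5e-3) {
  stopifnot(inherits(vol, "volume_grid"), dim(vol$data)[1] >= 2L)
  arr <- vol$data
  sp <- vol$spacing_mm
  sm <- box_smooth3(arr)
  expand <- function(p) c(0, p[1], p[2], p[3], 0, 0)  # (ry, rz, tx)
  obj <- function(p) {
    a <- apply_rigid(sm, expand(p), sp)
    s <- stats::cor(as.vector(a), as.vector(mirror_sagittal(a)))
    if (!is.finite(s)) -1 else s
  }
  id_obj <- obj(numeric(3))
  best <- numeric(3); best_obj <- id_obj
  for (t in setdiff(seq(-max_shift_vox, max_shift_vox), 0L)) {
    o <- obj(c(0, 0, t))
    if (o > best_obj) { best_obj <- o; best <- c(0, 0, t) }
  }
  fit <- stats::optim(best, function(p) -obj(p), method = "Nelder-Mead",
                      control = list(maxit = maxit,
                                     parscale = c(0.05, 0.05, 1)))
  if (-fit$value > best_obj) { best <- fit$par; best_obj <- -fit$value }
  if (best_obj <= id_obj + min_gain) { best <- numeric(3); best_obj <- id_obj }
  best <- expand(best)
  aligned <- if (all(best == 0)) arr else apply_rigid(arr, best, sp)
  structure(list(
    volume = volume_grid(aligned, spacing_mm = sp, origin_mm = vol$origin_mm,
                         kind = vol$kind),
    transform = stats::setNames(best, c("rx", "ry", "rz", "tx", "ty", "tz")),
    correlation_before = id_obj, correlation_after = best_obj),
    class = "midline_alignment")
}

#' @export
print.midline_alignment <- function(x, ...) {
  cat(sprintf(
    "<midline_alignment> mirror correlation %.4f -> %.4f\n  transform: %s\n",
    x$correlation_before, x$correlation_after,
    paste(sprintf("%s=%.4g", names(x$transform), x$transform),
          collapse = ", ")))
  invisible(x)
}

#' Partition a grid into left and right hemispheres
#'
#' Sagittal sheets strictly below the midline index go to the right
#' hemisphere and the remainder to the left (radiological convention: low
#' sagittal index = patient right). For an odd sagittal extent the single
#' midplane sheet at the midline index belongs to neither mask.
#'
#' @param vol_shape integer vector of 3 grid dimensions, or a
#'   [volume_grid()].
#' @param midline_plane_index 0-based sagittal split index; defaults to
#'   `extent / 2` (even extent) or `(extent - 1) / 2` (odd extent).
#' @return A list of class `hemisphere_partition`: logical arrays
#'   `left_mask` and `right_mask`, `midline_plane_index`, and the recorded
#'   `convention`.
#' @export
split_hemispheres <- function(vol_shape, midline_plane_index = NULL) {
  if (inherits(vol_shape, "volume_grid")) vol_shape <- dim(vol_shape$data)
  dims <- as.integer(vol_shape)
  stopifnot(length(dims) == 3L)
  nx <- dims[1]
  midline <- midline_plane_index %||% (if (nx %% 2L == 0L) nx / 2 else (nx - 1) / 2)
  if (midline <= 0 || midline >= nx)
    stop("midline index must lie strictly inside the sagittal extent")
  i0 <- seq_len(nx) - 1L  # 0-based sheet indices
  right_sheets <- i0 < midline
  left_sheets <- if (nx %% 2L == 1L) i0 > midline else i0 >= midline
  sheet_mask <- function(sel) {
    m <- array(FALSE, dims)
    m[sel, , ] <- TRUE
    m
  }
  structure(list(left_mask = sheet_mask(left_sheets),
                 right_mask = sheet_mask(right_sheets),
                 midline_plane_index = midline,
                 convention = "radiological: low sagittal index = right"),
            class = "hemisphere_partition")
}
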