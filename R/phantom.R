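#' Specification of a synthetic cerebrovascular phantom
#'
#' Describes one CTA-like head phantom: a pair of mirror-related vascular
#' trees (one per hemisphere) inside fixed half-ellipsoid MCA-territory
#' masks, with a controlled affected-to-healthy vessel-volume ratio. The
#' phantoms stand in for clinical CTA volumes with expert vessel
#' annotations: the generator returns the ground-truth masks that manual
#' tracing would provide.
#'
#' The affected-hemisphere tree is derived from the healthy tree by
#' mirroring its centerlines across the midsagittal plane and shrinking the
#' vessel radii by a global scale factor chosen so the voxel-volume ratio of
#' the two ground-truth trees hits `true_ratio`; at `true_ratio = 1` the
#' affected tree is exactly the mirrored healthy tree.
#'
#' @param grid_shape voxels per axis, sagittal x coronal x axial; all >= 16.
#' @param spacing_mm voxel spacing, mm. The default axial spacing of
#'   0.625 mm matches thin-slice CTA acquisition with no slice interval.
#' @param n_branches number of side branches per hemisphere tree.
#' @param radius_range_mm min/max vessel radius along the tree, mm.
#' @param tortuosity waviness of the centerline random walk (>= 0; 0 gives
#'   straight branches).
#' @param true_ratio target affected/healthy vessel-volume ratio in
#'   \[0, 1.5\].
#' @param affected_side `"left"` or `"right"` (the clinically known
#'   stroke side).
#' @param vessel_hu_range contrast-filled vessel intensity interval, HU.
#' @param background_hu mean parenchyma intensity, HU.
#' @param noise_sd_hu SD of additive Gaussian background noise, HU.
#' @param seed integer RNG seed; generation is a pure function of the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(48L, 48L, 24L),
                         spacing_mm = c(0.5, 0.5, 0.625),
                         n_branches = 6L,
                         radius_range_mm = c(0.8, 2.0),
                         tortuosity = 0.3,
                         true_ratio = 1.0,
                         affected_side = c("left", "right"),
                         vessel_hu_range = c(150, 450),
                         background_hu = 35,
                         noise_sd_hu = 10,
                         seed = 1L) {
  affected_side <- match.arg(affected_side)
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 16L),
            length(spacing_mm) == 3L, all(spacing_mm > 0),
            n_branches >= 0L,
            length(radius_range_mm) == 2L,
            radius_range_mm[1] <= radius_range_mm[2],
            radius_range_mm[1] > 0,
            tortuosity >= 0, noise_sd_hu >= 0,
            true_ratio >= 0, true_ratio <= 1.5,
            vessel_hu_range[1] <= vessel_hu_range[2])
  structure(list(grid_shape = grid_shape, spacing_mm = as.numeric(spacing_mm),
                 n_branches = as.integer(n_branches),
                 radius_range_mm = as.numeric(radius_range_mm),
                 tortuosity = tortuosity, true_ratio = true_ratio,
                 affected_side = affected_side,
                 vessel_hu_range = as.numeric(vessel_hu_range),
                 background_hu = background_hu, noise_sd_hu = noise_sd_hu,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Fixed, mirror-symmetric half-ellipsoid territory masks. The right mask is
# the exact sagittal mirror of the left one, so a symmetric tree yields a
# volume ratio of exactly 1.
territory_masks <- function(grid_shape) {
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  mid <- (nx + 1) / 2
  cx <- mid + 0.26 * nx; cy <- (ny + 1) / 2; cz <- (nz + 1) / 2
  ax <- 0.23 * nx; ay <- 0.40 * ny; az <- 0.44 * nz
  xi <- ((seq_len(nx) - cx) / ax)^2
  yi <- ((seq_len(ny) - cy) / ay)^2
  zi <- ((seq_len(nz) - cz) / az)^2
  e <- outer(outer(xi, yi, `+`), zi, `+`) <= 1
  left <- e & (slice.index(e, 1) > mid)
  right <- left[nx:1, , ]
  list(left = left, right = right, midline = mid)
}

# Random branching tube tree for one hemisphere, grown inside the left
# territory ellipsoid (callers mirror as needed). Positions are continuous
# voxel coordinates; radii in mm. Consumes the current RNG stream.
grow_tree <- function(spec) {
  dims <- spec$grid_shape; sp <- spec$spacing_mm
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  mid <- (nx + 1) / 2
  cx <- mid + 0.26 * nx; cy <- (ny + 1) / 2; cz <- (nz + 1) / 2
  az <- 0.44 * nz
  step <- 0.6 * min(sp)
  r_min <- spec$radius_range_mm[1]; r_max <- spec$radius_range_mm[2]

  walk <- function(pos, dir, n_steps, r0, r1) {
    pts <- matrix(NA_real_, n_steps, 3)
    dirs <- matrix(NA_real_, n_steps, 3)
    for (i in seq_len(n_steps)) {
      dir <- dir + spec$tortuosity * rnorm(3) * c(1, 1, 0.5)
      # gentle pull toward the territory axis keeps branches inside
      pull <- c(cx - pos[1], cy - pos[2], 0) * sp
      pull_n <- sqrt(sum(pull^2))
      if (pull_n > 1e-9) dir <- dir + 0.05 * pull / pull_n
      dir <- dir / sqrt(sum(dir^2))
      pos <- pos + step * dir / sp
      pts[i, ] <- pos
      dirs[i, ] <- dir
    }
    list(pts = pts, dirs = dirs,
         radii = seq(r0, r1, length.out = n_steps))
  }

  trunk_steps <- max(8L, as.integer(round(1.5 * az * sp[3] / step)))
  root <- c(cx, cy, cz - 0.6 * az)
  branches <- list(walk(root, c(0, 0, 1), trunk_steps, r_max, r_min))
  for (b in seq_len(spec$n_branches)) {
    parent <- branches[[sample.int(length(branches), 1)]]
    np <- nrow(parent$pts)
    at <- max(1L, as.integer(round(runif(1, 0.2, 0.9) * np)))
    dir0 <- parent$dirs[at, ] + rnorm(3) * 0.8 +
      c(runif(1, -0.5, 0.5), runif(1, -0.5, 0.5), 0.3)
    dir0 <- dir0 / sqrt(sum(dir0^2))
    len <- max(4L, as.integer(round(runif(1, 0.35, 0.75) * (np - at + 1))))
    r0 <- max(r_min, 0.7 * parent$radii[at])
    branches[[length(branches) + 1L]] <-
      walk(parent$pts[at, ], dir0, len, r0, max(0.8 * r_min, 0.3))
  }
  pts <- do.call(rbind, lapply(branches, `[[`, "pts"))
  radii <- unlist(lapply(branches, `[[`, "radii"))
  list(pts = pts, radii = radii)
}

# Per-voxel min over tree points of (distance in mm) / (point radius in mm).
# A voxel belongs to the tree scaled by radius factor s iff D <= s, so voxel
# counts are monotone in s and ratio control reduces to an order statistic.
distance_ratio_field <- function(pts, radii, dims, sp, support = 3) {
  D <- array(Inf, dims)
  for (k in seq_len(nrow(pts))) {
    p <- pts[k, ]; r <- radii[k]
    half <- support * r / sp
    i0 <- pmax(1, ceiling(p - half)); i1 <- pmin(dims, floor(p + half))
    if (any(i0 > i1)) next
    ii <- i0[1]:i1[1]; jj <- i0[2]:i1[2]; kk <- i0[3]:i1[3]
    dx2 <- ((ii - p[1]) * sp[1])^2
    dy2 <- ((jj - p[2]) * sp[2])^2
    dz2 <- ((kk - p[3]) * sp[3])^2
    d <- sqrt(outer(outer(dx2, dy2, `+`), dz2, `+`)) / r
    cur <- D[ii, jj, kk]
    D[ii, jj, kk] <- pmin(cur, d)
  }
  D
}

#' Generate one synthetic CTA phantom
#'
#' Deterministic for a fixed spec (including its seed): two calls with the
#' same spec return bit-identical volumes and masks. The realized
#' affected/healthy voxel-volume ratio is controlled to within +/- 2
#' percentage points (on the x100 scale) of `spec$true_ratio`, and equals
#' 1 exactly in the mirror-symmetric case `true_ratio = 1`.
#'
#' @param spec a [phantom_spec()].
#' @param case_id identifier recorded on the case.
#' @return An object of class `phantom_case`: fields `volume` (a
#'   [volume_grid()] in HU), `gt_vessels`, `territory_left`,
#'   `territory_right` (each a [vessel_mask()]), `realized_ratio`,
#'   `affected_side`, `case_id`, `spec`.
#' @export
generate_phantom <- function(spec, case_id = "case") {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$grid_shape; sp <- spec$spacing_mm
  terr <- territory_masks(dims)
  healthy_side <- if (spec$affected_side == "left") "right" else "left"
  terr_aff <- terr[[spec$affected_side]]
  terr_heal <- terr[[healthy_side]]

  res <- with_seed(spec$seed, {
    # the tree template grows in the left half; mirror it to whichever
    # hemisphere is healthy
    tree <- grow_tree(spec)
    nx <- dims[1]
    if (healthy_side == "right") tree$pts[, 1] <- (nx + 1) - tree$pts[, 1]
    Dh <- distance_ratio_field(tree$pts, tree$radii, dims, sp)
    H <- (Dh <= 1) & terr_heal
    nH <- sum(H)
    if (nH == 0L)
      stop("phantom generation failed: no healthy-hemisphere vessel voxel ",
           "could be placed at this grid resolution")
    if (spec$true_ratio == 1) {
      A <- H[dims[1]:1, , ]
      realized <- 1
    } else {
      mir <- tree
      mir$pts[, 1] <- (nx + 1) - mir$pts[, 1]
      Da <- distance_ratio_field(mir$pts, mir$radii, dims, sp)
      vals <- Da[terr_aff]
      m <- as.integer(round(spec$true_ratio * nH))
      if (m > sum(is.finite(vals)))
        stop(sprintf(paste0(
          "phantom generation failed: target ratio %.3f needs %d affected ",
          "voxels but only %d are reachable at this resolution"),
          spec$true_ratio, m, sum(is.finite(vals))))
      if (m == 0L) {
        A <- array(FALSE, dims)
      } else {
        s <- sort(vals, partial = m)[m]
        A <- (Da <= s) & terr_aff
      }
      realized <- sum(A) / nH
      if (abs(realized - spec$true_ratio) > 0.02)
        stop(sprintf(paste0(
          "phantom generation failed: realized ratio %.4f misses target ",
          "%.4f by more than 2 percentage points"), realized,
          spec$true_ratio))
    }
    gt <- H | A
    vol <- array(rnorm(prod(dims), spec$background_hu, spec$noise_sd_hu),
                 dims)
    nv <- sum(gt)
    vol[gt] <- runif(nv, spec$vessel_hu_range[1], spec$vessel_hu_range[2])
    list(gt = gt, realized = realized, vol = vol)
  })

  structure(list(
    volume = volume_grid(res$vol, spacing_mm = sp, kind = "HU"),
    gt_vessels = vessel_mask(res$gt, spacing_mm = sp),
    territory_left = vessel_mask(terr$left, spacing_mm = sp),
    territory_right = vessel_mask(terr$right, spacing_mm = sp),
    realized_ratio = res$realized,
    affected_side = spec$affected_side,
    case_id = case_id,
    spec = spec), class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf(
    "<phantom_case %s> affected %s, realized ratio %.4f (target %.4f), %d vessel voxels\n",
    x$case_id, x$affected_side, x$realized_ratio, x$spec$true_ratio,
    sum(x$gt_vessels)))
  invisible(x)
}

quaternary_ratio_intervals <- function(thresholds = grade_thresholds(),
                                       max_ratio = 1.2) {
  cuts <- c(0, thresholds$quaternary_cuts / 100, max_ratio)
  cbind(lo = cuts[-length(cuts)], hi = cuts[-1])
}

#' Generate a seeded phantom cohort
#'
#' Stands in for a clinical cohort: per-case seeds are derived reproducibly
#' from the master seed, so the same call regenerates bit-identical cases.
#'
#' @param n_cases number of phantoms (>= 1).
#' @param ratio_sampler how true ratios are drawn: `"uniform"` (uniform on
#'   `ratio_range`), `"stratified"` (round-robin over the four quaternary
#'   grade intervals, uniform within each), or a numeric vector of
#'   `n_cases` ratios.
#' @param base_spec a [phantom_spec()] providing all other parameters.
#' @param seed master seed.
#' @param ratio_range range for the uniform sampler.
#' @param dir if non-`NULL`, volumes/masks are written there as NIfTI and
#'   the manifest gains file-path columns.
#' @return An object of class `phantom_cohort`: `cases` (list of
#'   [generate_phantom()] results) and `manifest` (data frame with columns
#'   `case_id, true_ratio, realized_ratio, affected_side, seed` plus file
#'   paths when `dir` is given).
#' @export
generate_cohort <- function(n_cases, ratio_sampler = "uniform",
                            base_spec = phantom_spec(), seed = 1L,
                            ratio_range = c(0, 1.2), dir = NULL) {
  stopifnot(n_cases >= 1L)
  if (is.numeric(ratio_sampler)) {
    stopifnot(length(ratio_sampler) == n_cases)
    ratios <- as.numeric(ratio_sampler)
    sides <- with_seed(seed, sample(c("left", "right"), n_cases,
                                    replace = TRUE))
  } else if (identical(ratio_sampler, "uniform")) {
    ratios <- with_seed(seed, runif(n_cases, ratio_range[1], ratio_range[2]))
    sides <- with_seed(seed + 1L, sample(c("left", "right"), n_cases,
                                         replace = TRUE))
  } else if (identical(ratio_sampler, "stratified")) {
    iv <- quaternary_ratio_intervals(max_ratio = max(ratio_range))
    if (n_cases < nrow(iv))
      stop(sprintf("stratified sampling needs >= %d cases (one per grade interval)",
                   nrow(iv)))
    which_iv <- rep_len(seq_len(nrow(iv)), n_cases)
    ratios <- with_seed(seed, runif(n_cases, iv[which_iv, "lo"],
                                    iv[which_iv, "hi"]))
    sides <- with_seed(seed + 1L, sample(c("left", "right"), n_cases,
                                         replace = TRUE))
  } else {
    stop("unknown ratio_sampler")
  }
  case_seeds <- derive_seeds(seed + 2L, n_cases)
  ids <- sprintf("case_%03d", seq_len(n_cases))

  cases <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    sp_i <- base_spec
    sp_i$true_ratio <- ratios[i]
    sp_i$affected_side <- sides[i]
    sp_i$seed <- case_seeds[i]
    cases[[i]] <- generate_phantom(sp_i, case_id = ids[i])
  }
  manifest <- data.frame(
    case_id = ids, true_ratio = ratios,
    realized_ratio = vapply(cases, `[[`, numeric(1), "realized_ratio"),
    affected_side = sides, seed = case_seeds,
    stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- lapply(seq_len(n_cases), function(i) {
      p <- list(
        volume_path = file.path(dir, paste0(ids[i], "_cta.nii.gz")),
        mask_path = file.path(dir, paste0(ids[i], "_vessels.nii.gz")),
        territory_left_path = file.path(dir, paste0(ids[i], "_terr_L.nii.gz")),
        territory_right_path = file.path(dir, paste0(ids[i], "_terr_R.nii.gz")))
      write_volume(cases[[i]]$volume, p$volume_path)
      write_volume(cases[[i]]$gt_vessels, p$mask_path)
      write_volume(cases[[i]]$territory_left, p$territory_left_path)
      write_volume(cases[[i]]$territory_right, p$territory_right_path)
      p
    })
    for (col in names(paths[[1]]))
      manifest[[col]] <- vapply(paths, `[[`, character(1), col)
    manifest <- manifest[, c("case_id", "true_ratio", "realized_ratio",
                             "affected_side", "volume_path", "mask_path",
                             "territory_left_path", "territory_right_path",
                             "seed")]
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  structure(list(cases = cases, manifest = manifest),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d cases, ratios %.3f-%.3f\n",
              nrow(x$manifest), min(x$manifest$true_ratio),
              max(x$manifest$true_ratio)))
  invisible(x)
}

#' Extract paired axial image/mask slices from phantom cases
#'
#' The annotation and training unit is the axial slice. Every axial slice
#' intersecting the territory masks is emitted exactly once, including
#' slices whose vessel mask is empty; the slice-to-case mapping is kept so
#' cross-validation can split by case, never by slice.
#'
#' @param cases list of [generate_phantom()] cases (or a `phantom_cohort`).
#' @param plane only `"axial"` is supported.
#' @return An object of class `slice_dataset`: parallel lists `images`
#'   (HU matrices) and `masks` (logical matrices) plus vectors `case_id`
#'   and `z` (axial index).
#' @export
slice_dataset <- function(cases, plane = "axial") {
  if (inherits(cases, "phantom_cohort")) cases <- cases$cases
  stopifnot(length(cases) > 0L, identical(plane, "axial"))
  images <- list(); masks <- list(); case_id <- character(); z <- integer()
  for (cs in cases) {
    terr <- cs$territory_left | cs$territory_right
    zs <- which(apply(terr, 3, any))
    for (zz in zs) {
      images[[length(images) + 1L]] <- cs$volume$data[, , zz]
      masks[[length(masks) + 1L]] <- unclass(cs$gt_vessels)[, , zz]
      case_id <- c(case_id, cs$case_id)
      z <- c(z, zz)
    }
  }
  structure(list(images = images, masks = masks, case_id = case_id, z = z),
            class = "slice_dataset")
}
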