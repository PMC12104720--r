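#' Collateral grading thresholds
#'
#' Critical cutoffs on the quantitative collateral score (qCS, percent):
#' 5 / 49 / 95 for the binary and quaternary schemes (a refinement of the
#' nominal 0 / 50 / 100 four-grade cuts) and 5 / 25 / 49 / 75 / 95 for the
#' six-class scheme. All interval upper ends are closed: a qCS exactly at a
#' cutoff takes the lower grade.
#'
#' @param floor lowest cutoff, percent.
#' @param binary poor/good cutoff, percent (`qcs <= binary` is poor).
#' @param ceiling highest cutoff, percent.
#' @param six_class_cuts the five cutoffs of the six-class scheme.
#' @return An object of class `grade_thresholds`.
#' @export
grade_thresholds <- function(floor = 5, binary = 49, ceiling = 95,
                             six_class_cuts = c(5, 25, 49, 75, 95)) {
  quaternary <- c(floor, binary, ceiling)
  if (any(diff(quaternary) <= 0) || any(diff(six_class_cuts) <= 0))
    stop("thresholds must be strictly increasing")
  if (any(c(quaternary, six_class_cuts) < 0) ||
      any(c(quaternary, six_class_cuts) > 100))
    stop("thresholds must lie in [0, 100]")
  structure(list(floor = floor, binary = binary, ceiling = ceiling,
                 quaternary_cuts = quaternary,
                 six_class_cuts = as.numeric(six_class_cuts)),
            class = "grade_thresholds")
}

#' Vessel volume inside a territory
#'
#' @param mask a [vessel_mask()] (segmented vessels).
#' @param territory a region mask of the same shape.
#' @param spacing_mm voxel spacing; taken from `mask` if omitted.
#' @return Volume in mm^3: voxel count of `mask & territory` times the
#'   voxel volume.
#' @export
territory_volume <- function(mask, territory, spacing_mm = NULL) {
  if (!all(dim(mask) == dim(territory)))
    stop("mask and territory shapes differ")
  spacing_mm <- spacing_mm %||% mask_spacing(mask) %||% c(1, 1, 1)
  sum(mask & territory) * prod(spacing_mm)
}

#' Quantitative collateral score
#'
#' `qCS(%) = 100 * V_affected / V_healthy`, the percentage of vessel volume
#' in the affected-hemisphere MCA territory relative to the healthy side.
#' The score is non-negative and may exceed 100. A healthy-side volume of
#' zero makes the score undefined and raises an explicit degenerate-case
#' error (never infinity or a silent zero).
#'
#' @param v_affected_mm3,v_healthy_mm3 vessel volumes, mm^3 (>= 0).
#' @param affected_side which hemisphere is affected (clinical input).
#' @param case_id optional identifier carried into error messages.
#' @return An object of class `qcs_result`.
#' @export
compute_qcs <- function(v_affected_mm3, v_healthy_mm3,
                        affected_side = c("left", "right"),
                        case_id = NULL) {
  affected_side <- match.arg(affected_side)
  stopifnot(v_affected_mm3 >= 0, v_healthy_mm3 >= 0)
  if (v_healthy_mm3 == 0)
    stop_degenerate("healthy-hemisphere vessel volume is zero; qCS undefined",
                    case_id)
  structure(list(v_affected_mm3 = v_affected_mm3,
                 v_healthy_mm3 = v_healthy_mm3,
                 qcs_percent = 100 * v_affected_mm3 / v_healthy_mm3,
                 affected_side = affected_side, case_id = case_id),
            class = "qcs_result")
}

#' @export
print.qcs_result <- function(x, ...) {
  cat(sprintf(
    "<qcs_result%s> qCS = %.2f%% (affected %s: %.2f mm^3, healthy: %.2f mm^3)\n",
    if (is.null(x$case_id)) "" else paste0(" ", x$case_id),
    x$qcs_percent, x$affected_side, x$v_affected_mm3, x$v_healthy_mm3))
  if (!is.null(x$grade))
    cat(sprintf("  grades: binary %s, quaternary %d, six-class %d (source: %s)\n",
                x$grade$binary, x$grade$quaternary, x$grade$six_class,
                x$territory_source %||% "unknown"))
  invisible(x)
}

#' Grade a quantitative collateral score
#'
#' Interval membership with closed upper ends: binary poor iff
#' `qcs <= 49`; quaternary 0: `qcs <= 5`, 1: `5 < qcs <= 49`, 2:
#' `49 < qcs <= 95`, 3: `qcs > 95`; six-class analogously over
#' 5/25/49/75/95. The three schemes are mutually consistent at the shared
#' 49 cut: binary good, quaternary >= 2 and six-class >= 3 coincide.
#'
#' @param qcs_percent numeric vector of scores (>= 0).
#' @param thresholds a [grade_thresholds()].
#' @return A data frame of class `collateral_grade` with columns `qcs`,
#'   `binary` ("poor"/"good"), `quaternary` (0-3), `six_class` (0-5).
#' @export
classify_qcs <- function(qcs_percent, thresholds = grade_thresholds()) {
  stopifnot(all(qcs_percent >= 0))
  quater <- rowSums(outer(qcs_percent, thresholds$quaternary_cuts, `>`))
  six <- rowSums(outer(qcs_percent, thresholds$six_class_cuts, `>`))
  out <- data.frame(qcs = qcs_percent,
                    binary = ifelse(qcs_percent > thresholds$binary,
                                    "good", "poor"),
                    quaternary = as.integer(quater),
                    six_class = as.integer(six),
                    stringsAsFactors = FALSE)
  class(out) <- c("collateral_grade", class(out))
  out
}

#' Quantify one case: volumes, qCS and grades
#'
#' Composes [territory_volume()], [compute_qcs()] and [classify_qcs()].
#' Explicit MCA-territory masks take precedence; without them the
#' whole-hemisphere partition from [split_hemispheres()] is the fallback,
#' and the source used is recorded in the output.
#'
#' @param mask segmented [vessel_mask()].
#' @param affected_side `"left"` or `"right"` (clinical input, never
#'   inferred from the image).
#' @param territories optional list with `left` and `right` region masks.
#' @param spacing_mm voxel spacing; taken from `mask` if omitted.
#' @param thresholds a [grade_thresholds()].
#' @param case_id optional identifier.
#' @return A `qcs_result` with `grade` (one-row [classify_qcs()] frame) and
#'   `territory_source` fields added.
#' @export
quantify_case <- function(mask, affected_side, territories = NULL,
                          spacing_mm = NULL, thresholds = grade_thresholds(),
                          case_id = NULL) {
  affected_side <- match.arg(affected_side, c("left", "right"))
  if (is.null(territories)) {
    part <- split_hemispheres(dim(mask))
    territories <- list(left = part$left_mask, right = part$right_mask)
    source <- "hemisphere_partition"
  } else {
    stopifnot(all(c("left", "right") %in% names(territories)))
    source <- "explicit_territories"
  }
  spacing_mm <- spacing_mm %||% mask_spacing(mask) %||% c(1, 1, 1)
  healthy_side <- if (affected_side == "left") "right" else "left"
  v_aff <- territory_volume(mask, territories[[affected_side]], spacing_mm)
  v_heal <- territory_volume(mask, territories[[healthy_side]], spacing_mm)
  res <- compute_qcs(v_aff, v_heal, affected_side, case_id = case_id)
  res$grade <- classify_qcs(res$qcs_percent, thresholds)
  res$territory_source <- source
  res
}

boundary_candidates <- function(nominal, half_window, step) {
  seq(max(0, nominal - half_window), nominal + half_window, by = step)
}

#' Threshold refinement sweep
#'
#' Starting from nominal grade cutoffs (0, 50 and 100 by default), each
#' boundary is swept in 1-percentage-point increments across a 10-point
#' window (clipped at 0 below; candidates above 100 are allowed since qCS
#' can exceed 100). Each candidate dichotomizes the scores (positive iff
#' `qcs > candidate`, matching the grading rule) and is scored against the
#' reference labels for that boundary by accuracy, with ties broken by
#' sensitivity + specificity and then by proximity to the nominal value.
#' The full candidate tables are always returned so the selection rule can
#' be re-examined.
#'
#' @param qcs_values numeric vector of per-case scores.
#' @param labels reference labels: either binary (logical, 0/1, or
#'   "poor"/"good") applied to every boundary, or ordinal grades 0..K whose
#'   boundary `i` dichotomizes as `label >= i`.
#' @param nominal nominal thresholds to refine.
#' @param half_window half-width of each candidate window, percentage
#'   points.
#' @param step candidate spacing, percentage points.
#' @return An object of class `sweep_result`: `tables` (one data frame of
#'   candidates and metrics per boundary), `chosen` (named vector of
#'   selected thresholds), `skipped` (boundaries without both reference
#'   classes).
#' @export
sweep_thresholds <- function(qcs_values, labels, nominal = c(0, 50, 100),
                             half_window = 5, step = 1) {
  stopifnot(length(qcs_values) == length(labels), length(qcs_values) >= 2L)
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    stopifnot(all(labels %in% c("poor", "good")))
    labels <- as.integer(labels == "good")
    ordinal <- FALSE
  } else if (is.logical(labels)) {
    labels <- as.integer(labels)
    ordinal <- FALSE
  } else {
    labels <- as.integer(labels)
    ordinal <- length(unique(labels)) > 2L || max(labels) > 1L
  }
  tables <- list(); chosen <- numeric(0); skipped <- numeric(0)
  for (i in seq_along(nominal)) {
    t_nom <- nominal[i]
    ref <- if (ordinal) as.integer(labels >= i) else labels
    if (length(unique(ref)) < 2L) {
      warning(sprintf(
        "boundary at nominal %g%% skipped: reference labels single-class",
        t_nom))
      skipped <- c(skipped, t_nom)
      next
    }
    cands <- boundary_candidates(t_nom, half_window, step)
    tab <- do.call(rbind, lapply(cands, function(cc) {
      pred <- as.integer(qcs_values > cc)
      tp <- sum(pred == 1 & ref == 1); tn <- sum(pred == 0 & ref == 0)
      fp <- sum(pred == 1 & ref == 0); fn <- sum(pred == 0 & ref == 1)
      data.frame(candidate = cc,
                 accuracy = (tp + tn) / length(ref),
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp))
    }))
    ord <- order(-tab$accuracy, -(tab$sensitivity + tab$specificity),
                 abs(tab$candidate - t_nom), tab$candidate)
    chosen[as.character(t_nom)] <- tab$candidate[ord[1]]
    tables[[as.character(t_nom)]] <- tab
  }
  structure(list(tables = tables, chosen = chosen, skipped = skipped,
                 nominal = nominal),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result>\n")
  if (length(x$chosen))
    cat(sprintf("  nominal %s%% -> chosen %s%%\n", names(x$chosen),
                format(x$chosen)), sep = "")
  if (length(x$skipped))
    cat("  skipped boundaries:", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}
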