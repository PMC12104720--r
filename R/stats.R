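# Agreement and classification statistics. Degenerate inputs yield NA
# tagged with a reason (attribute "undefined"), never a silent 0.

flag_undefined <- function(reason) {
  structure(NA_real_, undefined = reason)
}

#' Dice similarity coefficient
#'
#' `2|A intersect B| / (|A| + |B|)`. Two empty masks are in perfect
#' agreement on absence, so their Dice is defined as 1 (conventions differ;
#' the case is flagged via the `"note"` attribute).
#'
#' @param a,b binary masks (any shape, must match).
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("mask shapes differ")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0)
    return(structure(1, note = "both masks empty; Dice defined as 1"))
  2 * sum(a & b) / (sa + sb)
}

#' Confusion matrix over an ordered class vocabulary
#'
#' Rows are reference labels, columns predictions. Classes absent from the
#' data keep their zero row/column.
#'
#' @param reference,predicted equal-length label vectors.
#' @param vocabulary ordered class labels; defaults to the sorted union.
#' @return A K x K integer matrix with `reference`/`prediction` dimnames.
#' @export
confusion <- function(reference, predicted,
                      vocabulary = sort(unique(c(reference, predicted)))) {
  stopifnot(length(reference) == length(predicted))
  bad <- setdiff(unique(c(reference, predicted)), vocabulary)
  if (length(bad))
    stop("labels outside vocabulary: ", paste(bad, collapse = ", "))
  rf <- factor(reference, levels = vocabulary)
  pf <- factor(predicted, levels = vocabulary)
  cm <- table(reference = rf, prediction = pf)
  m <- matrix(as.integer(cm), nrow = length(vocabulary),
              dimnames = list(reference = vocabulary,
                              prediction = vocabulary))
  m
}

#' Binary classification metrics from a 2x2 confusion matrix
#'
#' Standard definitions with the positive class given explicitly (good
#' collateral status is the positive class throughout the package). Any
#' metric with a zero denominator is reported as `NA` flagged with the
#' reason, never coerced to 0.
#'
#' @param cm 2x2 confusion matrix from [confusion()].
#' @param positive label of the positive class; defaults to the second
#'   vocabulary entry.
#' @return List with `accuracy`, `precision`, `f1`, `sensitivity`,
#'   `specificity`, `mcc`, the counts, and `undefined` (names of flagged
#'   metrics).
#' @export
binary_metrics <- function(cm, positive = colnames(cm)[2]) {
  stopifnot(all(dim(cm) == c(2L, 2L)))
  stopifnot(positive %in% colnames(cm))
  neg <- setdiff(colnames(cm), positive)
  tp <- cm[positive, positive]; tn <- cm[neg, neg]
  fp <- cm[neg, positive]; fn <- cm[positive, neg]
  n <- tp + tn + fp + fn
  safe <- function(num, den, what) {
    if (den == 0) flag_undefined(paste0(what, ": zero denominator"))
    else num / den
  }
  sens <- safe(tp, tp + fn, "sensitivity")
  spec <- safe(tn, tn + fp, "specificity")
  prec <- safe(tp, tp + fp, "precision")
  f1 <- if (is.na(prec) || is.na(sens)) {
    flag_undefined("f1: undefined precision or sensitivity")
  } else if (prec + sens == 0) {
    flag_undefined("f1: zero precision + sensitivity")
  } else 2 * prec * sens / (prec + sens)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) {
    flag_undefined("mcc: a marginal is zero")
  } else (tp * tn - fp * fn) / mcc_den
  out <- list(accuracy = safe(tp + tn, n, "accuracy"),
              precision = prec, f1 = f1, sensitivity = sens,
              specificity = spec, mcc = mcc,
              tp = tp, tn = tn, fp = fp, fn = fn)
  out$undefined <- names(which(vapply(
    out[c("accuracy", "precision", "f1", "sensitivity", "specificity",
          "mcc")], is.na, logical(1))))
  out
}

#' Multi-class accuracy
#' @param cm K x K confusion matrix (K >= 2).
#' @export
multiclass_accuracy <- function(cm) {
  stopifnot(nrow(cm) == ncol(cm), nrow(cm) >= 2L)
  if (sum(cm) == 0) stop("empty confusion matrix")
  sum(diag(cm)) / sum(cm)
}

#' Per-class recall (sensitivity of one class)
#' @param cm K x K confusion matrix.
#' @param class class label (row name).
#' @export
per_class_recall <- function(cm, class) {
  stopifnot(class %in% rownames(cm))
  rs <- sum(cm[class, ])
  if (rs == 0) return(flag_undefined("recall: class absent from reference"))
  cm[class, class] / rs
}

#' Rank-based ROC AUC with a normal-approximation CI
#'
#' The Mann-Whitney formulation: the probability that a random positive
#' case scores above a random negative one, with ties counting one half.
#' Equivalent to trapezoidal integration of the ROC curve. The confidence
#' interval uses the Hanley-McNeil standard error; the p-value tests
#' AUC = 0.5.
#'
#' @param scores continuous scores (the qCS feeds this in the pipeline).
#' @param labels binary reference (logical, 0/1 or two-level factor).
#' @param conf_level confidence level.
#' @return List with `auc`, `ci`, `se`, `p`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, conf_level = 0.95) {
  labels <- if (is.factor(labels)) as.integer(labels) - 1L else as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present for ROC analysis")
  r <- rank(scores)  # midranks: ties contribute 1/2
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci <- c(max(0, auc - z * se), min(1, auc + z * se))
  p <- if (se == 0) as.numeric(auc != 0.5) * 0 else
    2 * pnorm(-abs(auc - 0.5) / se)
  list(auc = auc, ci = ci, se = se, p = p, n_pos = n1, n_neg = n0)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties averaged), with the t
#' approximation for the p-value. Zero rank variance in either variable is
#' flagged as undefined.
#'
#' @param x,y numeric vectors, length >= 3.
#' @return List with `rho`, `p`, `n`.
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3L)
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    return(list(rho = flag_undefined("zero rank variance"), p = NA_real_,
                n = n))
  rho <- cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Intraclass correlation ICC(2,1): two-way random, absolute agreement,
#' single measure
#'
#' From the two-way ANOVA decomposition of an n-targets x k-raters matrix:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`, where MSR,
#' MSC and MSE are the mean squares for rows (targets), columns (raters)
#' and residual error. The confidence interval follows the F-based method
#' for this form; the p-value tests ICC = 0 via `F = MSR / MSE`.
#'
#' @param ratings complete numeric matrix, n targets (rows) x k raters
#'   (columns), n >= 2 and k >= 2.
#' @param conf_level confidence level.
#' @return List with `icc`, `ci`, `p`, `n`, `k`, `msr`, `msc`, `mse`.
#' @export
icc21 <- function(ratings, conf_level = 0.95) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  stopifnot(n >= 2L, k >= 2L)
  if (anyNA(ratings)) stop("ratings matrix must be complete")
  m <- mean(ratings)
  ri <- rowMeans(ratings); cj <- colMeans(ratings)
  msr <- k * sum((ri - m)^2) / (n - 1)
  msc <- n * sum((cj - m)^2) / (k - 1)
  sse <- sum((ratings - outer(ri, rep(1, k)) -
                outer(rep(1, n), cj) + m)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (denom <= 0 || (msr == 0 && mse == 0))
    return(list(icc = flag_undefined("zero between-target variance"),
                ci = c(NA_real_, NA_real_), p = NA_real_, n = n, k = k,
                msr = msr, msc = msc, mse = mse))
  icc <- (msr - mse) / denom
  alpha <- 1 - conf_level
  if (mse == 0) {
    ci <- c(icc, icc)
    p <- 0
  } else {
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- qf(1 - alpha / 2, n - 1, v)
    f_u <- qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    ci <- c(lower, upper)
    p <- pf(msr / mse, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  }
  list(icc = icc, ci = ci, p = p, n = n, k = k,
       msr = msr, msc = msc, mse = mse)
}

#' Assemble an evaluation report
#'
#' Bundles segmentation, classification, discrimination and agreement
#' statistics for one comparison (e.g. model vs ground truth).
#'
#' @param dsc_mean mean per-case Dice.
#' @param cm binary confusion matrix (or `NULL`).
#' @param auc [roc_auc()] result (or `NULL`).
#' @param spearman [spearman_cor()] result (or `NULL`).
#' @param icc [icc21()] result (or `NULL`).
#' @param n number of cases.
#' @param multiclass_cm optional K-class confusion matrix.
#' @return An object of class `metrics_report`.
#' @export
metrics_report <- function(dsc_mean = NULL, cm = NULL, auc = NULL,
                           spearman = NULL, icc = NULL, n = NULL,
                           multiclass_cm = NULL) {
  bm <- if (!is.null(cm)) binary_metrics(cm) else NULL
  structure(list(
    dsc_mean = dsc_mean, confusion = cm, binary = bm,
    multiclass = multiclass_cm,
    multiclass_accuracy = if (!is.null(multiclass_cm))
      multiclass_accuracy(multiclass_cm) else NULL,
    auc = auc, spearman = spearman, icc = icc, n = n),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  cat("<metrics_report>", if (!is.null(x$n)) sprintf("n = %d", x$n), "\n")
  fm <- function(v) formatC(v, digits = digits, format = "f")
  if (!is.null(x$dsc_mean)) cat("  mean DSC:", fm(x$dsc_mean), "\n")
  if (!is.null(x$binary))
    cat(sprintf("  binary: acc %s, F1 %s, sens %s, spec %s, MCC %s\n",
                fm(x$binary$accuracy), fm(x$binary$f1),
                fm(x$binary$sensitivity), fm(x$binary$specificity),
                fm(x$binary$mcc)))
  if (!is.null(x$multiclass_accuracy))
    cat("  multi-class accuracy:", fm(x$multiclass_accuracy), "\n")
  if (!is.null(x$auc))
    cat(sprintf("  AUC %s (%s-%s), p = %.3g\n", fm(x$auc$auc),
                fm(x$auc$ci[1]), fm(x$auc$ci[2]), x$auc$p))
  if (!is.null(x$spearman))
    cat(sprintf("  Spearman rho %s, p = %.3g\n", fm(x$spearman$rho),
                x$spearman$p))
  if (!is.null(x$icc))
    cat(sprintf("  ICC(2,1) %s (%s-%s), p = %.3g\n", fm(x$icc$icc),
                fm(x$icc$ci[1]), fm(x$icc$ci[2]), x$icc$p))
  invisible(x)
}
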