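# Independent brute-force oracles: definitional formulas, explicit ANOVA
# sums and pair enumeration, written without reference to the package
# implementations they check.

lexico_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

# Exhaustive threshold-sweep oracle for one boundary.
sweep_oracle <- function(qcs, ref01, t_nom, half = 5, step = 1) {
  cands <- seq(max(0, t_nom - half), t_nom + half, by = step)
  best <- NULL
  rows <- list()
  for (cc in cands) {
    pred <- ifelse(qcs > cc, 1L, 0L)
    tp <- 0; tn <- 0; fp <- 0; fn <- 0
    for (i in seq_along(qcs)) {
      if (pred[i] == 1 && ref01[i] == 1) tp <- tp + 1
      if (pred[i] == 0 && ref01[i] == 0) tn <- tn + 1
      if (pred[i] == 1 && ref01[i] == 0) fp <- fp + 1
      if (pred[i] == 0 && ref01[i] == 1) fn <- fn + 1
    }
    acc <- (tp + tn) / length(qcs)
    sens <- tp / (tp + fn); spec <- tn / (tn + fp)
    rows[[length(rows) + 1L]] <- c(cc, acc, sens, spec)
    key <- c(-acc, -(sens + spec), abs(cc - t_nom), cc)
    if (is.null(best) || lexico_less(key, best$key))
      best <- list(cand = cc, key = key)
  }
  list(chosen = best$cand, table = do.call(rbind, rows))
}

oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

oracle_mcc <- function(tp, tn, fp, fn) {
  (tp * tn - fp * fn) /
    sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
}

oracle_f1 <- function(tp, tn, fp, fn) {
  prec <- tp / (tp + fp); sens <- tp / (tp + fn)
  2 * prec * sens / (prec + sens)
}

oracle_icc21 <- function(x) {
  n <- nrow(x); k <- ncol(x); m <- mean(x)
  msr <- k * sum((rowMeans(x) - m)^2) / (n - 1)
  msc <- n * sum((colMeans(x) - m)^2) / (k - 1)
  sse <- 0
  for (i in 1:n) for (j in 1:k)
    sse <- sse + (x[i, j] - rowMeans(x)[i] - colMeans(x)[j] + m)^2
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# Spearman via the classical d^2 formula on tie-free data, mid-rank Pearson
# otherwise.
oracle_spearman <- function(x, y) {
  n <- length(x)
  if (!anyDuplicated(x) && !anyDuplicated(y)) {
    d <- rank(x) - rank(y)
    1 - 6 * sum(d^2) / (n * (n^2 - 1))
  } else {
    rx <- rank(x); ry <- rank(y)
    sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  }
}

oracle_dice <- function(a, b) {
  av <- as.logical(a); bv <- as.logical(b)
  if (sum(av) + sum(bv) == 0) return(1)
  2 * sum(av & bv) / (sum(av) + sum(bv))
}
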