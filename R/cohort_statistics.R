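# Rank-based group comparison, rank correlation and ROC/Youden
# threshold selection.

#' Wilcoxon rank-sum test
#'
#' Two-sample rank-sum test on mid-ranks. For small samples
#' (n_x + n_y <= 12) the two-tailed p-value is computed by exact
#' enumeration of all rank assignments (valid under ties, where the
#' classical null tables are not); larger samples use the tie-corrected
#' normal approximation with continuity correction. Identical pooled
#' values give p = 1.
#'
#' @param x,y Numeric samples, both non-empty.
#' @param exact_max Total sample size at or below which enumeration is
#'   used (default 12).
#' @return List with \code{statistic} (rank sum of \code{x}), \code{p},
#'   and \code{method}.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 12) {
  stopifnot(length(x) >= 1L, length(y) >= 1L,
            all(is.finite(x)), all(is.finite(y)))
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  ew <- nx * (n + 1) / 2
  if (n <= exact_max) {
    idx <- utils::combn(n, nx)
    ws <- colSums(matrix(r[idx], nrow = nx))
    p <- mean(abs(ws - ew) >= abs(w - ew) - 1e-9)
    return(list(statistic = w, p = p, method = "exact-enumeration"))
  }
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  v <- nx * ny / 12 * ((n + 1) - tie_term)
  if (v <= 0)
    return(list(statistic = w, p = 1, method = "degenerate"))
  d <- w - ew
  z <- (d - sign(d) * 0.5) / sqrt(v)
  list(statistic = w, p = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal-approximation")
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks under ties), via
#' \code{stats::cor}. Zero rank variance in either argument is an
#' error (the correlation is undefined).
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return The correlation in [-1, 1].
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0)
    stop("Spearman correlation undefined: zero variance in ranks")
  stats::cor(x, y, method = "spearman")
}

#' Confusion-matrix metrics
#'
#' Standard ratios from a 2x2 confusion table. Ratios with a zero
#' denominator are returned as NA with a warning rather than silently
#' coerced to 0.
#'
#' @param tp,fp,tn,fn Nonnegative counts, total > 0.
#' @return List with \code{sensitivity}, \code{specificity}, \code{ppv},
#'   \code{npv}, \code{accuracy}.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  stopifnot(all(counts >= 0), sum(counts) > 0)
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator)")
      return(NA_real_)
    }
    num / den
  }
  list(sensitivity = ratio(tp, tp + fn, "sensitivity"),
       specificity = ratio(tn, tn + fp, "specificity"),
       ppv = ratio(tp, tp + fp, "PPV"),
       npv = ratio(tn, tn + fn, "NPV"),
       accuracy = (tp + tn) / sum(counts))
}

#' ROC analysis with Youden-optimal threshold
#'
#' Scans classification thresholds at the midpoints between consecutive
#' distinct scores plus -Inf and +Inf; a patient is predicted a
#' responder when the score is at or above the threshold (higher Lambda
#' or mu is expected to mean more favorable response — no automatic
#' orientation flip). The operating threshold maximizes Youden's
#' J = sensitivity + specificity - 1, ties broken toward the smallest
#' threshold (favoring sensitivity). AUC is the tie-adjusted
#' Mann-Whitney statistic.
#'
#' @param scores Numeric predictor values.
#' @param labels Logical (TRUE = favorable/responder) or character
#'   \code{"favorable"}/\code{"unfavorable"}.
#' @return An object of class \code{"roc_result"}: list with
#'   \code{thresholds}, \code{sensitivity}, \code{specificity} (per
#'   threshold), \code{youden_threshold}, \code{youden_j}, \code{auc},
#'   and the confusion metrics at the chosen threshold.
#' @export
roc_with_youden <- function(scores, labels) {
  if (is.character(labels)) labels <- labels == "favorable"
  stopifnot(is.logical(labels), length(scores) == length(labels),
            all(is.finite(scores)))
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0L || nneg == 0L)
    stop("both classes must be present for ROC analysis")
  s <- sort(unique(scores))
  thresholds <- c(-Inf, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, Inf)
  sens <- spec <- numeric(length(thresholds))
  for (i in seq_along(thresholds)) {
    pred <- scores >= thresholds[i]
    sens[i] <- sum(pred & labels) / npos
    spec[i] <- sum(!pred & !labels) / nneg
  }
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)[1]  # thresholds ascending: first = smallest
  thr <- thresholds[best]
  pred <- scores >= thr
  cm <- confusion_metrics(tp = sum(pred & labels),
                          fp = sum(pred & !labels),
                          tn = sum(!pred & !labels),
                          fn = sum(!pred & labels))
  r <- rank(scores)
  auc <- (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
  structure(list(thresholds = thresholds, sensitivity = sens,
                 specificity = spec, youden_threshold = thr,
                 youden_j = j[best], auc = auc, at_youden = cm),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "ROC: AUC = %.3f; Youden threshold = %g (J = %.3f)\n",
    x$auc, x$youden_threshold, x$youden_j))
  cat(sprintf(
    "  sens %.3f, spec %.3f, acc %.3f, PPV %.3f, NPV %.3f\n",
    x$at_youden$sensitivity, x$at_youden$specificity,
    x$at_youden$accuracy, x$at_youden$ppv, x$at_youden$npv))
  invisible(x)
}
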