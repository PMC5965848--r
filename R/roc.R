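#' Empirical ROC curve
#'
#' Sweeps the decision threshold over the distinct score values (plus a
#' degenerate call-nothing endpoint) and records sensitivity and
#' specificity at each. With `direction = "lower"` (the default for
#' uptake-change scores, where responders show the deeper decline) a case
#' is called positive when `score <= threshold`; with `"higher"`, when
#' `score >= threshold`.
#'
#' @param score numeric scores (e.g. percent change in SUVmax).
#' @param is_responder logical, `TRUE` for positives.
#' @param direction `"lower"` (lower score calls positive) or `"higher"`.
#' @return data.frame of class `roc_points` with columns `threshold`,
#'   `sensitivity`, `specificity`; attributes `n_pos`, `n_neg`,
#'   `direction`.
#' @export
roc_curve <- function(score, is_responder,
                      direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  if (length(score) != length(is_responder))
    stop("'score' and 'is_responder' must have equal length")
  if (any(!is.finite(score))) stop("scores must be finite")
  is_responder <- as.logical(is_responder)
  n_pos <- sum(is_responder)
  n_neg <- sum(!is_responder)
  if (n_pos == 0L || n_neg == 0L)
    stop("need at least one responder and one non-responder (got ",
         n_pos, " / ", n_neg, ")")
  thr <- sort(unique(score))
  if (direction == "lower") {
    ends <- -Inf
    called <- function(t) score <= t
  } else {
    thr <- rev(thr)
    ends <- Inf
    called <- function(t) score >= t
  }
  thr <- c(ends, thr)
  sens <- spec <- numeric(length(thr))
  for (i in seq_along(thr)) {
    pos <- called(thr[i])
    sens[i] <- sum(pos & is_responder) / n_pos
    spec[i] <- sum(!pos & !is_responder) / n_neg
  }
  out <- data.frame(threshold = thr, sensitivity = sens,
                    specificity = spec)
  attr(out, "n_pos") <- n_pos
  attr(out, "n_neg") <- n_neg
  attr(out, "direction") <- direction
  attr(out, "scores") <- sort(unique(score))
  class(out) <- c("roc_points", "data.frame")
  out
}

#' Area under the ROC curve (trapezoid)
#'
#' Trapezoidal integration of the empirical curve in (1 - specificity,
#' sensitivity) space. On every instance this equals the Mann-Whitney
#' statistic: the fraction of responder/non-responder pairs whose scores
#' are correctly ordered, counting ties as one half.
#'
#' @param points an `roc_points` data.frame from [roc_curve()].
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(points) {
  stopifnot(inherits(points, "roc_points"))
  fpr <- 1 - points$specificity
  tpr <- points$sensitivity
  ord <- order(fpr, tpr)
  fpr <- c(0, fpr[ord], 1)
  tpr <- c(0, tpr[ord], 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# AUC straight from scores (used in the permutation loop)
.auc_of <- function(score, is_responder, direction) {
  roc_auc(roc_curve(score, is_responder, direction))
}

#' Permutation p-value for AUC against chance
#'
#' Two-sided test of the observed AUC against 0.5 by permuting the
#' responder labels over the animals. When the number of distinct
#' labelings `choose(n, n_pos)` is small enough they are fully enumerated
#' (an exact test); otherwise a seeded Monte-Carlo sample of permutations
#' is used with the add-one estimator.
#'
#' @param score,is_responder,direction as in [roc_curve()].
#' @param max_enumerate largest number of labelings enumerated exactly.
#' @param n_mc Monte-Carlo draws beyond that.
#' @param seed RNG seed for the Monte-Carlo branch.
#' @return list with `p_value`, `method` (`"exact"` or `"monte-carlo"`),
#'   `n_permutations`.
#' @export
roc_pvalue <- function(score, is_responder, direction = "lower",
                       max_enumerate = 1e5, n_mc = 2e4, seed = 1L) {
  is_responder <- as.logical(is_responder)
  n <- length(score)
  n_pos <- sum(is_responder)
  obs <- abs(.auc_of(score, is_responder, direction) - 0.5)
  tol <- 1e-12
  if (choose(n, n_pos) <= max_enumerate) {
    combos <- utils::combn(n, n_pos)
    stat <- apply(combos, 2, function(ix) {
      lab <- logical(n); lab[ix] <- TRUE
      abs(.auc_of(score, lab, direction) - 0.5)
    })
    list(p_value = mean(stat >= obs - tol), method = "exact",
         n_permutations = ncol(combos))
  } else {
    set.seed(as.integer(seed %% .Machine$integer.max))
    hits <- 0L
    for (b in seq_len(n_mc)) {
      lab <- logical(n)
      lab[sample.int(n, n_pos)] <- TRUE
      if (abs(.auc_of(score, lab, direction) - 0.5) >= obs - tol)
        hits <- hits + 1L
    }
    list(p_value = (hits + 1) / (n_mc + 1), method = "monte-carlo",
         n_permutations = n_mc)
  }
}

#' Youden-optimal operating cutoff
#'
#' Picks the threshold maximizing the Youden index
#' `J = sensitivity + specificity - 1`. Ties are broken toward higher
#' sensitivity, then toward the more negative threshold. The reported
#' cutoff is the midpoint between the two adjacent distinct scores
#' straddling the chosen threshold, so any value in that open interval
#' yields the same operating point.
#'
#' @param points an `roc_points` data.frame from [roc_curve()].
#' @return list with `cutoff` (midpoint), `threshold` (datum value),
#'   `sensitivity`, `specificity`, `youden`.
#' @export
optimal_cutoff <- function(points) {
  stopifnot(inherits(points, "roc_points"))
  J <- points$sensitivity + points$specificity - 1
  ord <- order(-J, -points$sensitivity, points$threshold)
  best <- ord[1]
  t <- points$threshold[best]
  sc <- attr(points, "scores")
  dirn <- attr(points, "direction")
  cutoff <- if (dirn == "lower") {
    above <- sc[sc > t]
    if (is.infinite(t)) min(sc)
    else if (length(above)) (t + min(above)) / 2 else t
  } else {
    below <- sc[sc < t]
    if (is.infinite(t)) max(sc)
    else if (length(below)) (t + max(below)) / 2 else t
  }
  list(cutoff = cutoff, threshold = t,
       sensitivity = points$sensitivity[best],
       specificity = points$specificity[best],
       youden = J[best])
}

#' Responder-discrimination ROC analysis
#'
#' The full analysis for one score: empirical ROC curve, trapezoidal AUC,
#' permutation p-value against chance, and Youden-optimal cutoff with its
#' sensitivity and specificity.
#'
#' @inheritParams roc_curve
#' @param seed RNG seed for the Monte-Carlo p-value branch (the exact
#'   branch ignores it).
#' @return An object of class `pet_roc`.
#' @export
#' @examples
#' sc <- c(-90, -80, -70, -40, -10, 0, 30)
#' resp <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
#' r <- roc_analysis(sc, resp)
#' r
roc_analysis <- function(score, is_responder,
                         direction = c("lower", "higher"), seed = 1L) {
  direction <- match.arg(direction)
  pts <- roc_curve(score, is_responder, direction)
  pv <- roc_pvalue(score, is_responder, direction, seed = seed)
  structure(list(points = pts,
                 auc = roc_auc(pts),
                 p_value = pv$p_value, p_method = pv$method,
                 n_permutations = pv$n_permutations,
                 optimal = optimal_cutoff(pts),
                 n_pos = attr(pts, "n_pos"), n_neg = attr(pts, "n_neg"),
                 direction = direction),
            class = "pet_roc")
}

#' @export
print.pet_roc <- function(x, ...) {
  cat("ROC analysis (", x$n_pos, " responders vs ", x$n_neg,
      " non-responders, ", x$direction, " score calls positive)\n",
      sep = "")
  cat(sprintf("  AUC = %.3f, p = %.4g (%s permutation, %d labelings)\n",
              x$auc, x$p_value, x$p_method, x$n_permutations))
  cat(sprintf(paste0("  optimal cutoff %.4g (Youden J = %.3f): ",
                     "sensitivity %.0f%%, specificity %.0f%%\n"),
              x$optimal$cutoff, x$optimal$youden,
              100 * x$optimal$sensitivity, 100 * x$optimal$specificity))
  invisible(x)
}

#' @export
plot.pet_roc <- function(x, ...) {
  fpr <- 1 - x$points$specificity
  tpr <- x$points$sensitivity
  ord <- order(fpr, tpr)
  graphics::plot(c(0, fpr[ord], 1), c(0, tpr[ord], 1), type = "b",
                 pch = 19, xlab = "1 - specificity",
                 ylab = "sensitivity",
                 main = sprintf("AUC = %.3f (p = %.3g)", x$auc, x$p_value),
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  op <- x$optimal
  graphics::points(1 - op$specificity, op$sensitivity, col = "red",
                   pch = 1, cex = 2)
  invisible(x)
}
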