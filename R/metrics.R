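# Confusion-matrix rates, ROC/AUC, score-separation tests, RMSD and the
# screening-report percentages.

#' Confusion counts
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  v <- c(TP = tp, FP = fp, TN = tn, FN = fn)
  if (any(v < 0) || any(v != floor(v))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  if (sum(v) == 0) stop("confusion counts must not all be zero", call. = FALSE)
  structure(as.list(v), class = "confusion_counts")
}

#' Classification rates from confusion counts
#'
#' `TPR = TP / (TP + FN)`, `FPR = FP / (FP + TN)`,
#' `ACC = (TP + TN) / (TP + TN + FP + FN)` — exact ratios, no smoothing.
#'
#' @param counts A [confusion_counts()].
#' @return Named list with `TPR`, `FPR`, `ACC`.
#' @examples
#' rates(confusion_counts(tp = 1, fp = 16, tn = 21, fn = 0))
#' @export
rates <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  with(counts, {
    if (TP + FN == 0) stop("TPR undefined: no positives (TP + FN = 0)",
                           call. = FALSE)
    if (FP + TN == 0) stop("FPR undefined: no negatives (FP + TN = 0)",
                           call. = FALSE)
    list(TPR = TP / (TP + FN), FPR = FP / (FP + TN),
         ACC = (TP + TN) / (TP + TN + FP + FN))
  })
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps a decision threshold over the unique scores (ties grouped at a
#' single threshold), honouring the score direction, and integrates the
#' curve by the trapezoidal rule. The resulting AUC equals the normalised
#' Mann-Whitney statistic: the fraction of (active, decoy) pairs ordered
#' correctly, with half credit for ties.
#'
#' @param scores Numeric scores, one per compound.
#' @param labels Binary labels (1 = active / positive).
#' @param direction `"higher"` if larger scores mean more active,
#'   `"lower"` if smaller scores do (the docking convention).
#' @return An object of class `roc`: `curve` (data frame of FPR, TPR from
#'   (0,0) to (1,1)), `auc`, `direction`.
#' @examples
#' r <- roc_auc(c(-12, -11, -5, -4), c(1, 1, 0, 0), direction = "lower")
#' r$auc
#' @export
roc_auc <- function(scores, labels, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    stop("both classes must be present to compute a ROC curve",
         call. = FALSE)
  }
  s <- if (direction == "lower") -scores else scores
  np <- sum(labels == 1L)
  nn <- sum(labels == 0L)
  # sweep thresholds from the most to the least "active" score
  ord <- order(s, decreasing = TRUE)
  s_ord <- s[ord]
  lab_ord <- labels[ord]
  grp <- cumsum(!duplicated(s_ord)) # tie groups share one threshold
  tp <- cumsum(lab_ord == 1L)
  fp <- cumsum(lab_ord == 0L)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / np)
  fpr <- c(0, fp[last] / nn)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(curve = data.frame(FPR = fpr, TPR = tpr), auc = auc,
                 direction = direction),
            class = "roc")
}

#' @export
print.roc <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUC = %.4f (direction: %s scores = more active)\n",
              nrow(x$curve), x$auc, x$direction))
  invisible(x)
}

#' Plot a ROC curve
#'
#' @param x A `roc` object from [roc_auc()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.roc <- function(x, ...) {
  graphics::plot(x$curve$FPR, x$curve$TPR, type = "l",
                 xlab = "False positive rate", ylab = "True positive rate",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  graphics::legend("bottomright", bty = "n",
                   legend = sprintf("AUC = %.3f", x$auc))
  invisible(x)
}

#' Active-versus-decoy score-separation p-value
#'
#' Tests whether actives score systematically better than decoys, the
#' standard sanity check that a docking protocol can discriminate at all.
#' One-sided in the "actives better" direction implied by `direction`.
#' Welch's unequal-variance t-test is the default (robust to the typically
#' very unbalanced active/decoy sizes); a pooled-variance t-test and the
#' Mann-Whitney test are available.
#'
#' @param active_scores,decoy_scores Numeric score vectors, >= 2 each.
#' @param direction `"lower"` if smaller scores are better (docking
#'   convention) else `"higher"`.
#' @param method `"welch"`, `"pooled"` or `"wilcox"`.
#' @return The one-sided p-value.
#' @export
separation_pvalue <- function(active_scores, decoy_scores,
                              direction = c("lower", "higher"),
                              method = c("welch", "pooled", "wilcox")) {
  direction <- match.arg(direction)
  method <- match.arg(method)
  if (length(active_scores) < 2 || length(decoy_scores) < 2) {
    stop("at least two scores per group are required", call. = FALSE)
  }
  alternative <- if (direction == "lower") "less" else "greater"
  if (stats::sd(active_scores) == 0 && stats::sd(decoy_scores) == 0) {
    ma <- mean(active_scores); md <- mean(decoy_scores)
    if (ma == md) return(1)
    better <- if (direction == "lower") ma < md else ma > md
    return(if (better) 0 else 1)
  }
  p <- switch(method,
    welch = stats::t.test(active_scores, decoy_scores,
                          alternative = alternative,
                          var.equal = FALSE)$p.value,
    pooled = stats::t.test(active_scores, decoy_scores,
                           alternative = alternative,
                           var.equal = TRUE)$p.value,
    wilcox = stats::wilcox.test(active_scores, decoy_scores,
                                alternative = alternative,
                                exact = FALSE)$p.value)
  unname(p)
}

#' Root mean square deviation between matched coordinates
#'
#' Pose-versus-pose RMSD in a common receptor frame: atoms are matched by
#' row order and no superposition is performed, the convention for
#' redocking validation against the crystallographic pose.
#'
#' @param coordsA,coordsB Numeric n x 3 matrices of coordinates in
#'   Angstroms, same atom order.
#' @return RMSD in Angstroms.
#' @examples
#' a <- matrix(0, 3, 3); b <- a; b[1, 1] <- 1
#' rmsd(a, b)
#' @export
rmsd <- function(coordsA, coordsB) {
  coordsA <- as.matrix(coordsA); coordsB <- as.matrix(coordsB)
  if (!all(dim(coordsA) == dim(coordsB)) || ncol(coordsA) != 3) {
    stop("coordinate sets must be n x 3 matrices with matched atoms",
         call. = FALSE)
  }
  sqrt(mean(rowSums((coordsA - coordsB)^2)))
}

#' Read coordinates from an xyz-style CSV
#'
#' Minimal coordinate table: columns `atom_id`, `x`, `y`, `z` (Angstroms).
#'
#' @param path CSV file path.
#' @return Numeric matrix (atoms x 3) with atom-id row names.
#' @export
read_coords <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("atom_id", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("coordinate file must have columns atom_id, x, y, z", call. = FALSE)
  }
  m <- as.matrix(df[, c("x", "y", "z")])
  rownames(m) <- df$atom_id
  m
}

#' Screening hit rate
#'
#' Percentage of experimentally tested candidates confirmed active,
#' rounded half away from zero to two decimals for reporting.
#'
#' @param n_hits Confirmed actives (<= `n_tested`).
#' @param n_tested Candidates tested (>= 1).
#' @return Percentage.
#' @examples
#' hit_rate(1, 38) # 2.63
#' @export
hit_rate <- function(n_hits, n_tested) {
  if (n_tested < 1) stop("n_tested must be at least 1", call. = FALSE)
  if (n_hits < 0 || n_hits > n_tested) {
    stop("n_hits must lie in [0, n_tested]", call. = FALSE)
  }
  round_half_up(100 * n_hits / n_tested, 2)
}

#' Classifier exclusion rate
#'
#' Percentage of candidates a rescoring classifier flags as inactive,
#' rounded half away from zero to two decimals for reporting.
#'
#' @param predicted_labels Binary vector of predicted labels
#'   (0 = inactive).
#' @return Percentage flagged inactive.
#' @examples
#' exclusion_rate(c(1, 1, 1, 1, 0, 0, 1, 1, 1, 1)) # 20
#' @export
exclusion_rate <- function(predicted_labels) {
  if (length(predicted_labels) == 0) {
    stop("predicted labels must be non-empty", call. = FALSE)
  }
  if (!all(predicted_labels %in% c(0L, 1L))) {
    stop("predicted labels must be binary (0/1)", call. = FALSE)
  }
  round_half_up(100 * mean(predicted_labels == 0L), 2)
}
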