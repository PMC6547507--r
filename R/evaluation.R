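# ROC / precision-recall evaluation of footprint scores against a
# reference binding set, including DeLong's test for correlated auROCs.

#' Label motif sites by overlap with a reference binding set
#'
#' Marks a site positive iff it overlaps any reference peak by at least
#' 1 bp (half-open interval convention: a site that merely abuts a peak is
#' negative).
#'
#' @param scores `GRanges` of scored sites (e.g. from [score_sites()]).
#' @param reference_peaks Non-empty `GRanges` of reference binding peaks
#'   (e.g. ChIP-seq peaks for the same TF).
#' @return `scores` with a logical `label` column.
#' @export
label_sites <- function(scores, reference_peaks) {
  stopifnot(is(scores, "GRanges"))
  if (!length(reference_peaks))
    stop("empty reference set: cannot define positives")
  S4Vectors::mcols(scores)$label <-
    IRanges::overlapsAny(scores, reference_peaks)
  scores
}

orient_scores <- function(score, label, direction) {
  if (is(score, "GRanges")) {
    label <- S4Vectors::mcols(score)$label
    score <- S4Vectors::mcols(score)$z
  }
  if (is.null(label)) stop("labels missing; run label_sites() first")
  ok <- !is.na(score) & !is.na(label)
  score <- score[ok]; label <- as.logical(label[ok])
  s <- if (direction == "lower") -score else score
  list(s = s, label = label)
}

#' ROC curve and auROC for footprint scores
#'
#' Sweeps thresholds over the unique score values (ties grouped into one
#' ROC vertex) and computes the area under the curve by the trapezoid rule,
#' which equals the tie-corrected Mann-Whitney statistic
#' `P(score_pos better than score_neg) + 0.5 P(tie)`.
#'
#' @param score Numeric scores, or a labelled `GRanges` from
#'   [label_sites()] (then the `z` column is used).
#' @param label Logical labels (`TRUE` = bound); ignored for `GRanges`
#'   input.
#' @param direction `"lower"` (default: more negative score means more
#'   bound, the convention for footprint z-scores) or `"higher"`.
#' @return Object of class `crossfoot_roc`: list with `fpr`, `tpr`,
#'   `thresholds`, `auroc`, `n_pos`, `n_neg`, and the oriented per-site
#'   `scores`/`labels` (kept for [compare_auroc()]).
#' @export
roc_curve <- function(score, label = NULL,
                      direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  o <- orient_scores(score, label, direction)
  n_pos <- sum(o$label); n_neg <- sum(!o$label)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present (", n_pos, " pos, ", n_neg, " neg)")
  ord <- order(o$s, decreasing = TRUE)
  s <- o$s[ord]; lab <- o$label[ord]
  last <- c(s[-1] != s[-length(s)], TRUE)     # last index of each tie group
  tp <- cumsum(lab)[last]
  fp <- cumsum(!lab)[last]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auroc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(fpr = fpr, tpr = tpr, thresholds = c(Inf, s[last]),
                 auroc = auroc, n_pos = n_pos, n_neg = n_neg,
                 scores = o$s, labels = o$label),
            class = "crossfoot_roc")
}

#' @export
print.crossfoot_roc <- function(x, ...) {
  cat("ROC:", x$n_pos, "positives /", x$n_neg, "negatives; auROC =",
      signif(x$auroc, 4), "\n")
  invisible(x)
}

# Placement values of DeLong (1988) from midranks.
delong_placements <- function(s, label) {
  x <- s[label]; y <- s[!label]
  n1 <- length(x); n0 <- length(y)
  r <- rank(c(x, y), ties.method = "average")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  v10 <- (r[seq_len(n1)] - rx) / n0
  v01 <- 1 - (r[n1 + seq_len(n0)] - ry) / n1
  list(v10 = v10, v01 = v01, auc = (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) /
         (as.numeric(n1) * n0))
}

#' Compare two auROCs with DeLong's test
#'
#' Two-sided test of `auROC_a = auROC_b` using DeLong's nonparametric
#' variance estimate based on placement values. The paired variant (for two
#' scorings of the same sites, the usual case when comparing cross-linking
#' conditions) accounts for the covariance between the two curves and
#' requires identical label vectors in identical site order and yields a
#' normal z statistic; the unpaired variant adds the independent variances
#' and refers the statistic to a t distribution with Welch-Satterthwaite
#' degrees of freedom.
#'
#' @param roc_a,roc_b `crossfoot_roc` objects.
#' @param paired Logical (default `TRUE`).
#' @return List with `auc_a`, `auc_b`, `diff`, `se`, `statistic` (z), and
#'   `p_value`.
#' @export
compare_auroc <- function(roc_a, roc_b, paired = TRUE) {
  stopifnot(inherits(roc_a, "crossfoot_roc"), inherits(roc_b, "crossfoot_roc"))
  pa <- delong_placements(roc_a$scores, roc_a$labels)
  pb <- delong_placements(roc_b$scores, roc_b$labels)
  n1a <- roc_a$n_pos; n0a <- roc_a$n_neg
  d <- pa$auc - pb$auc
  if (paired) {
    if (n1a != roc_b$n_pos || n0a != roc_b$n_neg ||
        !identical(roc_a$labels, roc_b$labels))
      stop("paired comparison requires identical site lists in identical order")
    s10 <- stats::var(pa$v10) + stats::var(pb$v10) - 2 * stats::cov(pa$v10, pb$v10)
    s01 <- stats::var(pa$v01) + stats::var(pb$v01) - 2 * stats::cov(pa$v01, pb$v01)
    v <- s10 / n1a + s01 / n0a
    se <- sqrt(max(v, 0))
    z <- if (se == 0) { if (d == 0) 0 else sign(d) * Inf } else d / se
    p <- if (is.infinite(z)) 0 else 2 * pnorm(-abs(z))
  } else {
    va <- stats::var(pa$v10) / n1a + stats::var(pa$v01) / n0a
    vb <- stats::var(pb$v10) / roc_b$n_pos + stats::var(pb$v01) / roc_b$n_neg
    se <- sqrt(max(va + vb, 0))
    z <- if (se == 0) { if (d == 0) 0 else sign(d) * Inf } else d / se
    df <- (va + vb)^2 / (va^2 / (n1a + n0a - 1) +
                         vb^2 / (roc_b$n_pos + roc_b$n_neg - 1))
    p <- if (is.infinite(z)) 0 else 2 * stats::pt(-abs(z), df)
  }
  list(auc_a = pa$auc, auc_b = pb$auc, diff = d, se = se,
       statistic = z, p_value = p)
}

#' Precision-recall curve and average precision
#'
#' Computes precision and recall at each unique-score threshold (ties
#' grouped) and average precision as the step-wise integral
#' `sum (recall_k - recall_{k-1}) * precision_k`. Useful alongside ROC when
#' bound sites are rare (unbalanced labels).
#'
#' @inheritParams roc_curve
#' @return Object of class `crossfoot_pr`: list with `recall`, `precision`,
#'   `thresholds`, `average_precision`, `n_pos`, `n_neg`.
#' @export
precision_recall <- function(score, label = NULL,
                             direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  o <- orient_scores(score, label, direction)
  n_pos <- sum(o$label); n_neg <- sum(!o$label)
  if (n_pos == 0) stop("no positive labels: precision-recall undefined")
  ord <- order(o$s, decreasing = TRUE)
  s <- o$s[ord]; lab <- o$label[ord]
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(lab)[last]
  fp <- cumsum(!lab)[last]
  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  ap <- sum(diff(c(0, recall)) * precision)
  structure(list(recall = recall, precision = precision,
                 thresholds = s[last], average_precision = ap,
                 n_pos = n_pos, n_neg = n_neg),
            class = "crossfoot_pr")
}

#' @export
print.crossfoot_pr <- function(x, ...) {
  cat("PR:", x$n_pos, "positives /", x$n_neg, "negatives; AP =",
      signif(x$average_precision, 4), "\n")
  invisible(x)
}
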