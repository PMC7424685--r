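as_binary_labels <- function(labels) {
  if (is.logical(labels)) pos <- labels
  else if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    pos <- labels == 1
  } else {
    l <- tolower(as.character(labels))
    if (!all(l %in% c("positive", "negative"))) {
      stop("labels must be logical, 0/1, or 'positive'/'negative'")
    }
    pos <- l == "positive"
  }
  if (!any(pos) || all(pos)) stop("both label classes must be present")
  pos
}

# Mid-rank AUC: identical to the trapezoid area under the empirical ROC and
# to the Mann-Whitney U statistic scaled by n_pos * n_neg.
auc_rank <- function(scores, pos) {
  np <- sum(pos); nn <- sum(!pos)
  (sum(rank(scores)[pos]) - np * (np + 1) / 2) / (np * nn)
}

#' Empirical ROC curve
#'
#' Classification convention: `score >= threshold` predicts the positive
#' class. Tied scores share one threshold; the AUC is the trapezoid area
#' under the curve, which equals the mid-rank Mann-Whitney statistic
#' `U / (n_pos * n_neg)`.
#'
#' @param scores numeric classifier scores (e.g. %HER2+CK+ fractions).
#' @param labels class labels: logical, 0/1, or `"positive"`/`"negative"`.
#'   Both classes must be present.
#' @return An `evg_roc` object: `thresholds` (descending, starting at
#'   `Inf`), `sensitivity`, `specificity` per threshold, `auc`, `n_pos`,
#'   `n_neg`.
#' @export
roc_curve <- function(scores, labels) {
  pos <- as_binary_labels(labels)
  stopifnot(length(scores) == length(pos), all(is.finite(scores)))
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!pos] < t), numeric(1))
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc_rank(scores, pos),
                 n_pos = sum(pos), n_neg = sum(!pos)),
            class = "evg_roc")
}

#' @export
print.evg_roc <- function(x, ...) {
  cat(sprintf("<evg_roc> AUC %.4f (%d positive / %d negative, %d thresholds)\n",
              x$auc, x$n_pos, x$n_neg, length(x$thresholds)))
  invisible(x)
}

#' @export
plot.evg_roc <- function(x, xlab = "1 - specificity", ylab = "sensitivity", ...) {
  fpr <- c(1 - x$specificity, 1)
  tpr <- c(x$sensitivity, 1)
  o <- order(fpr, tpr)
  plot(fpr[o], tpr[o], type = "l", xlim = c(0, 1), ylim = c(0, 1),
       xlab = xlab, ylab = ylab, ...)
  abline(0, 1, lty = 3)
  invisible(x)
}

# DeLong structural components: V10 (one per positive) and V01 (one per
# negative), with psi = 1, 1/2, 0 for win / tie / loss.
delong_components <- function(scores, pos) {
  x <- scores[pos]; y <- scores[!pos]
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = 1 - colMeans(psi), auc = mean(psi))
}

#' DeLong variance of a single empirical AUC
#'
#' @inheritParams roc_curve
#' @return The structural-components variance estimate of the AUC.
#' @export
auc_delong_variance <- function(scores, labels) {
  pos <- as_binary_labels(labels)
  comp <- delong_components(scores, pos)
  var(comp$v10) / sum(pos) + var(comp$v01) / sum(!pos)
}

#' DeLong comparison of two correlated ROC curves
#'
#' Nonparametric comparison of the AUCs of two scores measured on the same
#' subjects, using the structural-components estimator of
#' `Var(AUC_a - AUC_b)` that accounts for the pairing; the two-sided
#' p-value uses the normal approximation.
#'
#' @param scores_a,scores_b paired numeric scores on identical subjects.
#' @inheritParams roc_curve
#' @return An `evg_delong` list: `auc_a`, `auc_b`, `diff`, `var_diff`,
#'   `z`, `p`, `flag`. When the scores are identical up to rank (zero
#'   variance and zero difference), `p = 1` with flag
#'   `"identical_rankings"`.
#' @export
delong_compare <- function(scores_a, scores_b, labels) {
  pos <- as_binary_labels(labels)
  stopifnot(length(scores_a) == length(pos), length(scores_b) == length(pos))
  ca <- delong_components(scores_a, pos)
  cb <- delong_components(scores_b, pos)
  np <- sum(pos); nn <- sum(!pos)
  s10 <- cov(cbind(ca$v10, cb$v10))
  s01 <- cov(cbind(ca$v01, cb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / np +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / nn
  d <- ca$auc - cb$auc
  flag <- NA_character_
  if (var_diff <= 0) {
    if (abs(d) < 1e-12) {
      z <- 0; p <- 1; flag <- "identical_rankings"
    } else {
      z <- sign(d) * Inf; p <- 0; flag <- "zero_variance"
    }
  } else {
    z <- d / sqrt(var_diff)
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  structure(list(auc_a = ca$auc, auc_b = cb$auc, diff = d, var_diff = var_diff,
                 z = z, p = p, flag = flag),
            class = "evg_delong")
}

#' @export
print.evg_delong <- function(x, ...) {
  cat(sprintf("<evg_delong> AUC %.4f vs %.4f, diff %.4f, z = %.3f, p = %.4g%s\n",
              x$auc_a, x$auc_b, x$diff, x$z, x$p,
              if (!is.na(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Threshold with equal sensitivity and specificity
#'
#' Scans all ROC thresholds and returns the one minimizing
#' `|sensitivity - specificity|`; ties are broken toward the higher
#' specificity, then toward the larger threshold.
#'
#' @param roc an `evg_roc`.
#' @return List with `threshold`, `sensitivity`, `specificity`, `gap`
#'   (= `|sens - spec|` at the chosen threshold).
#' @export
sens_eq_spec_threshold <- function(roc) {
  stopifnot(inherits(roc, "evg_roc"))
  gap <- abs(roc$sensitivity - roc$specificity)
  best <- which(gap <= min(gap) + 1e-12)
  if (length(best) > 1L) {
    best <- best[order(-roc$specificity[best], -roc$thresholds[best])]
  }
  i <- best[1]
  list(threshold = roc$thresholds[i], sensitivity = roc$sensitivity[i],
       specificity = roc$specificity[i], gap = gap[i])
}

#' Prediction accuracy stratified by minimum total count
#'
#' Evaluates the rule "predict HER2-positive tissue iff the %HER2+CK+
#' fraction is at least `fraction_threshold`" on patients whose
#' compartment total reaches each minimum count, reporting sensitivity,
#' specificity and accuracy against the tissue label at the cost of the
#' number of eligible patients.
#'
#' @param cohort an `evg_cohort` data frame with `tissue_her2` labels
#'   (`"positive"`/`"negative"`; other values are treated as unknown and
#'   excluded).
#' @param compartment `"ctc"` or `"tdev"`.
#' @param fraction_threshold percentage threshold in (0, 100).
#' @param min_totals minimum total counts defining the strata.
#' @return Data frame with one row per stratum: `min_total`, `n_eligible`,
#'   `sensitivity`, `specificity`, `accuracy` (`NA` where undefined).
#' @export
accuracy_by_min_count <- function(cohort, compartment = c("ctc", "tdev"),
                                  fraction_threshold,
                                  min_totals = c(1, 5, 10, 20, 50, 100)) {
  compartment <- match.arg(compartment)
  if (fraction_threshold <= 0 || fraction_threshold >= 100) {
    stop("fraction_threshold must lie in (0, 100)")
  }
  fr <- cohort_fractions(cohort, compartment)
  known <- cohort$tissue_her2 %in% c("positive", "negative")
  truth_pos <- cohort$tissue_her2 == "positive"
  rows <- lapply(min_totals, function(mt) {
    el <- known & fr$total >= mt & !is.na(fr$pct_ck_her2)
    n_el <- sum(el)
    if (n_el == 0L) {
      return(data.frame(min_total = mt, n_eligible = 0L, sensitivity = NA_real_,
                        specificity = NA_real_, accuracy = NA_real_))
    }
    pred <- fr$pct_ck_her2[el] >= fraction_threshold
    tp <- truth_pos[el]
    sens <- if (any(tp)) mean(pred[tp]) else NA_real_
    spec <- if (any(!tp)) mean(!pred[!tp]) else NA_real_
    data.frame(min_total = mt, n_eligible = n_el, sensitivity = sens,
               specificity = spec, accuracy = mean(pred == tp))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
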