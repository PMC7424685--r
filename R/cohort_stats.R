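compartment_cols <- function(compartment = c("ctc", "tdev")) {
  compartment <- match.arg(compartment)
  paste0(compartment, "_", EVG_PHENOTYPES)
}

#' Phenotype fractions of one patient's CTC or tdEV counts
#'
#' @param rec one patient record: a one-row data frame (or named vector)
#'   holding the six subclass count columns.
#' @param compartment `"ctc"` or `"tdev"`.
#' @return Named numeric vector of the three phenotype percentages
#'   (summing to 100), or all-`NA` with a warning when the compartment
#'   total is zero (the fractions are then undefined, never 0/0 = 0).
#' @export
#' @examples
#' class_fractions(c(ctc_ck_her2neg = 10, ctc_ckneg_her2 = 5, ctc_ck_her2 = 5,
#'                   tdev_ck_her2neg = 0, tdev_ckneg_her2 = 0, tdev_ck_her2 = 0),
#'                 "ctc")
class_fractions <- function(rec, compartment = c("ctc", "tdev")) {
  cols <- compartment_cols(compartment)
  cnt <- vapply(cols, function(cl) as.numeric(rec[[cl]]), numeric(1))
  if (any(is.na(cnt)) || any(cnt < 0)) stop("counts must be non-negative and present")
  tot <- sum(cnt)
  if (tot == 0) {
    warning("compartment total is zero; fractions are undefined")
    return(setNames(rep(NA_real_, 3L), paste0("pct_", EVG_PHENOTYPES)))
  }
  setNames(100 * cnt / tot, paste0("pct_", EVG_PHENOTYPES))
}

#' Per-patient phenotype fractions for a whole cohort
#'
#' @param cohort an `evg_cohort` data frame.
#' @param compartment `"ctc"` or `"tdev"`.
#' @return Data frame with `patient_id`, the compartment `total`, and the
#'   three percentage columns (`NA` where the total is zero).
#' @export
cohort_fractions <- function(cohort, compartment = c("ctc", "tdev")) {
  cols <- compartment_cols(compartment)
  cnt <- as.matrix(cohort[, cols])
  tot <- rowSums(cnt)
  pct <- 100 * cnt / ifelse(tot > 0, tot, NA)
  out <- data.frame(patient_id = cohort$patient_id, total = tot,
                    pct, stringsAsFactors = FALSE)
  names(out)[3:5] <- paste0("pct_", EVG_PHENOTYPES)
  out
}

#' Immunophenotype heterogeneity class of one patient
#'
#' Counts how many of the three phenotype subclasses are present above a
#' noise threshold (strictly greater). The defaults encode presence as
#' ">= 1 count" for CTCs (threshold 0) and "> 10 counts" for tdEVs
#' (threshold 10, the tdEV noise level).
#'
#' @inheritParams class_fractions
#' @param presence_threshold count a class must strictly exceed to be
#'   considered present; default 0 for CTCs, 10 for tdEVs.
#' @return Integer in 0..3.
#' @export
heterogeneity_class <- function(rec, compartment = c("ctc", "tdev"),
                                presence_threshold = NULL) {
  compartment <- match.arg(compartment)
  if (is.null(presence_threshold)) {
    presence_threshold <- if (compartment == "ctc") 0 else 10
  }
  if (presence_threshold < 0) stop("presence_threshold must be >= 0")
  cols <- compartment_cols(compartment)
  cnt <- vapply(cols, function(cl) as.numeric(rec[[cl]]), numeric(1))
  sum(cnt > presence_threshold)
}

#' Partition a cohort by which subclasses are present
#'
#' Tallies patients by their presence pattern over the three phenotype
#' subclasses (the cells of a three-set Venn diagram, plus "none").
#'
#' @inheritParams cohort_fractions
#' @param presence_threshold as in [heterogeneity_class()].
#' @return Named integer vector over the 8 patterns (`none`, the three
#'   singletons, the three pairs, `all`); sums to the number of patients.
#' @export
venn_partition <- function(cohort, compartment = c("ctc", "tdev"),
                           presence_threshold = NULL) {
  compartment <- match.arg(compartment)
  if (is.null(presence_threshold)) {
    presence_threshold <- if (compartment == "ctc") 0 else 10
  }
  cols <- compartment_cols(compartment)
  if (nrow(cohort) < 1L) stop("cohort must contain at least one patient")
  pres <- as.matrix(cohort[, cols]) > presence_threshold
  pattern_names <- c("none", EVG_PHENOTYPES,
                     paste(EVG_PHENOTYPES[c(1, 1, 2)], EVG_PHENOTYPES[c(2, 3, 3)],
                           sep = "+"),
                     "all")
  key <- apply(pres, 1L, function(p) {
    k <- sum(p)
    if (k == 0L) "none"
    else if (k == 3L) "all"
    else paste(EVG_PHENOTYPES[p], collapse = "+")
  })
  tab <- table(factor(key, levels = pattern_names))
  setNames(as.integer(tab), pattern_names)
}

#' Compare paired counts: Spearman correlation and Wilcoxon signed ranks
#'
#' The Spearman rank correlation (mid-rank ties, two-sided asymptotic
#' p-value) quantifies the monotone relation between the paired counts;
#' the Wilcoxon signed-rank test (normal approximation with tie
#' correction) tests the equality of their distributions. Zero differences
#' are handled by Pratt's method by default (ranked with the rest, then
#' discarded from the statistic); the classical reduced-sample convention
#' is available via `zero_method = "wilcoxon"`.
#'
#' @param x,y paired numeric vectors of equal length >= 3.
#' @param zero_method `"pratt"` or `"wilcoxon"`.
#' @return List with `spearman_rho`, `spearman_p`, `wilcoxon_p`, `n`.
#'   `spearman_rho` is `NA` when either margin is constant; `wilcoxon_p`
#'   is `NA` when there is no non-zero difference.
#' @export
paired_compare <- function(x, y, zero_method = c("pratt", "wilcoxon")) {
  zero_method <- match.arg(zero_method)
  stopifnot(length(x) == length(y), length(x) >= 3L)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) {
    rho <- NA_real_; rho_p <- NA_real_
  } else {
    ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
    rho <- unname(ct$estimate); rho_p <- ct$p.value
  }
  list(spearman_rho = rho, spearman_p = rho_p,
       wilcoxon_p = signed_rank_p(x, y, zero_method), n = length(x))
}

# Wilcoxon signed-rank two-sided p-value, normal approximation with tie
# correction; Pratt or reduced-sample handling of zero differences.
signed_rank_p <- function(x, y, zero_method = "pratt") {
  d <- y - x
  if (all(d == 0)) return(NA_real_)
  if (zero_method == "wilcoxon") {
    d <- d[d != 0]
    r <- rank(abs(d))
    n <- length(d)
    w <- sum(r[d > 0])
    e_w <- n * (n + 1) / 4
    v_w <- n * (n + 1) * (2 * n + 1) / 24
    tie <- table(r)
  } else {
    r <- rank(abs(d))
    n <- length(d)
    z0 <- sum(d == 0)
    w <- sum(r[d > 0])
    e_w <- (n * (n + 1) - z0 * (z0 + 1)) / 4
    v_w <- (n * (n + 1) * (2 * n + 1) - z0 * (z0 + 1) * (2 * z0 + 1)) / 24
    tie <- table(r[d != 0])
  }
  v_w <- v_w - sum(tie^3 - tie) / 48
  if (v_w <= 0) return(NA_real_)
  z <- (w - e_w) / sqrt(v_w)
  min(1, 2 * pnorm(-abs(z)))
}

#' Compare two independent groups: Mann-Whitney U test
#'
#' Mid-rank U statistic. The two-sided p-value is exact (full enumeration
#' of group assignments, valid under ties) when the number of assignments
#' `choose(n1 + n2, n1)` is at most `max_enum`, and otherwise uses the
#' normal approximation with tie correction.
#'
#' @param x,y numeric vectors, both non-empty.
#' @param max_enum enumeration budget for the exact test.
#' @return List with `U` (for the first group), `p`, `method`.
#' @export
#' @examples
#' group_compare(c(1, 2, 3), c(10, 11, 12))  # complete separation: p = 0.1
group_compare <- function(x, y, max_enum = 2e5) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  center <- n1 * n2 / 2
  if (choose(n1 + n2, n1) <= max_enum) {
    sets <- combn(n1 + n2, n1)
    rsums <- colSums(matrix(r[sets], nrow = n1))
    u_all <- rsums - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - center) >= abs(u_obs - center) - 1e-9)
    method <- "exact"
  } else {
    N <- n1 + n2
    tie <- table(r)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u_obs - center) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal"
  }
  list(U = u_obs, p = p, method = method)
}
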