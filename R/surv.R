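#' Kaplan-Meier survival curves
#'
#' Product-limit estimates of overall survival per group; censored
#' subjects leave the risk set after their censoring time.
#'
#' @param times non-negative follow-up times (days).
#' @param events event indicators (1/TRUE = death observed, 0/FALSE =
#'   censored).
#' @param groups optional group labels; `NULL` fits one curve.
#' @return An `evg_km` data frame: `group`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`.
#' @export
km_estimate <- function(times, events, groups = NULL) {
  stopifnot(length(times) == length(events), all(times >= 0, na.rm = TRUE))
  if (is.null(groups)) groups <- rep("all", length(times))
  if (length(groups) != length(times)) stop("groups must match times in length")
  g <- factor(groups)
  if (any(table(g) == 0L) || length(times) == 0L) stop("empty group in km_estimate")
  out <- do.call(rbind, lapply(levels(g), function(lev) {
    sel <- g == lev
    fit <- survival::survfit(survival::Surv(times[sel], events[sel]) ~ 1)
    data.frame(group = lev, time = fit$time, n_risk = fit$n.risk,
               n_event = fit$n.event, n_censor = fit$n.censor,
               surv = fit$surv, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("evg_km", "data.frame")
  out
}

#' @export
plot.evg_km <- function(x, xlab = "days", ylab = "overall survival", ...) {
  groups <- unique(x$group)
  plot(NA, xlim = c(0, max(x$time)), ylim = c(0, 1), xlab = xlab, ylab = ylab, ...)
  for (i in seq_along(groups)) {
    d <- x[x$group == groups[i], ]
    lines(stats::stepfun(d$time, c(1, d$surv)), do.points = FALSE, col = i)
  }
  if (length(groups) > 1L) legend("topright", legend = groups,
                                  col = seq_along(groups), lty = 1, bty = "n")
  invisible(x)
}

#' Log-rank test
#'
#' Unweighted Mantel-Haenszel log-rank comparison of survival between
#' groups; two-sided p-value from a chi-square distribution with
#' (k - 1) degrees of freedom. With no events at all the statistic is 0
#' and p = 1 by convention.
#'
#' @inheritParams km_estimate
#' @param groups group labels (>= 2 non-empty groups).
#' @return List with `statistic`, `df`, `p`.
#' @export
logrank <- function(times, events, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("log-rank test needs at least 2 groups")
  if (any(table(g) == 0L)) stop("empty group in logrank")
  if (sum(events) == 0) {
    return(list(statistic = 0, df = nlevels(g) - 1L, p = 1))
  }
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ g)
  df <- nlevels(g) - 1L
  list(statistic = unname(sd_$chisq), df = df,
       p = pchisq(sd_$chisq, df, lower.tail = FALSE))
}

#' Univariable Cox proportional-hazards regression
#'
#' Partial-likelihood fit (Newton-Raphson, Efron tie handling) of a single
#' covariate. Counts are log-transformed as `log10(x + 1)` by default to
#' stabilize the model fit; `transform = "identity"` fits the raw
#' covariate (used for binary dichotomization indicators).
#'
#' @param covariate numeric covariate (e.g. a subclass count).
#' @param times,events follow-up times and event indicators.
#' @param transform `"log10p1"` or `"identity"`.
#' @return An `evg_cox_fit` list: `beta`, `se`, `hr`, `ci_lower`,
#'   `ci_upper` (Wald 95% on the log scale), `p`, `n`, `n_events`,
#'   `transform`, `flag` (`NA` for a clean fit; `"degenerate"` for a
#'   constant covariate, `"unstable"` when the partial likelihood is
#'   monotone / the fit did not converge cleanly).
#' @export
cox_univariable <- function(covariate, times, events,
                            transform = c("log10p1", "identity")) {
  transform <- match.arg(transform)
  stopifnot(length(covariate) == length(times), length(times) == length(events))
  if (sum(events) < 1) stop("at least one event is required")
  x <- switch(transform, log10p1 = log10(covariate + 1), identity = covariate)
  if (!all(is.finite(x))) stop("covariate must be finite after transformation")
  mk <- function(beta, se, p, flag) {
    structure(list(beta = beta, se = se, hr = exp(beta),
                   ci_lower = exp(beta - 1.96 * se),
                   ci_upper = exp(beta + 1.96 * se), p = p,
                   n = length(x), n_events = sum(events > 0),
                   transform = transform, flag = flag),
              class = "evg_cox_fit")
  }
  if (sd(x) == 0) return(mk(NA_real_, NA_real_, NA_real_, "degenerate"))
  flag <- NA_character_
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(times, events) ~ x, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge|singular", conditionMessage(w))) {
        flag <<- "unstable"
      }
      invokeRestart("muffleWarning")
    }
  )
  beta <- unname(fit$coefficients[1])
  se <- sqrt(unname(fit$var[1, 1]))
  if (!is.finite(beta) || !is.finite(se)) {
    return(mk(if (is.finite(beta)) beta else NA_real_, NA_real_, NA_real_,
              "unstable"))
  }
  p <- 2 * pnorm(-abs(beta / se))
  mk(beta, se, p, flag)
}

#' @export
print.evg_cox_fit <- function(x, ...) {
  cat(sprintf("<evg_cox_fit> HR %.3f (95%% CI %.3f-%.3f), p = %.4g, n = %d (%d events)%s\n",
              x$hr, x$ci_lower, x$ci_upper, x$p, x$n, x$n_events,
              if (!is.na(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Hazard-ratio scan over all dichotomization cutoffs
#'
#' For every distinct observed count value `c`, patients are dichotomized
#' into `>= c` ("unfavorable") versus `< c`, a binary-covariate Cox model
#' is fitted, and the hazard ratio with its 95% CI and p-value is
#' recorded. Cutoffs leaving either group smaller than
#' `min_group_fraction` of the cohort are excluded. This is the
#' optimization view popularized by cutoff-determination tools: the
#' summary reports the fraction of admissible cutoffs that reach
#' p < 0.05.
#'
#' @param counts per-patient counts to dichotomize on.
#' @param times,events follow-up times and event indicators.
#' @param min_group_fraction minimum admissible group size as a fraction
#'   of the cohort (default 0.1).
#' @return An `evg_cutoff_scan` data frame (`cutoff`, `n_low`, `n_high`,
#'   `hr`, `ci_lower`, `ci_upper`, `p`, `flag`) with attributes
#'   `sig_fraction` (fraction of clean fits with p < 0.05) and `n`. All
#'   counts equal yields an empty scan with a warning.
#' @export
cutoff_scan <- function(counts, times, events, min_group_fraction = 0.1) {
  stopifnot(length(counts) == length(times), length(times) == length(events))
  n <- length(counts)
  vals <- sort(unique(counts))
  empty <- data.frame(cutoff = numeric(0), n_low = integer(0), n_high = integer(0),
                      hr = numeric(0), ci_lower = numeric(0), ci_upper = numeric(0),
                      p = numeric(0), flag = character(0), stringsAsFactors = FALSE)
  if (length(vals) < 2L) {
    warning("all counts are equal; no admissible cutoff")
    class(empty) <- c("evg_cutoff_scan", "data.frame")
    attr(empty, "sig_fraction") <- NA_real_
    attr(empty, "n") <- n
    return(empty)
  }
  min_n <- max(1L, ceiling(min_group_fraction * n))
  rows <- lapply(vals, function(cc) {
    hi <- counts >= cc
    n_hi <- sum(hi); n_lo <- n - n_hi
    if (n_hi < min_n || n_lo < min_n) return(NULL)
    fit <- cox_univariable(as.numeric(hi), times, events, transform = "identity")
    data.frame(cutoff = cc, n_low = n_lo, n_high = n_hi, hr = fit$hr,
               ci_lower = fit$ci_lower, ci_upper = fit$ci_upper, p = fit$p,
               flag = fit$flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- empty
  rownames(out) <- NULL
  class(out) <- c("evg_cutoff_scan", "data.frame")
  clean <- is.na(out$flag) & is.finite(out$p)
  attr(out, "sig_fraction") <- if (any(clean)) mean(out$p[clean] < 0.05) else NA_real_
  attr(out, "n") <- n
  out
}

#' @export
plot.evg_cutoff_scan <- function(x, xlab = "cutoff (counts)",
                                 ylab = "hazard ratio (95% CI)", log = "y", ...) {
  ok <- is.finite(x$hr) & is.finite(x$ci_lower) & is.finite(x$ci_upper)
  d <- x[ok, ]
  plot(d$cutoff, d$hr, ylim = range(c(d$ci_lower, d$ci_upper, 1)),
       xlab = xlab, ylab = ylab, log = log, pch = 16, ...)
  segments(d$cutoff, d$ci_lower, d$cutoff, d$ci_upper)
  abline(h = 1, lty = 2)
  invisible(x)
}
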