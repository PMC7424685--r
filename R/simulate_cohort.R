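EVG_PHENOTYPES <- c("ck_her2neg", "ckneg_her2", "ck_her2")

#' Configuration for the synthetic patient-cohort generator
#'
#' Per-patient counts for the six CTC/tdEV subclasses are drawn from
#' zero-inflated negative binomial (ZINB) marginals coupled by a Gaussian
#' copula; overall survival follows an exponential proportional-hazards
#' model on the log10(count + 1) covariates with independent uniform
#' censoring; tissue HER2 status follows a logistic link on the patient's
#' %HER2+CK+ fraction.
#'
#' Defaults encode the cohort structure the analysis assumes: CK+HER2-
#' tdEVs about 15-fold more frequent than the matching CTCs, a strong
#' (Spearman 0.84) CTC-tdEV correlation in the CK+HER2- class and moderate
#' (0.55) correlations in the HER2+ classes, and a latent "%HER2+CK+ tdEVs
#' >= 7%" tissue rule observed through logistic noise.
#'
#' @param n_patients number of patients (>= 2).
#' @param ctc_marginals named list over phenotypes (`ck_her2neg`,
#'   `ckneg_her2`, `ck_her2`), each `c(pi0, mu, size)`: zero-inflation
#'   probability, negative-binomial mean and dispersion of the CTC counts.
#' @param tdev_fold multiplier linking the tdEV count distribution to the
#'   CTC distribution of the same phenotype, per phenotype: a tdEV count
#'   is a rounded `fold`-multiple of a ZINB draw with the phenotype's CTC
#'   parameters, so means AND medians scale by the fold.
#' @param tdev_pi0 zero-inflation probabilities of the tdEV classes;
#'   `NULL` (default) inherits each phenotype's CTC zero-inflation.
#' @param target_spearman target Spearman correlation between the CTC and
#'   tdEV counts of each phenotype; the copula's latent correlations are
#'   calibrated (deterministically) so the discrete margins attain these.
#' @param base_spearman Spearman correlation between all other class
#'   pairs, modeling shared tumor burden.
#' @param cox_betas named log-hazard ratios per unit log10(count + 1), one
#'   per subclass column.
#' @param baseline_hazard baseline event hazard (events/day).
#' @param censoring_rate target fraction of censored patients (uniform
#'   independent censoring calibrated to the realized event times).
#' @param tissue_model list with `compartment` (`"tdev"` or `"ctc"`),
#'   `cutpoint_pct` and `slope`: P(HER2+ tissue) =
#'   `plogis(slope * (pct_her2ck - cutpoint_pct))`.
#' @param manual_recount_rate per-object probability that the simulated
#'   manual CTC recount retains an automated CK+HER2- CTC.
#' @param seed integer seed; the generator is deterministic given the
#'   configuration.
#' @return An object of class `evg_cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_patients = 98L,
                              ctc_marginals = list(
                                ck_her2neg = c(pi0 = 0.10, mu = 8, size = 0.6),
                                ckneg_her2 = c(pi0 = 0.25, mu = 3, size = 0.6),
                                ck_her2    = c(pi0 = 0.20, mu = 4, size = 0.6)),
                              tdev_fold = c(ck_her2neg = 15, ckneg_her2 = 1,
                                            ck_her2 = 1),
                              tdev_pi0 = NULL,
                              target_spearman = c(ck_her2neg = 0.84,
                                                  ckneg_her2 = 0.55,
                                                  ck_her2 = 0.55),
                              base_spearman = 0.3,
                              cox_betas = c(ctc_ck_her2neg = 0,
                                            ctc_ckneg_her2 = 0,
                                            ctc_ck_her2 = 0,
                                            tdev_ck_her2neg = 0.5,
                                            tdev_ckneg_her2 = 0,
                                            tdev_ck_her2 = 0),
                              baseline_hazard = 1 / 600,
                              censoring_rate = 0.3,
                              tissue_model = list(compartment = "tdev",
                                                  cutpoint_pct = 7,
                                                  slope = 0.8),
                              manual_recount_rate = 0.9,
                              seed = 1L) {
  n_patients <- as.integer(n_patients)
  if (n_patients < 2L) stop("n_patients must be >= 2")
  for (ph in EVG_PHENOTYPES) {
    m <- ctc_marginals[[ph]]
    if (is.null(m) || length(m) != 3L) stop("ctc_marginals$", ph, " must be c(pi0, mu, size)")
    if (m[["pi0"]] < 0 || m[["pi0"]] > 1) stop("zero-inflation probability must be in [0, 1]")
    if (m[["mu"]] < 0 || m[["size"]] <= 0) stop("NB mean must be >= 0 and dispersion > 0")
  }
  if (is.null(tdev_pi0)) {
    tdev_pi0 <- vapply(EVG_PHENOTYPES, function(ph) ctc_marginals[[ph]][["pi0"]],
                       numeric(1))
  }
  if (any(tdev_pi0 < 0 | tdev_pi0 > 1)) stop("tdev_pi0 must be in [0, 1]")
  if (any(tdev_fold <= 0)) stop("tdev_fold must be positive")
  if (any(abs(target_spearman) >= 1) || abs(base_spearman) >= 1) {
    stop("Spearman targets must lie in (-1, 1)")
  }
  if (censoring_rate < 0 || censoring_rate >= 1) stop("censoring_rate must be in [0, 1)")
  if (baseline_hazard <= 0) stop("baseline_hazard must be positive")
  betas <- setNames(rep(0, length(EVG_CLASSES)), EVG_CLASSES)
  bad <- setdiff(names(cox_betas), EVG_CLASSES)
  if (length(bad) > 0L) stop("unknown cox_betas covariate(s): ", paste(bad, collapse = ", "))
  betas[names(cox_betas)] <- cox_betas
  structure(
    list(n_patients = n_patients, ctc_marginals = ctc_marginals,
         tdev_fold = tdev_fold[EVG_PHENOTYPES], tdev_pi0 = tdev_pi0[EVG_PHENOTYPES],
         target_spearman = target_spearman[EVG_PHENOTYPES],
         base_spearman = base_spearman, cox_betas = betas,
         baseline_hazard = baseline_hazard, censoring_rate = censoring_rate,
         tissue_model = tissue_model,
         manual_recount_rate = manual_recount_rate, seed = as.integer(seed)),
    class = "evg_cohort_sim_config"
  )
}

# ZINB quantile function via the probability-integral transform, with an
# optional fold multiplier (counts are rounded fold-multiples of the base
# ZINB quantiles, so the whole distribution scales by the fold).
qzinb <- function(u, pi0, mu, size, fold = 1) {
  out <- numeric(length(u))
  hit <- u > pi0
  out[hit] <- qnbinom((u[hit] - pi0) / (1 - pi0), size = size, mu = mu)
  if (fold != 1) out <- round(out * fold)
  out
}

# All six class marginals as a list of c(pi0, mu, size, fold).
class_marginals <- function(config) {
  m <- list()
  for (ph in EVG_PHENOTYPES) {
    cm <- config$ctc_marginals[[ph]]
    m[[paste0("ctc_", ph)]] <- c(pi0 = unname(cm[["pi0"]]), mu = unname(cm[["mu"]]),
                                 size = unname(cm[["size"]]), fold = 1)
    m[[paste0("tdev_", ph)]] <- c(pi0 = unname(config$tdev_pi0[[ph]]),
                                  mu = unname(cm[["mu"]]),
                                  size = unname(cm[["size"]]),
                                  fold = unname(config$tdev_fold[[ph]]))
  }
  m[EVG_CLASSES]
}

.evg_calib_cache <- new.env(parent = emptyenv())

# Calibrate the latent bivariate-normal correlation so that the ZINB margins
# attain `target` Spearman correlation. Deterministic (fixed internal seed,
# common random numbers across candidate correlations); memoised.
calibrate_latent_rho <- function(target, m1, m2, n_mc = 40000L) {
  key <- paste(signif(c(target, m1, m2), 10), collapse = "|")
  if (!is.null(.evg_calib_cache[[key]])) return(.evg_calib_cache[[key]])
  z <- with_seed(20200812L, matrix(rnorm(2L * n_mc), n_mc, 2L))
  # degenerate margins (e.g. full zero-inflation) carry no rank information;
  # fall back to the continuous-margin mapping
  degen <- function(m) m[["pi0"]] >= 1 || m[["mu"]] == 0
  if (degen(m1) || degen(m2)) {
    rho <- 2 * sin(pi * target / 6)
    .evg_calib_cache[[key]] <- rho
    return(rho)
  }
  emp <- function(r) {
    y2 <- r * z[, 1] + sqrt(1 - r^2) * z[, 2]
    x <- qzinb(pnorm(z[, 1]), m1[["pi0"]], m1[["mu"]], m1[["size"]], m1[["fold"]])
    y <- qzinb(pnorm(y2), m2[["pi0"]], m2[["mu"]], m2[["size"]], m2[["fold"]])
    suppressWarnings(cor(x, y, method = "spearman"))
  }
  lo <- max(-0.999, 2 * sin(pi * target / 6) - 0.2)
  hi <- 0.9995
  if (emp(hi) < target) {
    rho <- hi  # target unattainable for these margins; best effort
  } else {
    for (it in 1:18) {
      mid <- (lo + hi) / 2
      if (emp(mid) < target) lo <- mid else hi <- mid
    }
    rho <- (lo + hi) / 2
  }
  .evg_calib_cache[[key]] <- rho
  rho
}

# Build the 6x6 latent correlation matrix; errors if not positive
# semi-definite (infeasible correlation target).
latent_correlation <- function(config) {
  marg <- class_marginals(config)
  R <- matrix(2 * sin(pi * config$base_spearman / 6), 6, 6,
              dimnames = list(EVG_CLASSES, EVG_CLASSES))
  diag(R) <- 1
  for (ph in EVG_PHENOTYPES) {
    a <- paste0("ctc_", ph); b <- paste0("tdev_", ph)
    R[a, b] <- R[b, a] <- calibrate_latent_rho(config$target_spearman[[ph]],
                                               marg[[a]], marg[[b]])
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("infeasible correlation target: latent correlation matrix is not ",
         "positive semi-definite (smallest eigenvalue ", signif(min(ev), 3), ")")
  }
  R
}

#' Simulate a patient cohort with known generative truth
#'
#' @param config a [cohort_sim_config()].
#' @return A list with `cohort` (an `evg_cohort` data frame: `patient_id`,
#'   the six subclass count columns, `os_days`, `event`, `tissue_her2`,
#'   `manual_ctc`) and `truth` (the generative parameters actually used:
#'   `cox_betas`, `baseline_hazard`, `censoring_max`, `tissue_model`,
#'   `latent_corr`).
#' @export
#' @examples
#' sim <- simulate_cohort(cohort_sim_config(n_patients = 20, seed = 42))
#' head(sim$cohort)
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "evg_cohort_sim_config"))
  R <- latent_correlation(config)  # deterministic; outside the seeded block
  with_seed(config$seed, simulate_cohort_impl(config, R))
}

simulate_cohort_impl <- function(config, R) {
  n <- config$n_patients
  marg <- class_marginals(config)
  L <- chol(R + diag(1e-10, 6))
  Z <- matrix(rnorm(n * 6L), n, 6L) %*% L
  counts <- matrix(0, n, 6L, dimnames = list(NULL, EVG_CLASSES))
  for (j in seq_along(EVG_CLASSES)) {
    m <- marg[[EVG_CLASSES[j]]]
    counts[, j] <- qzinb(pnorm(Z[, j]), m[["pi0"]], m[["mu"]], m[["size"]],
                         m[["fold"]])
  }

  lp <- as.vector(log10(counts + 1) %*% config$cox_betas[EVG_CLASSES])
  t_event <- rexp(n) / (config$baseline_hazard * exp(lp))
  if (config$censoring_rate > 0) {
    # choose the uniform-censoring horizon so the expected censored fraction
    # over the realized event times equals the target rate
    f <- function(cmax) mean(pmin(t_event / cmax, 1)) - config$censoring_rate
    cmax <- uniroot(f, lower = min(t_event) * 1e-6, upper = max(t_event) * 1e6,
                    tol = 1e-8)$root
    cens <- runif(n, 0, cmax)
    os_days <- pmin(t_event, cens)
    event <- as.integer(t_event <= cens)
  } else {
    cmax <- Inf
    os_days <- t_event
    event <- rep(1L, n)
  }

  tm <- config$tissue_model
  comp_cols <- paste0(tm$compartment, "_", EVG_PHENOTYPES)
  tot <- rowSums(counts[, comp_cols, drop = FALSE])
  pct <- ifelse(tot > 0, 100 * counts[, paste0(tm$compartment, "_ck_her2")] / tot, 0)
  p_pos <- plogis(tm$slope * (pct - tm$cutpoint_pct))
  tissue <- ifelse(rbinom(n, 1L, p_pos) == 1L, "positive", "negative")

  manual <- rbinom(n, counts[, "ctc_ck_her2neg"], config$manual_recount_rate)

  cohort <- data.frame(patient_id = sprintf("P%03d", seq_len(n)),
                       counts, os_days = os_days, event = event,
                       tissue_her2 = tissue, manual_ctc = manual,
                       stringsAsFactors = FALSE)
  class(cohort) <- c("evg_cohort", "data.frame")
  list(cohort = cohort,
       truth = list(cox_betas = config$cox_betas,
                    baseline_hazard = config$baseline_hazard,
                    censoring_max = cmax, tissue_model = tm,
                    latent_corr = R))
}
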