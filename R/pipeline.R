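# Minimal CLI-style argument parsing: c("--key", "value", ...) -> named list.
parse_cli_args <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("usage error: unexpected argument '", a, "'")
    key <- gsub("-", "_", substring(a, 3))
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      stop("usage error: flag '", a, "' requires a value")
    }
    out[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  out
}

req_arg <- function(opts, key, sub) {
  if (is.null(opts[[key]])) {
    stop("usage error: ", sub, " requires --", gsub("_", "-", key))
  }
  opts[[key]]
}

log_msg <- function(...) message("[evgate] ", sprintf(...))

load_yaml_config <- function(path) {
  if (is.null(path)) return(list())
  if (!file.exists(path)) stop("config file not found: ", path)
  log_msg("config %s (md5 %s)", path, unname(tools::md5sum(path)))
  conf <- yaml::yaml.load_file(path)
  if (is.null(conf)) list() else conf
}

yaml_to_image_config <- function(conf, seed) {
  for (f in c("object_counts", "background_level", "read_noise_sd",
              "intensity_mean", "intensity_sd")) {
    if (!is.null(conf[[f]])) conf[[f]] <- unlist(conf[[f]])
  }
  if (!is.null(conf$diameter_um)) conf$diameter_um <- lapply(conf$diameter_um, unlist)
  conf$seed <- seed
  do.call(image_sim_config, conf)
}

yaml_to_cohort_config <- function(conf, seed) {
  for (f in c("tdev_fold", "tdev_pi0", "target_spearman", "cox_betas")) {
    if (!is.null(conf[[f]])) conf[[f]] <- unlist(conf[[f]])
  }
  if (!is.null(conf$ctc_marginals)) {
    conf$ctc_marginals <- lapply(conf$ctc_marginals, unlist)
  }
  conf$seed <- seed
  do.call(cohort_sim_config, conf)
}

#' Run a pipeline stage from command-line style arguments
#'
#' Subcommands (composable through file handoffs): `simulate-images`,
#' `simulate-cohort`, `detect`, `gate`, `cohort-stats`, `survival`,
#' `roc`. Every run logs the package version, seed and config hash to
#' stderr; identical arguments (and seed) reproduce identical outputs.
#' A thin executable wrapper over this function is installed at
#' `system.file("scripts", "evgate", package = "evgate")`.
#'
#' @param args character vector: the subcommand followed by `--flag value`
#'   pairs. See the package vignette for each subcommand's flags.
#' @return Invisibly, 0 on success; failures raise errors (the script
#'   wrapper converts them to a non-zero exit status).
#' @export
#' @examples
#' out <- tempfile()
#' run_pipeline(c("simulate-cohort", "--out", file.path(out, "cohort.csv"),
#'                "--seed", "7", "--n-patients", "10"))
#' nrow(read_cohort(file.path(out, "cohort.csv")))
run_pipeline <- function(args) {
  if (length(args) < 1L) {
    stop("usage error: evgate <simulate-images|simulate-cohort|detect|gate|",
         "cohort-stats|survival|roc> [--flag value ...]")
  }
  sub <- args[1]
  opts <- parse_cli_args(args[-1])
  log_msg("evgate %s | %s", as.character(utils::packageVersion("evgate")), sub)
  switch(sub,
         "simulate-images" = cmd_simulate_images(opts),
         "simulate-cohort" = cmd_simulate_cohort(opts),
         "detect" = cmd_detect(opts),
         "gate" = cmd_gate(opts),
         "cohort-stats" = cmd_cohort_stats(opts),
         "survival" = cmd_survival(opts),
         "roc" = cmd_roc(opts),
         stop("usage error: unknown subcommand '", sub, "'"))
  invisible(0L)
}

cmd_simulate_images <- function(opts) {
  out <- req_arg(opts, "out", "simulate-images")
  seed <- as.integer(req_arg(opts, "seed", "simulate-images"))
  n_frames <- as.integer(opts$n_frames %||% "1")
  conf <- load_yaml_config(opts$config)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  truth_all <- list()
  for (f in seq_len(n_frames)) {
    cfg <- yaml_to_image_config(conf, derive_seed(seed, paste0("frame", f)))
    fid <- sprintf("frame_%03d", f)
    sim <- simulate_image(cfg, frame_id = fid)
    write_image_stack(sim$stack, file.path(out, fid))
    if (nrow(sim$truth) > 0L) sim$truth$frame_id <- fid
    truth_all[[f]] <- sim$truth
  }
  truth <- do.call(rbind, truth_all)
  write.csv(truth, file.path(out, "ground_truth.csv"), row.names = FALSE)
  log_msg("wrote %d frame(s) and ground_truth.csv to %s", n_frames, out)
}

cmd_simulate_cohort <- function(opts) {
  out <- req_arg(opts, "out", "simulate-cohort")
  seed <- as.integer(req_arg(opts, "seed", "simulate-cohort"))
  conf <- load_yaml_config(opts$config)
  if (!is.null(opts$n_patients)) conf$n_patients <- as.integer(opts$n_patients)
  cfg <- yaml_to_cohort_config(conf, derive_seed(seed, "cohort"))
  sim <- simulate_cohort(cfg)
  write_cohort(sim$cohort, out)
  log_msg("wrote %d-patient cohort to %s", nrow(sim$cohort), out)
}

cmd_detect <- function(opts) {
  indir <- req_arg(opts, "in", "detect")
  out <- req_arg(opts, "out", "detect")
  sidecars <- sort(list.files(indir, pattern = "_meta\\.txt$", full.names = TRUE))
  if (length(sidecars) == 0L) stop("no *_meta.txt image sidecars found in ", indir)
  ps <- if (!is.null(opts$pixel_size)) as.numeric(opts$pixel_size) else NULL
  tabs <- lapply(sidecars, function(sc) {
    stack <- read_image_stack(sub("_meta\\.txt$", "", sc), pixel_size = ps)
    detect(stack)
  })
  ft <- do.call(rbind, tabs)
  dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
  write.table(ft, out, sep = "\t", row.names = FALSE, quote = FALSE)
  log_msg("detected %d object(s) in %d frame(s) -> %s", nrow(ft),
          length(sidecars), out)
}

cmd_gate <- function(opts) {
  infile <- req_arg(opts, "in", "gate")
  out <- req_arg(opts, "out", "gate")
  gates <- if (is.null(opts$gates)) {
    default_gate_set()
  } else {
    if (!file.exists(opts$gates)) stop("gate config not found: ", opts$gates)
    parse_gates(path = opts$gates)
  }
  if (!file.exists(infile)) stop("feature table not found: ", infile)
  ft <- read.delim(infile, check.names = FALSE, stringsAsFactors = FALSE)
  cl <- classify(ft, gates)
  dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
  write.table(cl, out, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(opts$counts)) {
    frames <- if (nrow(cl) > 0L) split(cl, cl$frame_id) else list()
    cnt <- do.call(rbind, lapply(names(frames), function(f) {
      data.frame(frame_id = f, t(count_classes(frames[[f]], gates)),
                 check.names = FALSE)
    }))
    write.csv(cnt, opts$counts, row.names = FALSE)
  }
  log_msg("classified %d object(s) -> %s", nrow(cl), out)
}

cmd_cohort_stats <- function(opts) {
  cohort <- read_cohort(req_arg(opts, "in", "cohort-stats"))
  out <- req_arg(opts, "out", "cohort-stats")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  for (comp in c("ctc", "tdev")) {
    write.csv(cohort_fractions(cohort, comp),
              file.path(out, paste0("fractions_", comp, ".csv")), row.names = FALSE)
    vp <- venn_partition(cohort, comp)
    write.csv(data.frame(pattern = names(vp), n_patients = unname(vp)),
              file.path(out, paste0("venn_", comp, ".csv")), row.names = FALSE)
  }
  het <- data.frame(
    patient_id = cohort$patient_id,
    ctc_classes = vapply(seq_len(nrow(cohort)), function(i)
      heterogeneity_class(cohort[i, ], "ctc"), numeric(1)),
    tdev_classes = vapply(seq_len(nrow(cohort)), function(i)
      heterogeneity_class(cohort[i, ], "tdev"), numeric(1)))
  write.csv(het, file.path(out, "heterogeneity.csv"), row.names = FALSE)
  paired <- do.call(rbind, lapply(EVG_PHENOTYPES, function(ph) {
    pc <- paired_compare(cohort[[paste0("ctc_", ph)]], cohort[[paste0("tdev_", ph)]])
    data.frame(phenotype = ph, spearman_rho = pc$spearman_rho,
               spearman_p = pc$spearman_p, wilcoxon_p = pc$wilcoxon_p, n = pc$n)
  }))
  write.csv(paired, file.path(out, "paired_ctc_vs_tdev.csv"), row.names = FALSE)
  known <- cohort$tissue_her2 %in% c("positive", "negative")
  if (sum(known) >= 4L && length(unique(cohort$tissue_her2[known])) == 2L) {
    grp <- do.call(rbind, lapply(EVG_CLASSES, function(cl) {
      v <- cohort[[cl]][known]
      pos <- cohort$tissue_her2[known] == "positive"
      gc <- group_compare(v[pos], v[!pos])
      data.frame(subclass = cl, U = gc$U, p = gc$p, method = gc$method)
    }))
    write.csv(grp, file.path(out, "group_by_tissue.csv"), row.names = FALSE)
  }
  log_msg("cohort statistics for %d patient(s) -> %s", nrow(cohort), out)
}

# The four count variables the survival analyses dichotomize, with their
# conventional cutoffs: CK+ counts (>= 5 CTCs / >= 20 tdEVs) and CK- counts
# (>= 1 CTC / > 10 i.e. >= 11 tdEVs).
survival_variables <- function(cohort) {
  list(
    ck_pos_ctc  = list(x = cohort$ctc_ck_her2neg + cohort$ctc_ck_her2, cutoff = 5),
    ck_neg_ctc  = list(x = cohort$ctc_ckneg_her2, cutoff = 1),
    ck_pos_tdev = list(x = cohort$tdev_ck_her2neg + cohort$tdev_ck_her2, cutoff = 20),
    ck_neg_tdev = list(x = cohort$tdev_ckneg_her2, cutoff = 11)
  )
}

cmd_survival <- function(opts) {
  cohort <- read_cohort(req_arg(opts, "in", "survival"))
  out <- req_arg(opts, "out", "survival")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  has_os <- !is.na(cohort$os_days)
  if (sum(has_os) < 2L) stop("survival analysis needs >= 2 patients with follow-up")
  times <- cohort$os_days[has_os]; events <- cohort$event[has_os]
  vars <- survival_variables(cohort[has_os, ])
  cox_rows <- list(); km_rows <- list(); lr_rows <- list()
  for (nm in names(vars)) {
    v <- vars[[nm]]
    fit <- cox_univariable(v$x, times, events, transform = "log10p1")
    cox_rows[[nm]] <- data.frame(variable = nm, beta = fit$beta, hr = fit$hr,
                                 ci_lower = fit$ci_lower, ci_upper = fit$ci_upper,
                                 p = fit$p, n = fit$n, n_events = fit$n_events,
                                 flag = fit$flag)
    grp <- ifelse(v$x >= v$cutoff, sprintf(">=%d", v$cutoff), sprintf("<%d", v$cutoff))
    if (length(unique(grp)) == 2L) {
      km <- km_estimate(times, events, grp)
      km$variable <- nm
      km_rows[[nm]] <- km
      lr <- logrank(times, events, grp)
      lr_rows[[nm]] <- data.frame(variable = nm, cutoff = v$cutoff,
                                  chisq = lr$statistic, p = lr$p)
    }
    scan <- cutoff_scan(v$x, times, events)
    write.csv(scan, file.path(out, paste0("cutoff_scan_", nm, ".csv")),
              row.names = FALSE)
  }
  write.csv(do.call(rbind, cox_rows), file.path(out, "cox_univariable.csv"),
            row.names = FALSE)
  if (length(km_rows) > 0L) {
    write.csv(do.call(rbind, km_rows), file.path(out, "km_curves.csv"),
              row.names = FALSE)
    write.csv(do.call(rbind, lr_rows), file.path(out, "logrank.csv"),
              row.names = FALSE)
  }
  log_msg("survival analysis for %d patient(s) -> %s", sum(has_os), out)
}

cmd_roc <- function(opts) {
  cohort <- read_cohort(req_arg(opts, "in", "roc"))
  out <- req_arg(opts, "out", "roc")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  known <- cohort$tissue_her2 %in% c("positive", "negative")
  res <- list()
  for (comp in c("ctc", "tdev")) {
    fr <- cohort_fractions(cohort, comp)
    el <- known & !is.na(fr$pct_ck_her2)
    if (length(unique(cohort$tissue_her2[el])) < 2L) next
    roc <- roc_curve(fr$pct_ck_her2[el], cohort$tissue_her2[el])
    thr <- sens_eq_spec_threshold(roc)
    write.csv(data.frame(threshold = roc$thresholds,
                         sensitivity = roc$sensitivity,
                         specificity = roc$specificity),
              file.path(out, paste0("roc_", comp, ".csv")), row.names = FALSE)
    write.csv(accuracy_by_min_count(cohort, comp, max(thr$threshold, 1e-6)),
              file.path(out, paste0("accuracy_by_min_count_", comp, ".csv")),
              row.names = FALSE)
    res[[comp]] <- data.frame(compartment = comp, auc = roc$auc,
                              n_pos = roc$n_pos, n_neg = roc$n_neg,
                              threshold_pct = thr$threshold,
                              sensitivity = thr$sensitivity,
                              specificity = thr$specificity)
  }
  if (length(res) == 0L) stop("no compartment with both tissue classes present")
  write.csv(do.call(rbind, res), file.path(out, "roc_summary.csv"),
            row.names = FALSE)
  if (length(res) == 2L) {
    frc <- cohort_fractions(cohort, "ctc"); frt <- cohort_fractions(cohort, "tdev")
    el <- known & !is.na(frc$pct_ck_her2) & !is.na(frt$pct_ck_her2)
    if (length(unique(cohort$tissue_her2[el])) == 2L) {
      dl <- delong_compare(frc$pct_ck_her2[el], frt$pct_ck_her2[el],
                           cohort$tissue_her2[el])
      write.csv(data.frame(auc_ctc = dl$auc_a, auc_tdev = dl$auc_b,
                           diff = dl$diff, var_diff = dl$var_diff, z = dl$z,
                           p = dl$p, flag = dl$flag),
                file.path(out, "delong_ctc_vs_tdev.csv"), row.names = FALSE)
    }
  }
  log_msg("ROC analysis -> %s", out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
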