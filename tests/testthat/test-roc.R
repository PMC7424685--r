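test_that("ROC handles separation and full ties per convention", {
  roc <- roc_curve(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(roc$auc, 1)
  roc <- roc_curve(rep(5, 10), rep(c(0, 1), 5))
  expect_equal(roc$auc, 0.5)
  expect_error(roc_curve(1:5, rep(1, 5)), "both label classes")
})

test_that("trapezoid AUC equals the mid-rank Mann-Whitney identity", {
  set.seed(50)
  for (rep in 1:25) {
    n <- sample(20:120, 1)
    scores <- round(runif(n, 0, 10), sample(c(0, 1, 3), 1))  # induce ties
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) == 0 || sum(labels) == n) next
    roc <- roc_curve(scores, labels)
    # trapezoid area from the curve points themselves
    fpr <- c(1 - roc$specificity, 1); tpr <- c(roc$sensitivity, 1)
    o <- order(fpr, tpr)
    trap <- sum(diff(fpr[o]) * (head(tpr[o], -1) + tail(tpr[o], -1)) / 2)
    # mid-rank U
    r <- rank(scores)
    np <- sum(labels); nn <- n - np
    u <- (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
    expect_equal(roc$auc, u, tolerance = 1e-12)
    expect_equal(trap, u, tolerance = 1e-12)
  }
})

test_that("AUC is invariant under monotone transforms and flips with negation", {
  set.seed(51)
  s <- rnorm(100); l <- rbinom(100, 1, 0.5)
  a <- roc_curve(s, l)$auc
  expect_equal(roc_curve(exp(s) + 5, l)$auc, a)
  expect_equal(roc_curve(-s, l)$auc, 1 - a)
})

test_that("ROC points are monotone", {
  set.seed(52)
  roc <- roc_curve(rnorm(60), rbinom(60, 1, 0.5))
  expect_true(all(diff(roc$sensitivity) >= 0))
  expect_true(all(diff(roc$specificity) <= 0))
})

test_that("DeLong self-comparison and rank-invariance give zero difference", {
  set.seed(60)
  s <- rnorm(80); l <- rbinom(80, 1, 0.5)
  dl <- delong_compare(s, s, l)
  expect_equal(dl$diff, 0)
  expect_equal(dl$p, 1)
  expect_equal(dl$flag, "identical_rankings")
  dl <- delong_compare(s, 3 * s + 7, l)
  expect_equal(dl$diff, 0)
})

test_that("DeLong agrees with the reference implementation in pROC", {
  set.seed(61)
  for (rep in 1:5) {
    n <- 120
    l <- rbinom(n, 1, 0.45)
    base <- rnorm(n) + l
    a <- base + rnorm(n, sd = 0.7)
    b <- 0.5 * base + rnorm(n, sd = 0.9)
    dl <- delong_compare(a, b, l)
    ref <- pROC::roc.test(pROC::roc(l, a, quiet = TRUE),
                          pROC::roc(l, b, quiet = TRUE),
                          method = "delong", paired = TRUE)
    expect_equal(dl$p, ref$p.value, tolerance = 1e-9)
    expect_equal(abs(dl$z), abs(unname(ref$statistic)), tolerance = 1e-9)
    # single-curve variance against pROC's DeLong variance
    expect_equal(auc_delong_variance(a, l),
                 pROC::var(pROC::roc(l, a, quiet = TRUE), method = "delong"),
                 tolerance = 1e-9)
  }
})

test_that("sens~spec threshold matches exhaustive enumeration", {
  set.seed(70)
  for (rep in 1:10) {
    s <- round(runif(60, 0, 50), 1); l <- rbinom(60, 1, 0.4)
    if (length(unique(l)) < 2) next
    roc <- roc_curve(s, l)
    ch <- sens_eq_spec_threshold(roc)
    # brute force over all thresholds
    gaps <- vapply(roc$thresholds, function(t) {
      abs(mean(s[l == 1] >= t) - mean(s[l == 0] < t))
    }, numeric(1))
    expect_equal(ch$gap, min(gaps), tolerance = 1e-12)
    best <- which(abs(gaps - min(gaps)) < 1e-12)
    expect_gte(ch$specificity, max(roc$specificity[best]) - 1e-12)
  }
  # perfect separation: the largest separating threshold is chosen
  roc <- roc_curve(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  ch <- sens_eq_spec_threshold(roc)
  expect_equal(ch$sensitivity, 1)
  expect_equal(ch$specificity, 1)
  expect_equal(ch$threshold, 10)
})

test_that("accuracy by minimum count matches a confusion-matrix oracle", {
  sim <- simulate_cohort(cohort_sim_config(n_patients = 300, seed = 55))
  co <- sim$cohort
  tab <- accuracy_by_min_count(co, "tdev", 7)
  expect_equal(tab$min_total, c(1, 5, 10, 20, 50, 100))
  expect_true(all(diff(tab$n_eligible) <= 0))
  fr <- cohort_fractions(co, "tdev")
  for (i in seq_len(nrow(tab))) {
    el <- co$tissue_her2 %in% c("positive", "negative") &
      fr$total >= tab$min_total[i] & !is.na(fr$pct_ck_her2)
    if (sum(el) == 0) next
    pred <- fr$pct_ck_her2[el] >= 7
    tp <- sum(pred & co$tissue_her2[el] == "positive")
    tn <- sum(!pred & co$tissue_her2[el] == "negative")
    fp <- sum(pred & co$tissue_her2[el] == "negative")
    fn <- sum(!pred & co$tissue_her2[el] == "positive")
    expect_equal(tab$n_eligible[i], tp + tn + fp + fn)
    expect_equal(tab$accuracy[i], (tp + tn) / (tp + tn + fp + fn))
    expect_equal(tab$sensitivity[i], tp / (tp + fn))
    expect_equal(tab$specificity[i], tn / (tn + fp))
  }
  # perfectly ordered cohort: accuracy 1 in every stratum
  co2 <- co[1:40, ]
  co2$tdev_ck_her2 <- c(rep(0, 20), rep(50, 20))
  co2$tdev_ck_her2neg <- 50
  co2$tdev_ckneg_her2 <- 0
  co2$tissue_her2 <- rep(c("negative", "positive"), each = 20)
  tab2 <- accuracy_by_min_count(co2, "tdev", 7)
  expect_true(all(tab2$accuracy[tab2$n_eligible > 0] == 1))
})
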