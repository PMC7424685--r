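rec <- function(ctc = c(0, 0, 0), tdev = c(0, 0, 0)) {
  setNames(as.list(c(ctc, tdev)),
           c("ctc_ck_her2neg", "ctc_ckneg_her2", "ctc_ck_her2",
             "tdev_ck_her2neg", "tdev_ckneg_her2", "tdev_ck_her2"))
}

test_that("class fractions are percentages of the compartment total", {
  f <- class_fractions(rec(ctc = c(10, 5, 5)), "ctc")
  expect_equal(unname(f), c(50, 25, 25))
  expect_equal(unname(f["pct_ck_her2"]), 25)  # %HER2+CK+
  f <- class_fractions(rec(ctc = c(7, 0, 0)), "ctc")
  expect_equal(unname(f), c(100, 0, 0))
  expect_equal(sum(f), 100)
  expect_warning(f0 <- class_fractions(rec(), "ctc"), "undefined")
  expect_true(all(is.na(f0)))
})

test_that("heterogeneity class applies the strict presence threshold", {
  expect_equal(heterogeneity_class(rec(tdev = c(15, 3, 12)), "tdev"), 2)
  expect_equal(heterogeneity_class(rec(tdev = c(10, 10, 10)), "tdev"), 0)
  expect_equal(heterogeneity_class(rec(ctc = c(1, 1, 1)), "ctc"), 3)
  expect_equal(heterogeneity_class(rec(tdev = c(11, 11, 11)), "tdev"), 3)
  # monotone in counts, non-increasing in threshold
  expect_gte(heterogeneity_class(rec(tdev = c(20, 3, 12)), "tdev"),
             heterogeneity_class(rec(tdev = c(15, 3, 12)), "tdev"))
  expect_gte(heterogeneity_class(rec(tdev = c(15, 3, 12)), "tdev", 5),
             heterogeneity_class(rec(tdev = c(15, 3, 12)), "tdev", 10))
})

test_that("venn partition equals exhaustive per-patient set computation", {
  set.seed(10)
  n <- 200
  co <- data.frame(patient_id = sprintf("P%03d", 1:n),
                   ctc_ck_her2neg = rpois(n, 2), ctc_ckneg_her2 = rpois(n, 1),
                   ctc_ck_her2 = rpois(n, 1), tdev_ck_her2neg = rpois(n, 15),
                   tdev_ckneg_her2 = rpois(n, 8), tdev_ck_her2 = rpois(n, 8))
  for (comp in c("ctc", "tdev")) {
    thr <- if (comp == "ctc") 0 else 10
    vp <- venn_partition(co, comp)
    expect_equal(sum(vp), n)
    # exhaustive oracle
    cols <- paste0(comp, "_", c("ck_her2neg", "ckneg_her2", "ck_her2"))
    for (i in 1:n) {
      p <- as.numeric(co[i, cols]) > thr
      key <- if (!any(p)) "none" else if (all(p)) "all" else
        paste(c("ck_her2neg", "ckneg_her2", "ck_her2")[p], collapse = "+")
      vp[key] <- vp[key] - 1L
    }
    expect_true(all(vp == 0L))
    # marginal consistency: patterns containing class k sum to its presence
    vp <- venn_partition(co, comp)
    for (k in c("ck_her2neg", "ckneg_her2", "ck_her2")) {
      has_k <- vapply(strsplit(names(vp), "\\+"), function(p) k %in% p, logical(1))
      marg <- sum(vp[has_k | names(vp) == "all"])
      expect_equal(marg, sum(co[[paste0(comp, "_", k)]] > thr))
    }
  }
  all_zero <- co; all_zero[, -1] <- 0
  expect_equal(unname(venn_partition(all_zero, "ctc")["none"]), n)
})

test_that("paired comparison recovers monotone association and degeneracy", {
  x <- c(1, 4, 9, 16, 25, 37)
  pc <- paired_compare(x, x^3 + 2)
  expect_equal(pc$spearman_rho, 1)
  pc <- paired_compare(x, x)      # no non-zero differences
  expect_true(is.na(pc$wilcoxon_p))
  pc <- paired_compare(rep(1, 5), c(1, 2, 3, 4, 5))
  expect_true(is.na(pc$spearman_rho))
})

test_that("spearman rho matches the rank-formula oracle", {
  set.seed(20)
  for (rep in 1:10) {
    x <- rpois(20, 5); y <- rpois(20, 5) + x
    rho <- paired_compare(x, y)$spearman_rho
    rx <- rank(x); ry <- rank(y)
    ora <- sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
    expect_equal(rho, ora, tolerance = 1e-12)
  }
})

test_that("signed-rank p agrees with the classical test when there are no ties", {
  set.seed(30)
  x <- rnorm(40); y <- x + rnorm(40, 0.4)
  p_pkg <- paired_compare(x, y, zero_method = "wilcoxon")$wilcoxon_p
  p_ref <- wilcox.test(y, x, paired = TRUE, exact = FALSE, correct = FALSE)$p.value
  expect_equal(p_pkg, p_ref, tolerance = 1e-10)
})

test_that("Mann-Whitney U matches the pairwise-comparison oracle", {
  set.seed(15)
  for (rep in 1:10) {
    x <- rpois(12, 4); y <- rpois(15, 6)
    gc <- group_compare(x, y)
    u_ora <- 0
    for (xi in x) for (yj in y) {
      u_ora <- u_ora + (xi > yj) + 0.5 * (xi == yj)
    }
    expect_equal(gc$U, u_ora)
  }
})

test_that("exact Mann-Whitney handles separation and identical groups", {
  gc <- group_compare(c(10, 11, 12), c(1, 2, 3))
  expect_equal(gc$U, 9)
  expect_equal(gc$p, 0.1)       # 2/20 orderings as extreme
  expect_equal(gc$method, "exact")
  gc <- group_compare(c(1, 2, 2, 5), c(2, 5, 1, 2))  # identical multisets
  expect_equal(gc$p, 1)
  expect_error(group_compare(numeric(0), 1:3), "non-empty")
})

test_that("large-sample Mann-Whitney agrees with the normal-approximation test", {
  set.seed(16)
  x <- rnorm(60); y <- rnorm(70, 0.3)
  gc <- group_compare(x, y)
  expect_equal(gc$method, "normal")
  ref <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(gc$U, unname(ref$statistic))
  expect_equal(gc$p, ref$p.value, tolerance = 1e-10)
})
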