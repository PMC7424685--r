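test_that("the shipped gate config parses to the default gate set", {
  path <- system.file("extdata", "default_gates.txt", package = "evgate")
  gs <- parse_gates(path = path)
  expect_s3_class(gs, "evg_gate_set")
  expect_identical(names(gs$gates),
                   c("ctc_ck_her2neg", "ctc_ckneg_her2", "ctc_ck_her2",
                     "tdev_ck_her2neg", "tdev_ckneg_her2", "tdev_ck_her2"))
  def <- default_gate_set()
  for (nm in names(def$gates)) {
    expect_equal(gs$gates[[nm]]$clauses[order(gs$gates[[nm]]$clauses$feature,
                                              gs$gates[[nm]]$clauses$op), ],
                 def$gates[[nm]]$clauses[order(def$gates[[nm]]$clauses$feature,
                                               def$gates[[nm]]$clauses$op), ],
                 ignore_attr = TRUE)
  }
})

test_that("parse errors name the offending line or feature", {
  expect_error(parse_gates(c("class a", "  CK.mean_int >= ")), "malformed")
  expect_error(parse_gates(c("class a", "  foo.bar >= 1")), "valid features")
  expect_error(parse_gates(c("class a", "  CK.mean_int >= 1",
                             "class a", "  CK.mean_int < 2")), "duplicate")
  expect_error(parse_gates(c("CK.mean_int >= 1")), "malformed")
  expect_error(parse_gates(character(0)), "no classes")
})

test_that("serialize-then-parse reproduces random gate sets", {
  set.seed(99)
  vocab <- gate_feature_vocabulary()
  for (rep in 1:20) {
    gates <- lapply(seq_len(sample(1:5, 1)), function(i) {
      k <- sample(1:4, 1)
      linear_gate(paste0("class_", i),
                  data.frame(feature = sample(vocab, k, replace = TRUE),
                             op = sample(c("<", "<=", ">", ">="), k, replace = TRUE),
                             value = round(runif(k, -10, 4000), 6)))
    })
    gs <- gate_set(gates, policy = sample(c("first_match", "error_on_multimatch"), 1))
    back <- parse_gates(serialize_gates(gs))
    expect_equal(back, gs)
  }
})

test_that("apply_gate agrees with brute-force clause evaluation", {
  set.seed(12)
  tab <- random_feature_table(500)
  vocab <- gate_feature_vocabulary()
  for (rep in 1:20) {
    k <- sample(1:4, 1)
    g <- linear_gate("g", data.frame(
      feature = sample(vocab, k), op = sample(c("<", "<=", ">", ">="), k, TRUE),
      value = runif(k, 0, 2000)))
    got <- apply_gate(g, tab)
    ora <- vapply(seq_len(nrow(tab)), function(i) {
      all(vapply(seq_len(k), function(j) {
        v <- tab[[g$clauses$feature[j]]][i]
        if (is.na(v)) return(FALSE)
        switch(g$clauses$op[j], "<" = v < g$clauses$value[j],
               "<=" = v <= g$clauses$value[j], ">" = v > g$clauses$value[j],
               ">=" = v >= g$clauses$value[j])
      }, logical(1)))
    }, logical(1))
    expect_identical(got, ora)
  }
})

test_that("degenerate gates behave sanely", {
  tab <- random_feature_table(50)
  g <- linear_gate("impossible", data.frame(
    feature = c("CK.mean_int", "CK.mean_int"), op = c(">", "<"), value = c(5, 3)))
  expect_false(any(apply_gate(g, tab)))
  expect_length(apply_gate(g, tab[0, ]), 0L)
})

test_that("classification follows the printed class definitions", {
  base <- random_feature_table(1)[, ]
  set_feats <- function(row, dna, cd45, ck, her2, diam, ck_ov = 0.9, her2_ov = 0.9) {
    row[["DNA.mean_int"]] <- dna; row[["CD45.mean_int"]] <- cd45
    row[["CK.mean_int"]] <- ck; row[["HER2.mean_int"]] <- her2
    row[["object.eq_diameter_um"]] <- diam
    row[["CK.dna_overlap"]] <- ck_ov; row[["HER2.dna_overlap"]] <- her2_ov
    row
  }
  # nucleated, CD45-, CK+, HER2-, 8 um, strong CK-DNA overlap -> CK+HER2- CTC
  r <- set_feats(base, 3000, 40, 2800, 60, 8)
  expect_equal(classify(r)$class, "ctc_ck_her2neg")
  # anucleate, CD45-, HER2+, 2 um -> CK-HER2+ tdEV
  r <- set_feats(base, 40, 40, 60, 2500, 2)
  expect_equal(classify(r)$class, "tdev_ckneg_her2")
  # CD45-positive objects are never assigned a tumor class
  r <- set_feats(base, 3000, 2800, 2800, 2500, 8)
  expect_equal(classify(r)$class, "unclassified")
  # nucleated double positive of CTC size -> CK+HER2+ CTC
  r <- set_feats(base, 3000, 40, 2800, 2500, 8)
  expect_equal(classify(r)$class, "ctc_ck_her2")
  # low CK-DNA overlap disqualifies the CTC gate
  r <- set_feats(base, 3000, 40, 2800, 60, 8, ck_ov = 0.2)
  expect_equal(classify(r)$class, "unclassified")
})

test_that("the six default gates are mutually exclusive on random tables", {
  set.seed(5)
  tab <- random_feature_table(3000)
  def <- default_gate_set()
  pass <- vapply(def$gates, apply_gate, logical(nrow(tab)), table = tab)
  expect_true(all(rowSums(pass) <= 1L))
  # so classification under error-on-multimatch never trips
  strict <- gate_set(unname(def$gates), policy = "error_on_multimatch")
  expect_silent(classify(tab, strict))
})

test_that("classification is row-permutation equivariant and idempotent", {
  set.seed(8)
  tab <- random_feature_table(200)
  cl <- classify(tab)
  perm <- sample(nrow(tab))
  cl_perm <- classify(tab[perm, ])
  expect_identical(cl_perm$class, cl$class[perm])
  expect_identical(classify(cl[, names(tab)])$class, cl$class)
})

test_that("raising a positivity threshold never increases the pass count", {
  set.seed(44)
  tab <- random_feature_table(800)
  for (thr in c(50, 150, 500, 1500, 3000)) {
    g <- linear_gate("g", data.frame(feature = "CK.mean_int", op = ">=", value = thr))
    if (thr == 50) prev <- sum(apply_gate(g, tab))
    cur <- sum(apply_gate(g, tab))
    expect_lte(cur, prev)
    prev <- cur
  }
})

test_that("count_classes tallies labels exactly", {
  def <- default_gate_set()
  tab <- random_feature_table(100)
  cl <- classify(tab, def)
  cnt <- count_classes(cl, def)
  expect_equal(sum(cnt), nrow(tab))
  expect_identical(unname(cnt[names(cnt) != "unclassified"]),
                   vapply(names(def$gates), function(nm) sum(cl$class == nm),
                          integer(1), USE.NAMES = FALSE))
  empty <- count_classes(classify(tab[0, ], def), def)
  expect_true(all(empty == 0L))
  tab3 <- tab[1:3, ]
  cl3 <- tab3; cl3$class <- "tdev_ck_her2neg"
  expect_equal(unname(count_classes(cl3, def)["tdev_ck_her2neg"]), 3L)
})
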