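test_that("blank and constant images segment to zero objects", {
  expect_equal(max(segment_channel(matrix(0, 64, 64))), 0)
  expect_equal(max(segment_channel(matrix(7, 64, 64))), 0)
})

test_that("components of four or fewer pixels are discarded", {
  img <- matrix(0, 64, 64)
  img[10, 10:12] <- 1000                       # 3-pixel line
  p <- detect_params(smooth_sigma = 0, threshold_method = "fixed",
                     fixed_threshold = 500, refine_frac = 0)
  expect_equal(max(segment_channel(img, p)), 0)
  img[20, 20:24] <- 1000                       # 5-pixel line survives
  expect_equal(max(segment_channel(img, p)), 1)
})

test_that("well-separated simulated disks are each recovered with true area", {
  # five CTC-sized disks of 8 px diameter (5.12 um at 0.64 um/px)
  cfg <- image_sim_config(object_counts = c(ctc_ck = 5),
                          diameter_um = list(ctc_ck = c(5.12, 5.12)), seed = 14)
  sim <- simulate_image(cfg)
  lab <- segment_channel(sim$stack$channels$CK)
  expect_equal(max(lab), 5)
  true_area <- pi * 4^2  # px^2
  for (k in 1:5) {
    expect_lt(abs(sum(lab == k) - true_area) / true_area, 0.15)
  }
})

test_that("labeling is 8-connected", {
  m <- matrix(0, 10, 10)
  m[2, 2] <- 1; m[3, 3] <- 1          # diagonal touch: one component
  m[7, 2] <- 1; m[7, 4] <- 1          # one-pixel gap: two components
  lab <- evgate:::label_components(m)
  expect_equal(lab[2, 2], lab[3, 3])
  expect_true(lab[7, 2] != lab[7, 4])
  expect_equal(max(lab), 3)
})

test_that("merge_channels builds objects with per-channel sub-masks", {
  d <- c(20L, 20L)
  blank <- matrix(0L, d[1], d[2])
  ck <- blank; ck[5:7, 5:7] <- 1L
  her2 <- blank; her2[5:7, 5:7] <- 1L             # coincident with CK
  ck2 <- ck; ck2[15, 10] <- 1L; ck2[15, 12] <- 1L  # two isolated single px
  masks <- list(DNA = blank, CK = ck, CD45 = blank, HER2 = blank)
  objs <- merge_channels(masks)
  expect_length(objs, 1L)
  expect_setequal(objs[[1]]$channel_pixels$CK, objs[[1]]$pixels)
  expect_length(objs[[1]]$channel_pixels$HER2, 0L)

  objs <- merge_channels(list(DNA = blank, CK = ck, CD45 = blank, HER2 = her2))
  expect_length(objs, 1L)
  expect_setequal(objs[[1]]$channel_pixels$HER2, objs[[1]]$pixels)

  # blobs one pixel apart are not 8-connected: distinct objects
  objs <- merge_channels(list(DNA = blank, CK = ck2, CD45 = blank, HER2 = blank))
  expect_length(objs, 3L)
})

test_that("uniform disks give exact intensity features and zero eccentricity", {
  d <- c(40L, 40L)
  rc <- as.matrix(expand.grid(r = 1:40, c = 1:40))
  disk <- rc[(rc[, 1] - 20)^2 + (rc[, 2] - 20)^2 <= 36, ]
  chans <- lapply(setNames(c("DNA", "CK", "CD45", "HER2"),
                           c("DNA", "CK", "CD45", "HER2")),
                  function(ch) matrix(100, 40, 40))
  env <- make_object(disk, list(CK = disk), dim = d, channels = chans)
  f <- extract_features(env$obj, env$stack)
  expect_equal(f[["CK.mean_int"]], 100)
  expect_equal(f[["CK.sd_int"]], 0)
  expect_equal(f[["CK.eccentricity"]], 0)
  expect_equal(f[["CK.area_um2"]], nrow(disk) * 0.64^2)
  expect_equal(f[["CK.dna_overlap"]], 0)      # no DNA sub-mask
  expect_equal(f[["DNA.mean_int"]], 100)       # union intensity still defined
  expect_true(is.na(f[["DNA.area_um2"]]))      # geometry absent, not zero
})

test_that("features match the naive per-pixel oracle on random masks", {
  set.seed(42)
  for (rep in 1:60) {
    union_rc <- random_mask_rc(50)
    sub <- union_rc[runif(nrow(union_rc)) < 0.7, , drop = FALSE]
    dna <- union_rc[runif(nrow(union_rc)) < 0.5, , drop = FALSE]
    chans <- lapply(setNames(c("DNA", "CK", "CD45", "HER2"),
                             c("DNA", "CK", "CD45", "HER2")),
                    function(ch) matrix(runif(1600, 0, 4000), 40, 40))
    env <- make_object(union_rc, list(CK = sub, DNA = dna), channels = chans)
    f <- extract_features(env$obj, env$stack)
    vals <- chans$CK[rc_to_lin(union_rc, c(40L, 40L))]
    ora <- naive_channel_features(sub, union_rc, dna, vals, 0.64)
    for (feat in names(ora)) {
      got <- f[[paste0("CK.", feat)]]
      if (is.na(ora[[feat]])) expect_true(is.na(got))
      else expect_equal(got, ora[[feat]], tolerance = 1e-12)
    }
  }
})

test_that("geometry scales correctly with pixel size", {
  rc <- random_mask_rc(30)
  e1 <- make_object(rc, list(CK = rc), pixel_size = 0.64)
  e2 <- make_object(rc, list(CK = rc), pixel_size = 1.28)
  f1 <- extract_features(e1$obj, e1$stack)
  f2 <- extract_features(e2$obj, e2$stack)
  expect_equal(f2[["CK.perimeter_um"]], 2 * f1[["CK.perimeter_um"]])
  expect_equal(f2[["CK.area_um2"]], 4 * f1[["CK.area_um2"]])
  expect_equal(f2[["CK.eccentricity"]], f1[["CK.eccentricity"]])
})

test_that("a constant intensity shift moves mean and max but not sd or geometry", {
  set.seed(7)
  rc <- random_mask_rc(40)
  chans <- lapply(setNames(c("DNA", "CK", "CD45", "HER2"),
                           c("DNA", "CK", "CD45", "HER2")),
                  function(ch) matrix(runif(1600, 0, 1000), 40, 40))
  e1 <- make_object(rc, list(CK = rc), channels = chans)
  chans2 <- chans
  chans2$CK <- chans$CK + 250
  e2 <- make_object(rc, list(CK = rc), channels = chans2)
  f1 <- extract_features(e1$obj, e1$stack)
  f2 <- extract_features(e2$obj, e2$stack)
  expect_equal(f2[["CK.mean_int"]], f1[["CK.mean_int"]] + 250)
  expect_equal(f2[["CK.max_int"]], f1[["CK.max_int"]] + 250)
  expect_equal(f2[["CK.sd_int"]], f1[["CK.sd_int"]])
  expect_equal(f2[["CK.perimeter_um"]], f1[["CK.perimeter_um"]])
})

test_that("area responds monotonically to dilation and erosion", {
  set.seed(3)
  for (rep in 1:5) {
    rc <- random_mask_rc(40)
    m <- matrix(0, 40, 40)
    m[rc] <- 1
    kern <- matrix(1, 3, 3)
    dil <- EBImage::dilate(m, kern)
    ero <- EBImage::erode(m, kern)
    a <- function(mm) sum(mm > 0)
    expect_gte(a(dil), a(m))
    expect_lte(a(ero), a(m))
  }
})

test_that("detect is deterministic and returns the full header when empty", {
  cfg <- image_sim_config(object_counts = c(tdev_ck = 3), seed = 6,
                          frame_size = c(96, 96))
  sim <- simulate_image(cfg)
  expect_identical(detect(sim$stack), detect(sim$stack))

  blank <- image_stack(lapply(setNames(c("DNA", "CK", "CD45", "HER2"),
                                       c("DNA", "CK", "CD45", "HER2")),
                              function(ch) matrix(10, 64, 64)))
  ft <- detect(blank)
  expect_equal(nrow(ft), 0L)
  expect_identical(names(ft), feature_columns())
})

test_that("detection recovers simulated objects at default SNR", {
  cfg <- image_sim_config(seed = 101)
  sim <- simulate_image(cfg)
  ft <- detect(sim$stack)
  m <- match_detections(ft, sim$truth, cfg$pixel_size)
  expect_gte(m$tp / m$n_truth, 0.95)
  expect_gte((m$n_det - m$fp) / m$n_det, 0.95)
})
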