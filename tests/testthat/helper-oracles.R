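# Independent reference implementations used as oracles. Deliberately naive:
# explicit per-pixel / per-row loops, no shared code with the package.

# All 10 features of one channel, from first principles.
naive_channel_features <- function(sub_rc, union_rc, dna_rc, values_union,
                                   pixel_size) {
  n <- nrow(sub_rc)
  out <- list()
  if (n == 0L) {
    out$area_um2 <- NA_real_; out$perimeter_um <- NA_real_
    out$eccentricity <- NA_real_; out$perim_area_ratio <- NA_real_
    out$eq_diameter_um <- NA_real_
  } else {
    area <- n * pixel_size^2
    per <- naive_crofton(sub_rc) * pixel_size
    out$area_um2 <- area
    out$perimeter_um <- per
    out$eccentricity <- naive_eccentricity(sub_rc)
    out$perim_area_ratio <- per / area
    out$eq_diameter_um <- 2 * sqrt(area / pi)
  }
  out$mean_int <- mean(values_union)
  out$max_int <- max(values_union)
  out$sd_int <- if (length(values_union) > 1) sd(values_union) else 0
  out$total_int <- sum(values_union)
  if (n == 0L) {
    out$dna_overlap <- 0
  } else {
    inside <- 0
    for (i in seq_len(n)) {
      for (j in seq_len(nrow(dna_rc))) {
        if (sub_rc[i, 1] == dna_rc[j, 1] && sub_rc[i, 2] == dna_rc[j, 2]) {
          inside <- inside + 1
          break
        }
      }
    }
    out$dna_overlap <- inside / n
  }
  out
}

# Crofton perimeter by explicitly walking every scan line in the four
# directions and counting foreground/background transitions.
naive_crofton <- function(rc) {
  # constant-time membership lookup (offset table); the scan-line walk
  # below stays fully explicit
  off_r <- min(rc[, 1]) - 2L; off_c <- min(rc[, 2]) - 2L
  M <- matrix(FALSE, max(rc[, 1]) - off_r + 2L, max(rc[, 2]) - off_c + 2L)
  for (i in seq_len(nrow(rc))) M[rc[i, 1] - off_r, rc[i, 2] - off_c] <- TRUE
  has <- function(r, c) {
    ri <- r - off_r; ci <- c - off_c
    ri >= 1 && ci >= 1 && ri <= nrow(M) && ci <= ncol(M) && M[ri, ci]
  }
  r_rng <- (min(rc[, 1]) - 1):(max(rc[, 1]) + 1)
  c_rng <- (min(rc[, 2]) - 1):(max(rc[, 2]) + 1)
  nh <- 0  # horizontal neighbour pairs differing
  for (r in r_rng) {
    prev <- FALSE
    for (c in c_rng) {
      cur <- has(r, c)
      if (cur != prev) nh <- nh + 1
      prev <- cur
    }
    if (prev) nh <- nh + 1
  }
  nv <- 0
  for (c in c_rng) {
    prev <- FALSE
    for (r in r_rng) {
      cur <- has(r, c)
      if (cur != prev) nv <- nv + 1
      prev <- cur
    }
    if (prev) nv <- nv + 1
  }
  # diagonal scan lines (down-right): constant r - c
  nd1 <- 0
  for (d in (min(rc[, 1] - rc[, 2]) - 1):(max(rc[, 1] - rc[, 2]) + 1)) {
    prev <- FALSE
    for (r in r_rng) {
      c <- r - d
      cur <- has(r, c)
      if (cur != prev) nd1 <- nd1 + 1
      prev <- cur
    }
    if (prev) nd1 <- nd1 + 1
  }
  # anti-diagonal (down-left): constant r + c
  nd2 <- 0
  for (s in (min(rc[, 1] + rc[, 2]) - 1):(max(rc[, 1] + rc[, 2]) + 1)) {
    prev <- FALSE
    for (r in r_rng) {
      c <- s - r
      cur <- has(r, c)
      if (cur != prev) nd2 <- nd2 + 1
      prev <- cur
    }
    if (prev) nd2 <- nd2 + 1
  }
  (pi / 4) * (nh / 2 + nv / 2 + (nd1 + nd2) / (2 * sqrt(2)))
}

naive_eccentricity <- function(rc) {
  n <- nrow(rc)
  rbar <- sum(rc[, 1]) / n
  cbar <- sum(rc[, 2]) / n
  m20 <- 1 / 12; m02 <- 1 / 12; m11 <- 0
  for (i in seq_len(n)) {
    m20 <- m20 + (rc[i, 1] - rbar)^2 / n
    m02 <- m02 + (rc[i, 2] - cbar)^2 / n
    m11 <- m11 + (rc[i, 1] - rbar) * (rc[i, 2] - cbar) / n
  }
  tr <- m20 + m02
  det <- m20 * m02 - m11^2
  l1 <- tr / 2 + sqrt(max(0, tr^2 / 4 - det))
  l2 <- tr / 2 - sqrt(max(0, tr^2 / 4 - det))
  sqrt(max(0, 1 - l2 / l1))
}

# Random connected pixel mask of up to max_px pixels (grown by random
# accretion so masks are 8-connected and irregular).
random_mask_rc <- function(max_px, dim = c(40L, 40L)) {
  n <- sample(1:max_px, 1)
  rc <- matrix(c(sample(5:(dim[1] - 5), 1), sample(5:(dim[2] - 5), 1)), 1, 2)
  while (nrow(rc) < n) {
    base <- rc[sample(nrow(rc), 1), ]
    cand <- base + sample(c(-1L, 0L, 1L), 2, replace = TRUE)
    if (cand[1] < 2 || cand[2] < 2 || cand[1] > dim[1] - 1 || cand[2] > dim[2] - 1) next
    if (!any(rc[, 1] == cand[1] & rc[, 2] == cand[2])) rc <- rbind(rc, cand)
  }
  unname(rc)
}

rc_to_lin <- function(rc, dim) (rc[, 2] - 1L) * dim[1] + rc[, 1]

# Build a synthetic object (merge_channels-shaped) plus a stack holding
# given channel images.
make_object <- function(union_rc, channel_rcs, dim = c(40L, 40L),
                        channels = NULL, pixel_size = 0.64) {
  if (is.null(channels)) {
    channels <- lapply(setNames(c("DNA", "CK", "CD45", "HER2"),
                                c("DNA", "CK", "CD45", "HER2")),
                       function(ch) matrix(100, dim[1], dim[2]))
  }
  stack <- image_stack(channels, pixel_size = pixel_size, frame_id = "t")
  chp <- lapply(setNames(c("DNA", "CK", "CD45", "HER2"),
                         c("DNA", "CK", "CD45", "HER2")),
                function(ch) {
                  rc <- channel_rcs[[ch]]
                  if (is.null(rc)) integer(0) else rc_to_lin(rc, dim)
                })
  obj <- list(object_id = 1L, dim = dim, pixels = rc_to_lin(union_rc, dim),
              channel_pixels = chp)
  list(obj = obj, stack = stack)
}

# Brute-force gate-set classification: per row, per gate, per clause.
brute_force_classify <- function(table, gates) {
  out <- character(nrow(table))
  for (i in seq_len(nrow(table))) {
    label <- "unclassified"
    for (g in gates$gates) {
      all_ok <- TRUE
      for (j in seq_len(nrow(g$clauses))) {
        v <- table[[g$clauses$feature[j]]][i]
        t <- g$clauses$value[j]
        ok <- if (is.na(v)) FALSE
        else if (g$clauses$op[j] == "<") v < t
        else if (g$clauses$op[j] == "<=") v <= t
        else if (g$clauses$op[j] == ">") v > t
        else v >= t
        if (!ok) { all_ok <- FALSE; break }
      }
      if (all_ok) { label <- g$name; break }
    }
    out[i] <- label
  }
  out
}

# Random feature table with plausible ranges and some missing geometry.
random_feature_table <- function(n) {
  tab <- data.frame(frame_id = "f", object_id = seq_len(n),
                    n_pixels = sample(5:500, n, replace = TRUE),
                    centroid_row = runif(n, 1, 100), centroid_col = runif(n, 1, 100),
                    check.names = FALSE, stringsAsFactors = FALSE)
  geom <- function(n) {
    d <- runif(n, 0.5, 20)
    cbind(area_um2 = pi * (d / 2)^2, perimeter_um = pi * d,
          eccentricity = runif(n), perim_area_ratio = 4 / d,
          eq_diameter_um = d)
  }
  g <- geom(n)
  for (f in colnames(g)) tab[[paste0("object.", f)]] <- g[, f]
  tab[["object.dna_overlap"]] <- runif(n)
  for (ch in c("DNA", "CK", "CD45", "HER2")) {
    g <- geom(n)
    absent <- runif(n) < 0.25
    g[absent, ] <- NA
    for (f in colnames(g)) tab[[paste0(ch, ".", f)]] <- g[, f]
    tab[[paste0(ch, ".mean_int")]] <- runif(n, 0, 4000)
    tab[[paste0(ch, ".max_int")]] <- tab[[paste0(ch, ".mean_int")]] * runif(n, 1, 2)
    tab[[paste0(ch, ".sd_int")]] <- runif(n, 0, 300)
    tab[[paste0(ch, ".total_int")]] <- tab[[paste0(ch, ".mean_int")]] * tab$n_pixels
    tab[[paste0(ch, ".dna_overlap")]] <- ifelse(absent, 0, runif(n))
  }
  tab
}

# Match detections to ground truth by centroid distance below the true
# object radius; returns recall / precision counts.
match_detections <- function(ft, truth, pixel_size) {
  truth <- truth[truth$archetype != "debris", , drop = FALSE]
  matched <- rep(FALSE, nrow(truth))
  fp <- 0L
  for (i in seq_len(nrow(ft))) {
    if (nrow(truth) == 0L) { fp <- fp + 1L; next }
    d <- sqrt((truth$centroid_row - ft$centroid_row[i])^2 +
              (truth$centroid_col - ft$centroid_col[i])^2)
    j <- which.min(d)
    if (d[j] < truth$diameter_um[j] / 2 / pixel_size + 1) {
      matched[j] <- TRUE
    } else {
      fp <- fp + 1L
    }
  }
  list(tp = sum(matched), n_truth = nrow(truth), fp = fp, n_det = nrow(ft))
}
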