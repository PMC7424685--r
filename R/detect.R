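#' Detection stage parameters
#'
#' @param smooth_sigma Gaussian smoothing sigma (px) applied before
#'   thresholding.
#' @param threshold_method global threshold on the smoothed,
#'   background-subtracted image: `"triangle"` (histogram triangle method)
#'   or `"fixed"` (use `fixed_threshold`).
#' @param fixed_threshold threshold value when `threshold_method = "fixed"`.
#' @param refine_frac per-component refinement: within each thresholded
#'   component, pixels below `refine_frac` times the component's maximum
#'   (on the smoothed image) are trimmed. This recovers object areas close
#'   to their physical footprint for point-spread-blurred objects (the
#'   half-maximum radius of a blurred disk is its true radius). Set to 0 to
#'   disable.
#' @param min_area_px components with area at or below this many pixels are
#'   discarded; the default 4 implements the "size larger than 4 pixels"
#'   detection rule (strict `> 4`).
#' @param split_touching if `TRUE`, touching objects are split by a
#'   watershed on the distance transform.
#' @param n_bins histogram bins for the triangle threshold.
#' @param min_snr floor on the global threshold, in robust noise units
#'   (median absolute deviations of the smoothed image). Keeps dim
#'   sub-resolution clutter and correlated noise below the detection
#'   threshold, including in channels that contain no bright objects
#'   (where the triangle threshold alone would drop into the noise).
#' @return A list of class `evg_detect_params`.
#' @export
detect_params <- function(smooth_sigma = 1, threshold_method = c("triangle", "fixed"),
                          fixed_threshold = NA_real_, refine_frac = 0.5,
                          min_area_px = 4L, split_touching = FALSE,
                          n_bins = 256L, min_snr = 10) {
  threshold_method <- match.arg(threshold_method)
  structure(list(smooth_sigma = smooth_sigma, threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold, refine_frac = refine_frac,
                 min_area_px = as.integer(min_area_px),
                 split_touching = split_touching, n_bins = as.integer(n_bins),
                 min_snr = min_snr),
            class = "evg_detect_params")
}

# Triangle threshold: place a line from the histogram peak to the far end of
# the longer tail; threshold at the bin maximizing the distance below the
# line. Returns Inf for (near-)constant images, i.e. nothing is segmented.
triangle_threshold <- function(x, n_bins = 256L) {
  rng <- range(x)
  if (diff(rng) <= 0) return(Inf)
  brk <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  cnt <- tabulate(findInterval(x, brk, rightmost.closed = TRUE), nbins = n_bins)
  mids <- (brk[-1] + brk[-length(brk)]) / 2
  p <- which.max(cnt)
  nz <- which(cnt > 0)
  lo <- min(nz); hi <- max(nz)
  # pick the longer tail side
  if ((hi - p) >= (p - lo)) { a <- p; b <- hi } else { a <- lo; b <- p }
  if (b <= a) return(Inf)
  idx <- a:b
  # distance from point (i, cnt[i]) to line through (a, cnt[a]) and (b, cnt[b])
  dx <- b - a; dy <- cnt[b] - cnt[a]
  d <- abs(dx * (cnt[a] - cnt[idx]) + dy * (idx - a)) / sqrt(dx^2 + dy^2)
  mids[idx[which.max(d)]]
}

# 8-connected component labeling: 4-connected labeling (EBImage::bwlabel)
# followed by union-find merging of diagonally adjacent labels. Labels are
# renumbered 1..k in order of first appearance in column-major scan order.
label_components <- function(mask) {
  mask <- mask > 0
  storage.mode(mask) <- "double"
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  k <- max(lab)
  if (k <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal pairs
  a2 <- lab[-nr, -1]; b2 <- lab[-1, -nc]    # down-left diagonal pairs
  pa <- c(a1[a1 > 0 & b1 > 0 & a1 != b1], a2[a2 > 0 & b2 > 0 & a2 != b2])
  pb <- c(b1[a1 > 0 & b1 > 0 & a1 != b1], b2[a2 > 0 & b2 > 0 & a2 != b2])
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (e in seq_along(pa)) {
    ra <- find(pa[e]); rb <- find(pb[e])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(k), find, integer(1))
  # compact renumbering in first-appearance order
  first <- integer(k)
  occ <- lab[lab > 0]
  firsts <- tapply(seq_along(occ), root[occ], min)
  ord <- order(unlist(firsts))
  remap <- integer(k)
  remap[as.integer(names(firsts))[ord]] <- seq_along(ord)
  out <- lab
  out[lab > 0] <- remap[root[lab[lab > 0]]]
  out
}

#' Segment one fluorescence channel into labeled objects
#'
#' Pipeline: median background subtraction, Gaussian smoothing, a global
#' triangle threshold, per-component half-maximum refinement, 8-connected
#' component labeling, optional watershed splitting, and removal of
#' components whose area is not larger than `min_area_px` pixels.
#'
#' @param img numeric intensity matrix.
#' @param params an [detect_params()] list.
#' @return Integer label matrix of the same dimension (0 = background). A
#'   constant image yields zero objects, not an error.
#' @export
segment_channel <- function(img, params = detect_params()) {
  stopifnot(is.matrix(img), length(img) > 0)
  sm <- gaussian_blur(img - median(img), params$smooth_sigma)
  noise <- stats::mad(sm)  # robust noise scale, before clamping
  sm[sm < 0] <- 0
  thr <- switch(params$threshold_method,
                triangle = max(triangle_threshold(sm, params$n_bins),
                               params$min_snr * noise),
                fixed = params$fixed_threshold)
  mask <- sm > thr
  if (!any(mask)) return(matrix(0L, nrow(img), ncol(img)))
  lab <- label_components(mask)
  if (params$refine_frac > 0) {
    fg <- lab > 0
    mx <- tapply(sm[fg], lab[fg], max)
    keep <- fg & sm >= (params$refine_frac * as.numeric(mx)[ifelse(fg, lab, 1L)])
    keep[!fg] <- FALSE
    lab <- label_components(keep)
  }
  if (params$split_touching && max(lab) > 0) {
    dm <- EBImage::distmap(lab > 0)
    ws <- EBImage::watershed(dm, tolerance = 1)
    lab <- matrix(as.integer(round(ws)), nrow(img), ncol(img))
  }
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    drop <- which(sizes <= params$min_area_px)
    if (length(drop) > 0) {
      lab[lab %in% drop] <- 0L
      lab <- relabel(lab)
    }
  }
  lab
}

relabel <- function(lab) {
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids) == 0L) return(lab)
  remap <- integer(max(ids))
  remap[ids] <- seq_along(ids)
  lab[lab > 0] <- remap[lab[lab > 0]]
  lab
}

#' Merge per-channel segmentation masks into multichannel objects
#'
#' The union of all channel masks is partitioned into 8-connected
#' components; each component is one object, and the pixels contributed by
#' each channel are recorded as that object's per-channel sub-mask.
#'
#' @param masks named list of label (or logical) matrices, one per channel,
#'   all of identical dimension.
#' @return A list of segmented objects; each has `object_id`, `dim`,
#'   `pixels` (linear indices into the frame, column-major, 1-based) and
#'   `channel_pixels` (named list of linear-index vectors, subsets of
#'   `pixels`).
#' @export
merge_channels <- function(masks) {
  stopifnot(is.list(masks), length(masks) >= 1L)
  dims <- vapply(masks, dim, integer(2))
  if (any(dims != dims[, 1])) stop("channel masks must share dimensions")
  un <- Reduce(`+`, lapply(masks, function(m) (m > 0) * 1L))
  lab <- label_components(un > 0)
  k <- max(lab)
  if (k == 0L) return(list())
  obj_pixels <- split(which(lab > 0), lab[lab > 0])
  lapply(seq_len(k), function(i) {
    pix <- obj_pixels[[as.character(i)]]
    chp <- lapply(masks, function(m) pix[m[pix] > 0])
    list(object_id = i, dim = dim(lab), pixels = pix, channel_pixels = chp)
  })
}
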