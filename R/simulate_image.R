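# Object archetypes rendered by the image simulator, and the channels in
# which each one fluoresces. Nucleated archetypes additionally get a DNA
# signal confined to a concentric nucleus ellipse.
EVG_ARCHETYPES <- c("ctc_ck", "ctc_her2", "ctc_ckher2",
                    "tdev_ck", "tdev_her2", "tdev_ckher2",
                    "leukocyte", "debris")

archetype_channels <- list(
  ctc_ck      = c("DNA", "CK"),
  ctc_her2    = c("DNA", "HER2"),
  ctc_ckher2  = c("DNA", "CK", "HER2"),
  tdev_ck     = c("CK"),
  tdev_her2   = c("HER2"),
  tdev_ckher2 = c("CK", "HER2"),
  leukocyte   = c("DNA", "CD45"),
  debris      = c("CK")
)

#' Configuration for the synthetic image generator
#'
#' Defines one frame's worth of simulated immunofluorescence content:
#' how many objects of each archetype to render, their physical sizes,
#' their per-channel staining intensities, and the imaging model
#' (Gaussian point-spread function, uniform background, Gaussian read
#' noise, 16-bit quantization).
#'
#' Default sizes follow the class definitions used for gating: CTC-like
#' cells are nucleated and larger than 4 um, vesicles lie within 1-14 um,
#' and debris is sub-micron so its rendered footprint stays at or below a
#' few pixels. The default pixel pitch of 0.64 um/px matches thumbnail
#' imagery in which a 6.4 um scale bar spans ten pixels.
#'
#' @param frame_size integer vector `c(height, width)` in pixels (>= 64).
#' @param pixel_size um per pixel.
#' @param psf_sigma point-spread-function sigma in pixels.
#' @param background_level,read_noise_sd per-channel scalars (recycled) or
#'   named vectors over DNA, CK, CD45, HER2, in intensity units.
#' @param object_counts named integer vector over the archetypes
#'   `r paste(EVG_ARCHETYPES, collapse = ", ")`; missing names default to 0.
#' @param diameter_um named list of `c(min, max)` equivalent-diameter ranges
#'   (um) per archetype.
#' @param intensity_mean,intensity_sd named numeric vectors: mean/sd of the
#'   in-object staining level for each archetype (applied to each of its
#'   positive channels).
#' @param nucleus_frac linear scale of the DNA (nucleus) ellipse relative to
#'   the cell ellipse, for nucleated archetypes.
#' @param min_margin_um additional clearance required between object rims
#'   when placing objects.
#' @param max_place_attempts rejection-sampling attempts per object before
#'   placement fails with an overcrowding error.
#' @param seed integer seed; the generator is fully deterministic given the
#'   configuration.
#' @return An object of class `evg_image_sim_config`.
#' @export
image_sim_config <- function(frame_size = c(256L, 256L),
                             pixel_size = 0.64,
                             psf_sigma = 1.0,
                             background_level = 40,
                             read_noise_sd = 8,
                             object_counts = c(ctc_ck = 4, ctc_her2 = 3,
                                               ctc_ckher2 = 3,
                                               tdev_ck = 12, tdev_her2 = 6,
                                               tdev_ckher2 = 6,
                                               leukocyte = 10, debris = 8),
                             diameter_um = NULL,
                             intensity_mean = c(ctc_ck = 3000, ctc_her2 = 3000,
                                                ctc_ckher2 = 3000, tdev_ck = 2000,
                                                tdev_her2 = 2000, tdev_ckher2 = 2000,
                                                leukocyte = 3000, debris = 20),
                             intensity_sd = c(ctc_ck = 300, ctc_her2 = 300,
                                              ctc_ckher2 = 300, tdev_ck = 250,
                                              tdev_her2 = 250, tdev_ckher2 = 250,
                                              leukocyte = 300, debris = 3),
                             nucleus_frac = 0.9,
                             min_margin_um = 2,
                             max_place_attempts = 5000L,
                             seed = 1L) {
  default_diam <- list(
    ctc_ck = c(8, 16), ctc_her2 = c(8, 16), ctc_ckher2 = c(8, 16),
    tdev_ck = c(2, 8), tdev_her2 = c(2, 8), tdev_ckher2 = c(2, 8),
    leukocyte = c(8, 12), debris = c(0.5, 0.9)
  )
  if (!is.null(diameter_um)) {
    default_diam[names(diameter_um)] <- diameter_um
  }
  diameter_um <- default_diam

  counts <- setNames(rep(0L, length(EVG_ARCHETYPES)), EVG_ARCHETYPES)
  bad <- setdiff(names(object_counts), EVG_ARCHETYPES)
  if (length(bad) > 0L) stop("unknown archetype(s): ", paste(bad, collapse = ", "))
  counts[names(object_counts)] <- as.integer(object_counts)

  expand_ch <- function(x, what) {
    if (is.null(names(x))) x <- setNames(rep(x, length.out = 4L), EVG_CHANNELS)
    if (!all(EVG_CHANNELS %in% names(x))) stop(what, " must cover all channels")
    x[EVG_CHANNELS]
  }
  background_level <- expand_ch(background_level, "background_level")
  read_noise_sd <- expand_ch(read_noise_sd, "read_noise_sd")

  frame_size <- as.integer(frame_size)
  if (length(frame_size) != 2L || any(frame_size < 64L)) {
    stop("frame_size must be c(height, width) with both >= 64")
  }
  if (pixel_size <= 0) stop("pixel_size must be positive")
  if (any(counts < 0L)) stop("object counts must be >= 0")
  for (a in c("ctc_ck", "ctc_her2", "ctc_ckher2")) {
    if (diameter_um[[a]][1] <= 4) stop("CTC archetype '", a, "' diameters must exceed 4 um")
  }
  for (a in c("tdev_ck", "tdev_her2", "tdev_ckher2")) {
    if (diameter_um[[a]][1] < 1 || diameter_um[[a]][2] > 14) {
      stop("tdEV archetype '", a, "' diameters must lie within [1, 14] um")
    }
  }
  structure(
    list(frame_size = frame_size, pixel_size = pixel_size, psf_sigma = psf_sigma,
         background_level = background_level, read_noise_sd = read_noise_sd,
         object_counts = counts, diameter_um = diameter_um,
         intensity_mean = intensity_mean[EVG_ARCHETYPES],
         intensity_sd = intensity_sd[EVG_ARCHETYPES],
         nucleus_frac = nucleus_frac, min_margin_um = min_margin_um,
         max_place_attempts = as.integer(max_place_attempts),
         seed = as.integer(seed)),
    class = "evg_image_sim_config"
  )
}

# 1-D Gaussian convolution matrix (same-size, zero boundary) for an n-vector.
conv_matrix <- function(n, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  K <- matrix(0, n, n)
  for (d in seq(-r, r)) {
    idx <- seq_len(n)
    j <- idx + d
    ok <- j >= 1L & j <= n
    K[cbind(idx[ok], j[ok])] <- K[cbind(idx[ok], j[ok])] + k[d + r + 1L]
  }
  K
}

gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  Kr <- conv_matrix(nrow(m), sigma)
  Kc <- conv_matrix(ncol(m), sigma)
  Kr %*% m %*% t(Kc)
}

# Pixel-centre indicator of an ellipse (semi-axes a, b px, orientation theta)
# on the local window grid.
ellipse_mask <- function(rows, cols, cr, cc, a, b, theta) {
  dr <- outer(rows - cr, rep(1, length(cols)))
  dc <- outer(rep(1, length(rows)), cols - cc)
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

#' Simulate one multichannel immunofluorescence frame with ground truth
#'
#' Objects are rendered as point-spread-blurred ellipses with archetype-
#' specific channel signatures (e.g. leukocytes DNA+CD45+, vesicles
#' anucleate CK/HER2+), placed by rejection sampling so that rims do not
#' approach within `min_margin_um`. The staining level drawn for an object
#' equals, by construction, the post-blur mean intensity over its true
#' pixel mask, so the recorded truth is directly comparable to measured
#' mean intensities. Background and Gaussian read noise are added last and
#' the frame is quantized to 16-bit.
#'
#' @param config an [image_sim_config()].
#' @param frame_id identifier stored in the stack and truth table.
#' @return A list with components `stack` (an `evg_image_stack`) and
#'   `truth` (data frame: object_id, archetype, centroid_row/col in px,
#'   diameter_um (equivalent diameter), axis_ratio, angle, and true mean
#'   intensity per channel; one row per rendered object).
#' @export
#' @examples
#' sim <- simulate_image(image_sim_config(object_counts = c(tdev_ck = 5), seed = 7))
#' nrow(sim$truth)
simulate_image <- function(config, frame_id = "frame_1") {
  stopifnot(inherits(config, "evg_image_sim_config"))
  with_seed(config$seed, simulate_image_impl(config, frame_id))
}

simulate_image_impl <- function(config, frame_id) {
  H <- config$frame_size[1]; W <- config$frame_size[2]
  px <- config$pixel_size
  channels <- lapply(setNames(EVG_CHANNELS, EVG_CHANNELS),
                     function(ch) matrix(0, H, W))

  # draw object geometry
  arche <- rep(EVG_ARCHETYPES, times = config$object_counts[EVG_ARCHETYPES])
  n <- length(arche)
  truth <- data.frame(object_id = integer(0), archetype = character(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      diameter_um = numeric(0), axis_ratio = numeric(0),
                      angle = numeric(0),
                      DNA = numeric(0), CK = numeric(0), CD45 = numeric(0),
                      HER2 = numeric(0), stringsAsFactors = FALSE)
  if (n == 0L) {
    return(list(stack = finish_frame(channels, config, frame_id),
                truth = truth))
  }

  diam <- vapply(arche, function(a) {
    r <- config$diameter_um[[a]]; runif(1, r[1], r[2])
  }, numeric(1))
  axis_ratio <- runif(n, 1, 1.3)
  angle <- runif(n, 0, pi)

  # placement with pairwise clearance (rim-to-rim >= min_margin_um)
  rad_px <- diam / 2 / px * sqrt(axis_ratio)  # major semi-axis in px
  margin_px <- config$min_margin_um / px
  centers <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    placed <- FALSE
    edge <- rad_px[i] + 3 * config$psf_sigma + 1
    if (2 * edge >= min(H, W)) stop("object too large for frame")
    for (att in seq_len(config$max_place_attempts)) {
      cand <- c(runif(1, edge, H - edge), runif(1, edge, W - edge))
      if (i == 1L || all(sqrt(rowSums(sweep(centers[seq_len(i - 1L), , drop = FALSE],
                                            2, cand)^2)) >=
                         rad_px[seq_len(i - 1L)] + rad_px[i] + margin_px)) {
        centers[i, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("overcrowding: could not place object ", i, " of ", n,
           " after ", config$max_place_attempts, " attempts; ",
           "reduce object counts or enlarge the frame")
    }
  }

  # staining levels per object x channel
  levels <- matrix(0, n, 4, dimnames = list(NULL, EVG_CHANNELS))
  for (i in seq_len(n)) {
    a <- arche[i]
    lv <- max(rnorm(1, config$intensity_mean[[a]], config$intensity_sd[[a]]), 0)
    levels[i, archetype_channels[[a]]] <- lv
  }

  # render each object on a local window and accumulate
  for (i in seq_len(n)) {
    amaj <- diam[i] / 2 / px * sqrt(axis_ratio[i])
    bmin <- diam[i] / 2 / px / sqrt(axis_ratio[i])
    h <- ceiling(amaj + 3 * config$psf_sigma + 2)
    r0 <- max(1L, floor(centers[i, 1] - h)); r1 <- min(H, ceiling(centers[i, 1] + h))
    c0 <- max(1L, floor(centers[i, 2] - h)); c1 <- min(W, ceiling(centers[i, 2] + h))
    rows <- r0:r1; cols <- c0:c1
    for (ch in EVG_CHANNELS) {
      if (levels[i, ch] <= 0) next
      scale_ax <- if (ch == "DNA" && startsWith(arche[i], "ctc") ||
                      (ch == "DNA" && arche[i] == "leukocyte")) config$nucleus_frac else 1
      mask <- ellipse_mask(rows, cols, centers[i, 1], centers[i, 2],
                           amaj * scale_ax, bmin * scale_ax, angle[i])
      if (!any(mask)) {
        # sub-pixel object: deposit on the nearest pixel centre
        rr <- which.min(abs(rows - centers[i, 1]))
        cc <- which.min(abs(cols - centers[i, 2]))
        mask[rr, cc] <- TRUE
      }
      blurred <- gaussian_blur(mask * 1, config$psf_sigma)
      att <- mean(blurred[mask])
      channels[[ch]][rows, cols] <- channels[[ch]][rows, cols] +
        blurred * (levels[i, ch] / att)
    }
  }

  truth <- data.frame(object_id = seq_len(n), archetype = arche,
                      centroid_row = centers[, 1], centroid_col = centers[, 2],
                      diameter_um = diam, axis_ratio = axis_ratio, angle = angle,
                      DNA = levels[, "DNA"], CK = levels[, "CK"],
                      CD45 = levels[, "CD45"], HER2 = levels[, "HER2"],
                      stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  list(stack = finish_frame(channels, config, frame_id), truth = truth)
}

finish_frame <- function(channels, config, frame_id) {
  for (ch in EVG_CHANNELS) {
    m <- channels[[ch]] + config$background_level[[ch]] +
      rnorm(length(channels[[ch]]), 0, config$read_noise_sd[[ch]])
    channels[[ch]] <- matrix(pmin(pmax(round(m), 0), 65535),
                             nrow(channels[[ch]]), ncol(channels[[ch]]))
  }
  image_stack(channels, pixel_size = config$pixel_size, frame_id = frame_id)
}
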