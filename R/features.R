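# --- feature definitions -----------------------------------------------------
#
# Geometry is computed on a pixel set, treating pixels as unit squares:
#   area         = n * s^2                         (s = pixel size, um)
#   perimeter    = Crofton 4-direction estimate * s:
#                  P_px = (pi/4) * (Nh/2 + Nv/2 + (Nd1 + Nd2) / (2*sqrt(2)))
#                  where Nh/Nv/Nd1/Nd2 count foreground/background transitions
#                  along horizontal / vertical / the two diagonal scan
#                  directions (image border counts as background).
#   eccentricity = sqrt(1 - l2/l1) from the eigenvalues l1 >= l2 of the
#                  pixel-coordinate covariance matrix with the unit-square
#                  self-moment 1/12 added (so even degenerate pixel lines
#                  stay strictly below 1, and a disk is ~0).
#   perim_area_ratio = perimeter / area (1/um)
#   eq_diameter  = 2 * sqrt(area / pi)
#
# Intensity features (mean/max/sd/total) are measured on the raw channel
# values over the OBJECT's union pixel set, so they are defined for every
# channel including ones with no segmented signal (which then read at
# background level); this is what makes negativity gates expressible.
# The DNA-overlap fraction of a channel is |sub-mask  ∩ DNA sub-mask| /
# |sub-mask| over that channel's own sub-mask (0 when the sub-mask is empty).

mask_geometry <- function(pix, dim, pixel_size) {
  n <- length(pix)
  if (n == 0L) {
    return(c(area_um2 = NA_real_, perimeter_um = NA_real_,
             eccentricity = NA_real_, perim_area_ratio = NA_real_,
             eq_diameter_um = NA_real_))
  }
  rc <- arrayInd(pix, dim)
  r <- rc[, 1]; c <- rc[, 2]
  # local bounding-box matrix with a 1-px background border
  r0 <- min(r); c0 <- min(c)
  m <- matrix(FALSE, max(r) - r0 + 3L, max(c) - c0 + 3L)
  m[cbind(r - r0 + 2L, c - c0 + 2L)] <- TRUE
  per_px <- crofton_perimeter(m)

  area <- n * pixel_size^2
  per <- per_px * pixel_size
  mu20 <- mean((r - mean(r))^2) + 1 / 12
  mu02 <- mean((c - mean(c))^2) + 1 / 12
  mu11 <- mean((r - mean(r)) * (c - mean(c)))
  disc <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (mu20 + mu02 + disc) / 2
  l2 <- (mu20 + mu02 - disc) / 2
  ecc <- sqrt(max(0, 1 - l2 / l1))
  c(area_um2 = area, perimeter_um = per, eccentricity = ecc,
    perim_area_ratio = per / area, eq_diameter_um = 2 * sqrt(area / pi))
}

crofton_perimeter <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  nh <- sum(m[, -1] != m[, -nc])
  nv <- sum(m[-1, ] != m[-nr, ])
  nd1 <- sum(m[-nr, -nc] != m[-1, -1])
  nd2 <- sum(m[-nr, -1] != m[-1, -nc])
  (pi / 4) * (nh / 2 + nv / 2 + (nd1 + nd2) / (2 * sqrt(2)))
}

#' Extract the per-channel feature vector of one segmented object
#'
#' Computes, for each fluorescence channel, 10 features: five geometric
#' descriptors of the channel's segmented sub-mask (area, Crofton
#' perimeter, ellipse-fit eccentricity, perimeter-to-area ratio,
#' equivalent circular diameter; `NA` when the sub-mask is empty), four
#' intensity statistics of the raw channel over the object's union pixel
#' set (mean, max, sd, total), and the fraction of the sub-mask
#' overlapping the DNA sub-mask (0 for an empty sub-mask). Geometry of the
#' union pixel set is reported under the `object.` prefix. All lengths are
#' physical (um) via the stack's pixel size.
#'
#' @param obj one element of the list returned by [merge_channels()].
#' @param stack the `evg_image_stack` the object was segmented from.
#' @return A one-row data frame; see [feature_columns()] for the header.
#' @export
extract_features <- function(obj, stack) {
  stopifnot(inherits(stack, "evg_image_stack"))
  d <- dim(stack$channels[[1]])
  if (any(obj$pixels < 1L | obj$pixels > prod(d))) {
    stop("object pixels outside stack bounds")
  }
  s <- stack$pixel_size
  rc <- arrayInd(obj$pixels, d)
  out <- list(frame_id = stack$frame_id, object_id = obj$object_id,
              n_pixels = length(obj$pixels),
              centroid_row = mean(rc[, 1]), centroid_col = mean(rc[, 2]))
  g <- mask_geometry(obj$pixels, d, s)
  for (f in names(g)) out[[paste0("object.", f)]] <- unname(g[[f]])
  dna_sub <- obj$channel_pixels[["DNA"]]
  out[["object.dna_overlap"]] <- length(dna_sub) / length(obj$pixels)
  for (ch in EVG_CHANNELS) {
    sub <- obj$channel_pixels[[ch]]
    g <- mask_geometry(sub, d, s)
    for (f in names(g)) out[[paste0(ch, ".", f)]] <- unname(g[[f]])
    v <- stack$channels[[ch]][obj$pixels]
    out[[paste0(ch, ".mean_int")]] <- mean(v)
    out[[paste0(ch, ".max_int")]] <- max(v)
    out[[paste0(ch, ".sd_int")]] <- if (length(v) > 1L) sd(v) else 0
    out[[paste0(ch, ".total_int")]] <- sum(v)
    out[[paste0(ch, ".dna_overlap")]] <-
      if (length(sub) == 0L) 0 else length(intersect(sub, dna_sub)) / length(sub)
  }
  as.data.frame(out, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Column header of a feature table
#'
#' @return Character vector of all feature-table columns, in stable order.
#' @export
feature_columns <- function() {
  c("frame_id", "object_id", "n_pixels", "centroid_row", "centroid_col",
    paste0("object.", c(EVG_GEOM_FEATURES, "dna_overlap")),
    unlist(lapply(EVG_CHANNELS, function(ch) paste0(ch, ".", EVG_FEATURES))))
}

#' Full detection: segment all channels, merge, and extract features
#'
#' The composition [segment_channel()] (per channel) -> [merge_channels()]
#' -> [extract_features()] (per object). Deterministic: the same stack and
#' parameters always yield the same table.
#'
#' @param stack an `evg_image_stack`.
#' @param params an [detect_params()] list.
#' @return A feature table (data frame), one row per detected object, with
#'   the [feature_columns()] header; a blank stack yields a 0-row table
#'   with the full header.
#' @export
#' @examples
#' sim <- simulate_image(image_sim_config(object_counts = c(ctc_ck = 2), seed = 3))
#' ft <- detect(sim$stack)
#' ft[, c("object_id", "object.eq_diameter_um", "CK.mean_int")]
detect <- function(stack, params = detect_params()) {
  stopifnot(inherits(stack, "evg_image_stack"))
  masks <- lapply(stack$channels, segment_channel, params = params)
  objs <- merge_channels(masks)
  if (length(objs) == 0L) {
    tmpl <- setNames(rep(list(numeric(0)), length(feature_columns())),
                     feature_columns())
    tmpl$frame_id <- character(0)
    tmpl$object_id <- integer(0)
    return(as.data.frame(tmpl, check.names = FALSE, stringsAsFactors = FALSE))
  }
  rows <- lapply(objs, extract_features, stack = stack)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, feature_columns()]
}
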