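#' Construct a multichannel fluorescence image stack
#'
#' An image stack is one frame of four co-registered grayscale channels
#' (DNA, CK, CD45, HER2) plus the physical pixel size. Intensities are
#' non-negative integer photon counts (arbitrary detector units).
#'
#' @param channels named list of numeric matrices, one per channel; must
#'   contain at least `DNA`, `CK`, `CD45`, `HER2`, all of identical dimension.
#' @param pixel_size physical pixel pitch in micrometres per pixel.
#' @param frame_id character identifier for the frame.
#' @return An object of class `evg_image_stack`.
#' @export
image_stack <- function(channels, pixel_size = 0.64, frame_id = "frame_1") {
  stopifnot(is.list(channels), length(channels) >= 1L)
  missing_ch <- setdiff(EVG_CHANNELS, names(channels))
  if (length(missing_ch) > 0L) {
    stop("image stack is missing channel(s): ", paste(missing_ch, collapse = ", "))
  }
  channels <- channels[EVG_CHANNELS]
  dims <- vapply(channels, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all channels must share identical dimensions")
  }
  if (any(vapply(channels, function(m) any(m < 0), logical(1)))) {
    stop("channel intensities must be non-negative")
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stop("pixel_size must be a single positive number")
  }
  structure(
    list(channels = channels, pixel_size = pixel_size,
         frame_id = as.character(frame_id)),
    class = "evg_image_stack"
  )
}

#' @export
print.evg_image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<evg_image_stack> %s: %d x %d px (%.3g x %.3g um), channels: %s\n",
              x$frame_id, d[1], d[2],
              d[1] * x$pixel_size, d[2] * x$pixel_size,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' @export
dim.evg_image_stack <- function(x) dim(x$channels[[1]])

#' Write an image stack to per-channel TIFF files with a metadata sidecar
#'
#' Each channel is written as a 16-bit grayscale TIFF
#' `<prefix>_<channel>.tif`; pixel size, frame id and channel file names go
#' to a plain-text `<prefix>_meta.txt` sidecar (`key: value` lines) so the
#' stack round-trips losslessly through [read_image_stack()].
#'
#' @param stack an `evg_image_stack`. Intensities must lie in `[0, 65535]`;
#'   they are rounded to integers on write.
#' @param prefix path prefix for the output files.
#' @return Invisibly, the sidecar path.
#' @export
write_image_stack <- function(stack, prefix) {
  stopifnot(inherits(stack, "evg_image_stack"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (ch in names(stack$channels)) {
    m <- round(stack$channels[[ch]])
    if (any(m > 65535)) stop("intensities exceed 16-bit range in channel ", ch)
    f <- paste0(prefix, "_", ch, ".tif")
    tiff::writeTIFF(m / 65535, f, bits.per.sample = 16L, reduce = FALSE)
    files <- c(files, basename(f))
  }
  meta <- c(
    paste0("frame_id: ", stack$frame_id),
    paste0("pixel_size_um: ", format(stack$pixel_size, digits = 15)),
    paste0("channels: ", paste(names(stack$channels), collapse = ",")),
    paste0("files: ", paste(files, collapse = ","))
  )
  sidecar <- paste0(prefix, "_meta.txt")
  writeLines(meta, sidecar)
  invisible(sidecar)
}

#' Read an image stack written by [write_image_stack()] or from plain TIFFs
#'
#' With `channel_map = NULL` the `<prefix>_meta.txt` sidecar is consulted.
#' Alternatively `channel_map` gives explicit per-channel TIFF paths, e.g.
#' `c(DNA = "dapi.tif", CK = "pe.tif", CD45 = "apc.tif", HER2 = "fitc.tif")`;
#' 8- and 16-bit integer TIFFs are loaded with integer values preserved.
#'
#' @param prefix path prefix used at write time (ignored when `channel_map`
#'   has absolute paths for all channels).
#' @param channel_map optional named character vector of TIFF paths covering
#'   all of DNA, CK, CD45, HER2.
#' @param pixel_size override for the pixel pitch (um/px); required when no
#'   sidecar is available.
#' @return An `evg_image_stack`.
#' @export
read_image_stack <- function(prefix = NULL, channel_map = NULL, pixel_size = NULL) {
  frame_id <- "frame_1"
  if (is.null(channel_map)) {
    sidecar <- paste0(prefix, "_meta.txt")
    if (!file.exists(sidecar)) stop("metadata sidecar not found: ", sidecar)
    meta <- read_sidecar(sidecar)
    chs <- strsplit(meta[["channels"]], ",")[[1]]
    fls <- strsplit(meta[["files"]], ",")[[1]]
    channel_map <- setNames(file.path(dirname(sidecar), fls), chs)
    if (is.null(pixel_size)) pixel_size <- as.numeric(meta[["pixel_size_um"]])
    frame_id <- meta[["frame_id"]]
  }
  missing_ch <- setdiff(EVG_CHANNELS, names(channel_map))
  if (length(missing_ch) > 0L) {
    stop("channel_map is missing channel(s): ", paste(missing_ch, collapse = ", "))
  }
  if (is.null(pixel_size)) stop("pixel_size required when no sidecar metadata is present")
  channels <- lapply(channel_map[EVG_CHANNELS], function(f) {
    if (!file.exists(f)) stop("TIFF not found: ", f)
    m <- tiff::readTIFF(f, as.is = TRUE)
    if (length(dim(m)) == 3L) m <- m[, , 1]  # tolerate accidental RGB
    storage.mode(m) <- "double"
    m
  })
  image_stack(channels, pixel_size = pixel_size, frame_id = frame_id)
}

read_sidecar <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexpr(":", lines), invert = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  setNames(as.list(vals), keys)
}
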