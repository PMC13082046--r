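#' Read and write label masks and intensity images as TIFF
#'
#' Label masks are stored as single-channel 16-bit integer TIFFs (labels up
#' to 65535).  Intensity images are stored as 32-bit float TIFFs; because
#' TIFF float samples are kept in `[0, 1]`, values are divided by their
#' maximum on write and the scale is recorded in the sidecar.  Pixel size
#' and origin do not fit standard baseline TIFF tags, so both writers drop a
#' JSON sidecar (`<path>.json`) holding `pixel_size`, `origin` and the
#' intensity scale; the readers restore them.  Without a sidecar the reader
#' falls back to the supplied `default_frame` or a unit frame at the Xenium
#' default pixel size.
#'
#' @param mask,image A [label_mask()] / [intensity_image()].
#' @param path TIFF file path; the sidecar is written next to it.
#' @return Readers return the respective container; writers return `path`
#'   invisibly.
#' @name image_io
NULL

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(path, frame, extra = list()) {
  meta <- c(list(pixel_size = frame$pixel_size, origin = frame$origin), extra)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

frame_from_sidecar <- function(path, width, height, default_frame = NULL) {
  meta <- read_sidecar(path)
  if (is.null(meta)) {
    if (!is.null(default_frame)) {
      assert_frame(default_frame)
      if (default_frame$width != width || default_frame$height != height)
        stop("default_frame does not match the image dimensions")
      return(list(frame = default_frame, meta = NULL))
    }
    return(list(frame = pixel_frame(width, height), meta = NULL))
  }
  list(frame = pixel_frame(width, height, meta$pixel_size,
                           as.numeric(meta$origin)),
       meta = meta)
}

read_tiff_checked <- function(path, what = c("mask", "intensity")) {
  what <- match.arg(what)
  if (!file.exists(path)) stop("no such file: ", path)
  info <- tiff::readTIFF(path, info = TRUE, as.is = (what == "mask"))
  spp <- attr(info, "samples.per.pixel")
  if (!is.null(spp) && spp > 1L || length(dim(info)) > 2L)
    stop("expected a single-channel TIFF, got ", max(spp, dim(info)[3]),
         " channels: ", path)
  bps <- attr(info, "bits.per.sample")
  if (what == "mask") {
    if (!is.null(bps) && bps >= 32L)
      stop("label masks must be 8- or 16-bit integer TIFFs, got ",
           bps, "-bit (floating point?): ", path)
    vals <- matrix(as.numeric(info), nrow(info), ncol(info))
    if (any(vals != floor(vals)))
      stop("label mask TIFF contains non-integer values: ", path)
  }
  info
}

#' @rdname image_io
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  if (max(mask$labels) > 65535L)
    stop("labels exceed 65535; 16-bit mask TIFF cannot represent them")
  tiff::writeTIFF(mask$labels / 65535, path, bits.per.sample = 16,
                  compression = "LZW")
  write_sidecar(path, mask$frame, list(kind = "label_mask"))
  invisible(path)
}

#' @rdname image_io
#' @param default_frame Optional [pixel_frame()] used when no sidecar is
#'   found.
#' @export
read_label_mask <- function(path, default_frame = NULL) {
  arr <- read_tiff_checked(path, "mask")
  lab <- matrix(as.integer(arr), nrow(arr), ncol(arr))
  fr <- frame_from_sidecar(path, ncol(lab), nrow(lab), default_frame)
  label_mask(lab, fr$frame)
}

#' @rdname image_io
#' @export
write_intensity_image <- function(image, path) {
  stopifnot(inherits(image, "intensity_image"))
  mx <- max(image$values)
  scale <- if (mx > 0) mx else 1
  tiff::writeTIFF(image$values / scale, path, bits.per.sample = 32,
                  compression = "LZW")
  write_sidecar(path, image$frame,
                list(kind = "intensity_image", scale = scale))
  invisible(path)
}

#' @rdname image_io
#' @export
read_intensity_image <- function(path, default_frame = NULL) {
  arr <- read_tiff_checked(path, "intensity")
  vals <- matrix(as.numeric(arr), nrow(arr), ncol(arr))
  fr <- frame_from_sidecar(path, ncol(vals), nrow(vals), default_frame)
  if (!is.null(fr$meta$scale)) vals <- vals * fr$meta$scale
  intensity_image(vals, fr$frame)
}

#' Write a two-channel stack (DAPI + density) as a multi-page TIFF
#'
#' @param stack A [channel_stack()].
#' @param path Output TIFF path.
#' @export
write_channel_stack <- function(stack, path) {
  stopifnot(inherits(stack, "channel_stack"))
  tiff::writeTIFF(list(stack$dapi$values, stack$density$values), path,
                  bits.per.sample = 32, compression = "LZW")
  write_sidecar(path, stack$frame,
                list(kind = "channel_stack", channels = c("dapi", "density")))
  invisible(path)
}
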