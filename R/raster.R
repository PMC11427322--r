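#' 8-bit RGB raster image
#'
#' Lightweight container for an 8-bit RGB pixel grid. Every estimator in the
#' package consumes this type. Pixels are stored as an integer array of
#' dimension `height x width x 3` with channel values in `[0, 255]`.
#'
#' @param pixels Integer (or numeric) array `H x W x 3`, values in `[0, 255]`.
#' @param source_id Character photograph identifier.
#' @return An object of class `raster_image`.
#' @export
raster_image <- function(pixels, source_id = "unknown") {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 array")
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop("image must have height >= 1 and width >= 1")
  px <- pixels
  if (is.double(px)) px <- round(px)
  if (anyNA(px) || min(px) < 0 || max(px) > 255)
    stop("channel values must lie in [0, 255]")
  storage.mode(px) <- "integer"
  structure(list(pixels = px,
                 height = dim(px)[1], width = dim(px)[2],
                 source_id = as.character(source_id)),
            class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf("<raster_image '%s': %d x %d (w x h), 8-bit RGB>\n",
              x$source_id, x$width, x$height))
  invisible(x)
}

#' @export
dim.raster_image <- function(x) c(x$height, x$width, 3L)

#' Read a PNG or JPEG photograph
#'
#' Reads an 8-bit RGB image from disk. Grayscale images are expanded to three
#' identical channels; an alpha channel is dropped with a warning.
#'
#' @param path Path to a `.png`, `.jpg` or `.jpeg` file.
#' @param source_id Identifier stored with the image; defaults to the file
#'   name without extension.
#' @return A [raster_image].
#' @export
read_image <- function(path, source_id = NULL) {
  if (is.null(source_id))
    source_id <- sub("\\.[^.]*$", "", basename(path))
  ext <- tolower(sub(".*\\.", "", path))
  arr <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("reading JPEG requires the 'jpeg' package")
      jpeg::readJPEG(path)
    },
    stop("unsupported image format: .", ext)
  )
  if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
  if (dim(arr)[3] == 1L) arr <- arr[, , c(1L, 1L, 1L), drop = FALSE]
  if (dim(arr)[3] == 4L) {
    warning("alpha channel dropped from ", basename(path))
    arr <- arr[, , 1:3, drop = FALSE]
  }
  raster_image(round(arr[, , 1:3, drop = FALSE] * 255), source_id = source_id)
}

#' Write a raster image to PNG
#'
#' @param img A [raster_image].
#' @param path Output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "raster_image"))
  png::writePNG(img$pixels / 255, target = path)
  invisible(path)
}

## Area-averaging (box) resampling matrix: maps n_in samples onto n_out,
## each output pixel the exact mean of the input interval it covers.
## Used for large-factor downscaling, where interpolating resamplers alias.
resample_weights <- function(n_in, n_out) {
  W <- matrix(0, n_out, n_in)
  step <- n_in / n_out
  for (i in seq_len(n_out)) {
    lo <- (i - 1) * step
    hi <- i * step
    j0 <- floor(lo) + 1
    j1 <- ceiling(hi)
    for (j in j0:min(j1, n_in)) {
      overlap <- min(hi, j) - max(lo, j - 1)
      if (overlap > 0) W[i, j] <- overlap
    }
    W[i, ] <- W[i, ] / step
  }
  W
}

#' Resize an image by area averaging
#'
#' Each output pixel is the exact area-weighted mean of the input pixels it
#' covers (box filter), which avoids the aliasing that bilinear interpolation
#' introduces at large downscale factors and would corrupt the downstream
#' fractal estimates.
#'
#' @param img A [raster_image].
#' @param width,height Target size in pixels.
#' @return A [raster_image] of the requested size.
#' @export
resize_image <- function(img, width, height) {
  stopifnot(inherits(img, "raster_image"))
  if (width == img$width && height == img$height) return(img)
  A <- resample_weights(img$height, height)
  B <- resample_weights(img$width, width)
  out <- array(0, c(height, width, 3L))
  for (ch in 1:3)
    out[, , ch] <- A %*% img$pixels[, , ch] %*% t(B)
  raster_image(round(out), source_id = img$source_id)
}

#' Centre-crop an image
#'
#' @param img A [raster_image].
#' @param width,height Crop window in pixels; must not exceed the image.
#' @return The cropped [raster_image].
#' @export
crop_center <- function(img, width, height) {
  stopifnot(inherits(img, "raster_image"))
  if (img$width < width || img$height < height)
    stop(sprintf("image %d x %d smaller than crop window %d x %d",
                 img$width, img$height, width, height))
  r0 <- floor((img$height - height) / 2)
  c0 <- floor((img$width - width) / 2)
  raster_image(img$pixels[r0 + seq_len(height), c0 + seq_len(width), ,
                          drop = FALSE],
               source_id = img$source_id)
}

#' Standardize a photograph to the working resolution
#'
#' Reproduces the study's image preparation: centre-crop to
#' `crop_width x crop_height` (default 4096 x 2048), then resize by area
#' averaging to `width x height` (default 640 x 320). Images already at the
#' working size pass through unchanged. With `crop = FALSE` the crop step is
#' skipped and the image is only resized (useful for synthetic scenes that
#' are generated directly at the working size).
#'
#' @param img A [raster_image].
#' @param crop Apply the centre crop? Default `TRUE`.
#' @param crop_width,crop_height Crop window (pixels).
#' @param width,height Working resolution (pixels).
#' @return A [raster_image] at the working resolution.
#' @export
preprocess <- function(img, crop = TRUE,
                       crop_width = 4096L, crop_height = 2048L,
                       width = 640L, height = 320L) {
  stopifnot(inherits(img, "raster_image"))
  if (img$width == width && img$height == height) return(img)
  if (crop) img <- crop_center(img, crop_width, crop_height)
  resize_image(img, width, height)
}

#' Single-channel field in [0, 1]
#'
#' A real-valued `H x W` grid holding one normalized channel (brightness,
#' saturation, or hue). All grayscale estimators operate on this type.
#'
#' @param values Numeric matrix with entries in `[0, 1]`.
#' @param channel_name One of `"brightness"`, `"saturation"`, `"hue"`, or a
#'   free-form label for synthetic fields.
#' @return An object of class `channel_field` (a matrix with attributes).
#' @export
channel_field <- function(values, channel_name = "brightness") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (anyNA(values) || min(values) < 0 || max(values) > 1)
    stop("channel values must lie in [0, 1]")
  structure(values, channel_name = channel_name, class = c("channel_field", "matrix"))
}

#' @export
print.channel_field <- function(x, ...) {
  cat(sprintf("<channel_field '%s': %d x %d, range [%.3f, %.3f]>\n",
              attr(x, "channel_name"), nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

as_field_matrix <- function(field) {
  m <- unclass(field)
  attr(m, "channel_name") <- NULL
  m
}
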