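#' HSV criteria for green-pixel detection
#'
#' Defines the inclusive HSV window used to classify a pixel as "green".
#' The default window -- hue 50-170 degrees, saturation 20-100%, value
#' 10-100% -- spans yellow-green through cyan-green, the range that picks up
#' foliage in indoor photographs. Two unit conventions are supported:
#'
#' * `degrees_percent` (default): hue in degrees `[0, 360)`, saturation and
#'   value in percent `[0, 100]`.
#' * `native_8bit`: thresholds interpreted on the OpenCV 8-bit scale
#'   (hue `0-179` = half-degrees, saturation/value `0-255`).
#'
#' @param hue_min,hue_max Hue bounds (degrees, or half-degrees for
#'   `native_8bit`).
#' @param sat_min,sat_max Saturation bounds (percent, or 0-255).
#' @param val_min,val_max Value bounds (percent, or 0-255).
#' @param convention `"degrees_percent"` or `"native_8bit"`.
#' @return An object of class `hsv_criteria`.
#' @export
hsv_criteria <- function(hue_min = 50, hue_max = 170,
                         sat_min = 20, sat_max = 100,
                         val_min = 10, val_max = 100,
                         convention = c("degrees_percent", "native_8bit")) {
  convention <- match.arg(convention)
  if (!(hue_min < hue_max)) stop("hue_min must be < hue_max")
  if (sat_min > sat_max) stop("sat_min must be <= sat_max")
  if (val_min > val_max) stop("val_min must be <= val_max")
  structure(list(hue_min = hue_min, hue_max = hue_max,
                 sat_min = sat_min, sat_max = sat_max,
                 val_min = val_min, val_max = val_max,
                 convention = convention),
            class = "hsv_criteria")
}

#' Convert an RGB image to HSV channel grids
#'
#' Standard RGB to HSV conversion. Hue is returned in degrees `[0, 360)`,
#' saturation and value in percent `[0, 100]`. The hue of an achromatic pixel
#' (zero saturation) is defined as 0.
#'
#' @param img A [raster_image].
#' @return A list with matrices `hue` (degrees), `sat` and `val` (percent),
#'   each `H x W`.
#' @export
to_hsv <- function(img) {
  stopifnot(inherits(img, "raster_image"))
  h <- img$height; w <- img$width
  rgbmat <- rbind(as.vector(img$pixels[, , 1]),
                  as.vector(img$pixels[, , 2]),
                  as.vector(img$pixels[, , 3]))
  hsv <- grDevices::rgb2hsv(rgbmat, maxColorValue = 255)
  list(hue = matrix((hsv[1, ] * 360) %% 360, h, w),
       sat = matrix(hsv[2, ] * 100, h, w),
       val = matrix(hsv[3, ] * 100, h, w))
}

## Logical green mask for an image under the given criteria.
green_mask <- function(img, crit = hsv_criteria()) {
  hsv <- to_hsv(img)
  if (crit$convention == "native_8bit") {
    hue <- hsv$hue / 2            # OpenCV hue: half-degrees 0..179
    sat <- hsv$sat * 255 / 100
    val <- hsv$val * 255 / 100
  } else {
    hue <- hsv$hue; sat <- hsv$sat; val <- hsv$val
  }
  hue >= crit$hue_min & hue <= crit$hue_max &
    sat >= crit$sat_min & sat <= crit$sat_max &
    val >= crit$val_min & val <= crit$val_max
}

#' Green-area percentage of a photograph
#'
#' Counts the pixels whose hue, saturation and value all fall inclusively
#' within the criteria window and returns `100 * green pixels / all pixels`.
#' The measure is a pure pixel count: it is invariant under pixel
#' permutation and does not distinguish live plants from green furniture.
#'
#' @param img A [raster_image].
#' @param crit An [hsv_criteria]; the default is the study window.
#' @return Percentage in `[0, 100]`.
#' @export
greenery_percentage <- function(img, crit = hsv_criteria()) {
  m <- green_mask(img, crit)
  100 * sum(m) / length(m)
}

#' Square-root transform of a percentage
#'
#' Perceived density of texture follows a square-root law at moderate to
#' high densities, so the analysis uses the square root of the green-area
#' percentage as the working predictor.
#'
#' @param pct Non-negative percentage.
#' @return `sqrt(pct)`.
#' @export
sqrt_transform <- function(pct) {
  if (any(pct < 0)) stop("percentage must be non-negative")
  sqrt(pct)
}

#' Mean of a channel field
#'
#' @param field A [channel_field] (or plain numeric matrix in `[0, 1]`).
#' @return Arithmetic mean of all values.
#' @export
mean_channel <- function(field) {
  if (length(field) == 0L) stop("empty channel field")
  mean(field)
}
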