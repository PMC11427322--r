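#' Names of the 19 modelled visual-property indicators
#'
#' The indicator catalogue: square root of greenery, mean brightness, mean
#' saturation, shape fractal, geometric fractal of brightness at three
#' scales, statistical fractals of brightness / saturation / hue at three
#' scales each, colour fractal, and 1/f fluctuation of brightness and of
#' saturation. The raw greenery percentage is carried alongside but is
#' excluded from modelling as redundant with its square root.
#'
#' @return Character vector of length 19.
#' @export
feature_names <- function() {
  c("sqrt_greenery", "mean_brightness", "mean_saturation", "shape_fractal",
    paste0("geom_fractal_brightness_", c("small", "large", "overall")),
    paste0("stat_fractal_brightness_", c("small", "large", "overall")),
    paste0("stat_fractal_saturation_", c("small", "large", "overall")),
    paste0("stat_fractal_hue_", c("small", "large", "overall")),
    "color_fractal", "one_over_f_brightness", "one_over_f_saturation")
}

#' Feature-extraction configuration
#'
#' Bundles every tunable of the indicator pipeline: the HSV greenery
#' criteria, the preprocessing toggles, edge-detector thresholds, and the
#' spectral fit band. Serializes losslessly to JSON via [write_config()].
#'
#' @param criteria An [hsv_criteria].
#' @param preprocess Run [preprocess()] on each image first?
#' @param crop Centre-crop before resizing (see [preprocess()]).
#' @param width,height Working resolution.
#' @param edge_high_quantile,edge_low_ratio Hysteresis controls for
#'   [shape_fractal()].
#' @param fft_bins Radial bins for [one_over_f_fluctuation()].
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(criteria = hsv_criteria(),
                           preprocess = TRUE, crop = TRUE,
                           width = 640L, height = 320L,
                           edge_high_quantile = 0.9, edge_low_ratio = 0.5,
                           fft_bins = 24L) {
  structure(list(criteria = criteria, preprocess = preprocess, crop = crop,
                 width = as.integer(width), height = as.integer(height),
                 edge_high_quantile = edge_high_quantile,
                 edge_low_ratio = edge_low_ratio,
                 fft_bins = as.integer(fft_bins)),
            class = "feature_config")
}

#' Read / write a feature configuration as JSON
#'
#' @param path JSON path.
#' @return [read_config()]: a [feature_config]; [write_config()]: `path`.
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cr <- x$criteria
  feature_config(
    criteria = hsv_criteria(cr$hue_min, cr$hue_max, cr$sat_min, cr$sat_max,
                            cr$val_min, cr$val_max,
                            convention = cr$convention),
    preprocess = x$preprocess, crop = x$crop,
    width = x$width, height = x$height,
    edge_high_quantile = x$edge_high_quantile,
    edge_low_ratio = x$edge_low_ratio, fft_bins = x$fft_bins)
}

#' @rdname read_config
#' @param config A [feature_config].
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(list(criteria = unclass(config$criteria),
                            preprocess = config$preprocess, crop = config$crop,
                            width = config$width, height = config$height,
                            edge_high_quantile = config$edge_high_quantile,
                            edge_low_ratio = config$edge_low_ratio,
                            fft_bins = config$fft_bins),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

with_feature_name <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("feature '%s': %s", name, conditionMessage(e)), call. = FALSE))
}

#' Extract the full visual-property vector of a photograph
#'
#' Runs the whole indicator pipeline on one image: optional preprocessing,
#' HSV conversion, greenery percentage and its square root, channel means,
#' the shape fractal of the brightness edge map, geometric fractals of
#' brightness at three scale windows, differential box-counting fractals of
#' brightness, saturation and hue at three windows each, the 5-D colour
#' fractal, and the 1/f fluctuation indices of brightness and saturation.
#' Hue is treated as a linear field in `[0, 1]` for its fractal indices (a
#' documented approximation for the circular quantity). Deterministic for a
#' fixed image and configuration. Degenerate inputs (uniform images) yield
#' flagged fallback values rather than errors; flags are returned in the
#' `flags` attribute.
#'
#' @param img A [raster_image].
#' @param config A [feature_config].
#' @return Named numeric vector: `greenery_pct` plus the 19 indicators of
#'   [feature_names()], with attributes `source_id` and `flags`.
#' @export
extract_features <- function(img, config = feature_config()) {
  stopifnot(inherits(img, "raster_image"))
  if (config$preprocess)
    img <- preprocess(img, crop = config$crop,
                      width = config$width, height = config$height)
  hsv <- to_hsv(img)
  bright <- hsv$val / 100
  satur <- hsv$sat / 100
  huef <- hsv$hue / 360
  dims <- c(img$height, img$width)
  win <- with_feature_name("box_size_ladder",
    lapply(c(small = "small", large = "large", overall = "overall"),
           function(l) scale_window(dims, l)))
  flags <- character()
  grab_flag <- function(name, v) {
    if (isTRUE(attr(v, "flagged"))) flags <<- c(flags, name)
    as.numeric(v)
  }
  out <- c()
  gp <- with_feature_name("greenery_pct",
                          greenery_percentage(img, config$criteria))
  out["greenery_pct"] <- gp
  out["sqrt_greenery"] <- sqrt_transform(gp)
  out["mean_brightness"] <- with_feature_name("mean_brightness", mean_channel(bright))
  out["mean_saturation"] <- with_feature_name("mean_saturation", mean_channel(satur))
  out["shape_fractal"] <- grab_flag("shape_fractal", with_feature_name(
    "shape_fractal",
    suppressWarnings(shape_fractal(img, high_quantile = config$edge_high_quantile,
                                   low_ratio = config$edge_low_ratio))))
  channels <- list(brightness = bright, saturation = satur, hue = huef)
  for (lab in names(win)) {
    nm <- paste0("geom_fractal_brightness_", lab)
    out[nm] <- grab_flag(nm, with_feature_name(
      nm, suppressWarnings(geometric_fractal(bright, win[[lab]]))))
  }
  for (ch in names(channels)) for (lab in names(win)) {
    nm <- paste0("stat_fractal_", ch, "_", lab)
    out[nm] <- with_feature_name(
      nm, statistical_fractal(channels[[ch]], win[[lab]]))
  }
  out["color_fractal"] <- with_feature_name("color_fractal", color_fractal(img))
  for (ch in c("brightness", "saturation")) {
    nm <- paste0("one_over_f_", ch)
    out[nm] <- with_feature_name(nm, {
      f <- channels[[ch]]
      if (max(f) == min(f)) {        # constant channel: flat spectrum
        flags <- c(flags, nm)
        0
      } else one_over_f_fluctuation(f, n_bins = config$fft_bins)
    })
  }
  structure(out, source_id = img$source_id, flags = flags)
}

#' Extract features for a list of images
#'
#' @param images List of [raster_image] objects (or a directory path of
#'   PNG/JPEG files, read in sorted order).
#' @param config A [feature_config].
#' @return Tibble with `source_id`, `greenery_pct`, and the 19 indicator
#'   columns, one row per image.
#' @export
extract_features_batch <- function(images, config = feature_config()) {
  if (is.character(images) && length(images) == 1 && dir.exists(images)) {
    paths <- sort(list.files(images, pattern = "\\.(png|jpe?g)$",
                             ignore.case = TRUE, full.names = TRUE))
    images <- lapply(paths, read_image)
  }
  rows <- lapply(images, function(im) {
    v <- extract_features(im, config)
    tibble::as_tibble(c(list(source_id = attr(v, "source_id")),
                        as.list(v)))
  })
  dplyr::bind_rows(rows)
}

#' Write / read a feature table as CSV
#'
#' Comma-separated, UTF-8, '.' decimal separator, header row mandatory.
#'
#' @param features Tibble from [extract_features_batch()].
#' @param path CSV path.
#' @return [write_features()]: `path`; [read_features()]: the tibble.
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  tibble::as_tibble(utils::read.csv(path, fileEncoding = "UTF-8",
                                    check.names = FALSE))
}
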