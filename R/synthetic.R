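#' Sierpinski carpet mask
#'
#' Analytic fixture for the box-counting estimators: the level-`level`
#' Sierpinski carpet on a `3^level x 3^level` grid. Its box-counting
#' dimension is exactly `log(8)/log(3) = 1.8928`, and the occupied fraction
#' is `(8/9)^level`.
#'
#' @param level Recursion depth, 1 to 6.
#' @return Logical `3^level x 3^level` matrix.
#' @export
gen_sierpinski <- function(level) {
  if (level < 1 || level > 6) stop("level must be between 1 and 6")
  base <- matrix(TRUE, 3, 3); base[2, 2] <- FALSE
  m <- base
  if (level > 1) for (i in 2:level) m <- kronecker(m, base)
  m
}

## Shared spectral-synthesis engine: white Gaussian noise filtered so the
## amplitude spectrum falls off as f^(-exponent); real by Hermitian symmetry
## of the radially symmetric filter.
spectral_noise <- function(exponent, size, seed) {
  wn <- withr::with_seed(seed, matrix(stats::rnorm(size * size), size, size))
  f <- radial_freq(size, size)
  filt <- ifelse(f > 0, f^(-exponent), 0)
  x <- Re(stats::fft(stats::fft(wn) * filt, inverse = TRUE)) / size^2
  (x - min(x)) / (max(x) - min(x))   # affine map to [0, 1]; slope unchanged
}

#' Fractional Brownian surface (spectral synthesis)
#'
#' Synthesizes an isotropic fractional Brownian motion surface with Hurst
#' exponent `H` by filtering white noise so the amplitude spectrum falls off
#' as \eqn{f^{-(H+1)}}, then normalizing to `[0, 1]`. The analytic fractal
#' dimension of such a surface is `D = 3 - H`. To reproduce the
#' supra-Nyquist power that a truly sampled fBm aliases into the grid
#' (plain band-limited synthesis leaves the field too smooth at 1-2 pixel
#' lags, distorting its small-lag increment scaling), the surface is
#' synthesized at 4x resolution and decimated, for sizes up to 1024.
#'
#' @param H Hurst exponent in `(0, 1)`.
#' @param size Side length, a power of 2, at least 64.
#' @param seed Integer seed; output is bit-reproducible per seed.
#' @return A [channel_field] of dimension `size x size`.
#' @export
gen_fbm_surface <- function(H, size = 512, seed = 1) {
  if (H <= 0 || H >= 1) stop("Hurst exponent must lie in (0, 1)")
  if (size < 64 || bitwAnd(size, size - 1L) != 0)
    stop("size must be a power of 2, at least 64")
  factor <- if (size <= 1024) 4L else 1L
  x <- spectral_noise(H + 1, factor * size, seed)
  if (factor > 1L) {
    idx <- seq(1L, factor * size, by = factor)
    x <- x[idx, idx]
    x <- (x - min(x)) / (max(x) - min(x))
  }
  channel_field(x, "fbm")
}

#' Noise field with a planted spectral exponent
#'
#' Synthesizes 2-D noise whose radially averaged amplitude spectrum falls
#' off as \eqn{f^{-\beta}}; the oracle fixture for
#' [one_over_f_fluctuation()], which should recover `beta`.
#'
#' @param beta Amplitude-spectrum exponent in `[0, 3]`.
#' @param size Side length, a power of 2.
#' @param seed Integer seed.
#' @return A [channel_field] of dimension `size x size`.
#' @export
gen_spectral_image <- function(beta, size = 512, seed = 1) {
  if (beta < 0 || beta > 3) stop("beta must lie in [0, 3]")
  channel_field(spectral_noise(beta, size, seed), "spectral_noise")
}

#' Specification of a synthetic office scene
#'
#' Parameters controlling one generated office-like image: working size,
#' target green-pixel percentage, number of elliptical plant blobs,
#' background style and its spectral complexity, and the seed.
#'
#' @param greenery_target Target green-area percentage in `[0, 100]`.
#' @param width,height Image size in pixels, each at least 64.
#' @param n_plant_blobs Initial number of plant ellipses.
#' @param background `"flat"`, `"gradient"`, or `"texture"`.
#' @param texture_exponent Spectral exponent of the textured background.
#' @param n_furniture Number of furniture-like rectangles.
#' @param colorfulness In `[0, 1]`: how saturated and hue-diverse the
#'   (non-green) furniture palette and clutter are. Drives colour
#'   complexity independently of greenery, as real offices do.
#' @param clutter_grain Edge length (pixels) of the clutter patches; fine
#'   grain roughens the per-channel textures, coarse grain raises colour
#'   diversity while leaving channel surfaces smoother.
#' @param palette_size Number of distinct colours in the clutter palette.
#'   A small palette gives rough hue texture with little colour diversity;
#'   a large one raises the joint colour diversity at fixed span. Clutter
#'   only nudges the brightness surface (small per-patch offsets), so the
#'   colour and brightness axes vary separately.
#' @param clutter_coverage Fraction of non-plant pixels covered by clutter.
#' @param hue_span In `[0, 1]`: width of the (non-green) hue band and
#'   saturation range the clutter palette is drawn from. Drives the range
#'   (and hence the surface roughness) of the hue and saturation channels,
#'   while `palette_size` drives how densely that range is filled.
#' @param seed Integer seed.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(greenery_target, width = 640, height = 320,
                       n_plant_blobs = 6,
                       background = c("flat", "gradient", "texture"),
                       texture_exponent = 1.2,
                       n_furniture = 8, colorfulness = 0.3,
                       clutter_grain = 4, palette_size = 16,
                       clutter_coverage = 0.5, hue_span = 0.7, seed = 1) {
  background <- match.arg(background)
  if (greenery_target < 0 || greenery_target > 100)
    stop("greenery_target must lie in [0, 100]")
  if (width < 64 || height < 64) stop("width and height must be >= 64")
  if (colorfulness < 0 || colorfulness > 1)
    stop("colorfulness must lie in [0, 1]")
  structure(list(greenery_target = greenery_target, width = width,
                 height = height, n_plant_blobs = n_plant_blobs,
                 background = background,
                 texture_exponent = texture_exponent,
                 n_furniture = n_furniture, colorfulness = colorfulness,
                 clutter_grain = clutter_grain,
                 palette_size = palette_size,
                 clutter_coverage = clutter_coverage, hue_span = hue_span,
                 seed = seed),
            class = "scene_spec")
}

## Vectorized HSV -> 8-bit RGB (hue degrees, sat/val percent).
hsv_to_rgb255 <- function(hue, sat, val) {
  cols <- grDevices::hsv(pmin(hue / 360, 1 - 1e-9), sat / 100, val / 100)
  t(grDevices::col2rgb(cols))
}

#' Generate an office-like synthetic scene
#'
#' Builds a non-green background (flat, vertical gradient, or 1/f-textured;
#' warm low-saturation hues that can never satisfy the green criteria) and
#' adds elliptical "plant" blobs whose HSV values are drawn strictly inside
#' the detection window (hue 70-150 deg, saturation 30-90%, value 20-90%),
#' growing or shrinking the planted area until the measured
#' [greenery_percentage()] is within 2 percentage points of the target
#' (exactly 0 when the target is 0). Deterministic per seed.
#'
#' @param spec A [scene_spec].
#' @param crit The [hsv_criteria] the generator calibrates against.
#' @return A [raster_image]; attribute `greenery_measured` records the
#'   achieved percentage.
#' @export
gen_office_scene <- function(spec, crit = hsv_criteria()) {
  stopifnot(inherits(spec, "scene_spec"))
  h <- spec$height; w <- spec$width; n <- h * w
  withr::with_seed(spec$seed, {
    ## background: hue 20-40 (warm), saturation below the green floor
    bg_hue <- stats::runif(1, 20, 40)
    bg_sat <- stats::runif(1, 3, 12)
    base_val <- switch(spec$background,
      flat = matrix(stats::runif(1, 40, 80), h, w),
      gradient = matrix(rep(seq(30, 85, length.out = w), each = h), h, w),
      texture = {
        tx <- spectral_noise(spec$texture_exponent, 2^ceiling(log2(max(h, w))),
                             seed = spec$seed + 77L)
        20 + 70 * tx[seq_len(h), seq_len(w)]
      })
    rgb <- hsv_to_rgb255(rep(bg_hue, n), rep(bg_sat, n), as.vector(base_val))
    ## furniture-like rectangles: hue drawn outside the green window, with
    ## saturation/hue diversity scaled by the colorfulness control, so
    ## colour complexity varies independently of greenery
    for (i in seq_len(spec$n_furniture)) {
      r0 <- sample.int(h - 16, 1); c0 <- sample.int(w - 16, 1)
      rh <- sample.int(h %/% 3, 1) + 8; rw <- sample.int(w %/% 3, 1) + 8
      rows <- r0:min(r0 + rh, h); cols <- c0:min(c0 + rw, w)
      idx <- as.vector(outer(rows, (cols - 1) * h, `+`))
      fh <- if (stats::runif(1) < 0.5) stats::runif(1, 185, 355)
            else stats::runif(1, 0, 42)
      rect_col <- hsv_to_rgb255(fh,
                                stats::runif(1, 2, 8 + 70 * spec$colorfulness),
                                stats::runif(1, 20, 95))
      rgb[idx, ] <- matrix(rect_col, length(idx), 3, byrow = TRUE)
    }
    target <- spec$greenery_target
    if (target > 0) {
      rowg <- as.vector(row(matrix(0, h, w)))
      colg <- as.vector(col(matrix(0, h, w)))
      ## coherent foliage colour: one base tone per blob plus small
      ## pixel-level jitter, all strictly inside the detection window --
      ## plants read as smooth green regions, not colour noise
      green_of <- function(k) {
        hb <- stats::runif(1, 82, 138); sb <- stats::runif(1, 40, 80)
        vb <- stats::runif(1, 32, 78)
        hsv_to_rgb255(pmin(pmax(hb + stats::rnorm(k, 0, 3), 71), 149),
                      pmin(pmax(sb + stats::rnorm(k, 0, 3), 31), 89),
                      pmin(pmax(vb + stats::rnorm(k, 0, 4), 21), 89))
      }
      painted <- rep(FALSE, n)
      paint_blob <- function(area) {
        rad <- sqrt(area / pi)
        cy <- stats::runif(1, rad, h - rad); cx <- stats::runif(1, rad, w - rad)
        ax <- rad * stats::runif(1, 0.6, 1.6); ay <- (area / pi) / ax
        inside <- ((rowg - cy) / ay)^2 + ((colg - cx) / ax)^2 <= 1
        inside & !painted
      }
      iter <- 0
      repeat {
        iter <- iter + 1
        cur <- 100 * sum(painted) / n
        if (abs(cur - target) <= 2) break
        if (iter > 400) stop("greenery target unreachable at this image size")
        if (cur < target) {
          deficit_px <- (target - cur) / 100 * n
          area <- max(40, min(deficit_px, n / max(4, spec$n_plant_blobs)))
          new <- paint_blob(area)
          if (any(new)) {
            ## trim overshoot inside this blob
            excess <- sum(painted) + sum(new) - target / 100 * n
            if (excess > 0) {
              drop <- utils::tail(which(new), round(excess))
              new[drop] <- FALSE
            }
            rgb[new, ] <- green_of(sum(new))
            painted <- painted | new
          }
        } else {
          ## erode: repaint surplus painted pixels with background colour
          surplus <- round((cur - target) / 100 * n)
          drop <- utils::tail(which(painted), surplus)
          rgb[drop, ] <- hsv_to_rgb255(rep(bg_hue, length(drop)),
                                       rep(bg_sat, length(drop)),
                                       base_val[drop])
          painted[drop] <- FALSE
        }
      }
    }
    ## clutter speckle on non-plant pixels: density scales with
    ## colorfulness; hue confined to the non-green bands so the greenery
    ## calibration is untouched. This is what separates drab offices from
    ## colour-busy ones independently of their plants.
    if (spec$colorfulness > 0) {
      unpainted <- if (exists("painted", inherits = FALSE)) !painted
                   else rep(TRUE, n)
      grain <- max(1L, as.integer(spec$clutter_grain))
      n_patch <- round(spec$clutter_coverage * sum(unpainted) / grain^2)
      if (n_patch > 0) {
        np <- max(2L, as.integer(spec$palette_size))
        ## palette drawn from a blue-violet band of width hue_span * 170
        ## degrees centred at 270 (never green); saturation range scales
        ## with the same span
        half <- 85 * spec$hue_span
        pal_hue <- stats::runif(np, 270 - half, 270 + half)
        pal_sat <- stats::runif(np, 5, 10 + 75 * spec$hue_span)
        pal_val <- stats::runif(np, 10, 95)
        anchors <- sample(which(unpainted), min(n_patch, sum(unpainted)))
        a_row <- (anchors - 1L) %% h + 1L
        a_col <- (anchors - 1L) %/% h + 1L
        pick <- sample.int(np, length(anchors), replace = TRUE)
        for (b in seq_along(anchors)) {
          rows <- a_row[b]:min(a_row[b] + grain - 1L, h)
          cols <- a_col[b]:min(a_col[b] + grain - 1L, w)
          idx <- as.vector(outer(rows, (cols - 1L) * h, `+`))
          idx <- idx[unpainted[idx]]
          if (length(idx))
            rgb[idx, ] <- hsv_to_rgb255(rep(pal_hue[pick[b]], length(idx)),
                                        rep(pal_sat[pick[b]], length(idx)),
                                        rep(pal_val[pick[b]], length(idx)))
        }
      }
    }
    px <- array(0L, c(h, w, 3))
    px[, , 1] <- rgb[, 1]; px[, , 2] <- rgb[, 2]; px[, , 3] <- rgb[, 3]
    img <- raster_image(px, source_id = sprintf("scene_g%02.0f_s%d",
                                                spec$greenery_target, spec$seed))
    attr(img, "greenery_measured") <- greenery_percentage(img, crit)
    img
  })
}

#' Generate a balanced photo set
#'
#' Generates `length(specs)` scenes and assigns them to `n_groups` groups
#' of equal size, balancing greenery across groups: photos are sorted by
#' target greenery and dealt in snake order (1..k, k..1, ...), so every
#' group spans low to high greenery and group means stay close to the
#' grand mean.
#'
#' @param specs List of [scene_spec] objects (default emulation: 60 scenes
#'   spanning 0-60% greenery).
#' @param n_groups Number of groups; must divide `length(specs)`.
#' @return List with `images` (list of [raster_image]) and `manifest`
#'   (tibble: photo_id, group, greenery_target, greenery_measured, seed).
#' @export
gen_photo_set <- function(specs = default_scene_specs(), n_groups = 12) {
  n <- length(specs)
  if (n %% n_groups != 0) stop("n_groups must divide the number of scenes")
  targets <- vapply(specs, `[[`, numeric(1), "greenery_target")
  ord <- order(targets)
  group <- integer(n)
  snake <- c(seq_len(n_groups), rev(seq_len(n_groups)))
  group[ord] <- rep_len(snake, n)   # snake-deal by sorted greenery
  images <- lapply(seq_len(n), function(i) {
    img <- gen_office_scene(specs[[i]])
    img$source_id <- sprintf("photo_%02d", i)
    img
  })
  manifest <- tibble::tibble(
    photo_id = vapply(images, `[[`, character(1), "source_id"),
    group = group,
    greenery_target = targets,
    greenery_measured = vapply(images, attr, numeric(1), "greenery_measured"),
    seed = vapply(specs, `[[`, numeric(1), "seed"))
  list(images = images, manifest = manifest)
}

#' Default scene specifications for a study-shaped photo set
#'
#' 60 scenes with greenery targets evenly spanning 0-60% (the observed range
#' in office photography). Background style, texture exponent, furniture
#' count and palette colorfulness cycle with periods coprime to the greenery
#' ramp, so colour and brightness complexity vary independently of greenery.
#'
#' @param n Number of scenes.
#' @param max_green Largest greenery target (percent).
#' @param width,height Scene size in pixels.
#' @param seed Base seed; scene `i` uses `seed + i`.
#' @return List of [scene_spec].
#' @export
default_scene_specs <- function(n = 60, max_green = 60,
                                width = 640, height = 320, seed = 100) {
  ## Knob cycles use periods coprime to the 24-scene snake-dealing cycle
  ## (and mutually distinct), so no scene attribute aligns with the photo
  ## groups or with another attribute.
  backgrounds <- rep(c("flat", "gradient", "texture", "texture", "flat",
                       "gradient", "texture", "flat", "texture", "gradient",
                       "flat"), length.out = n)                      # 11
  exponents <- rep(c(0.6, 1.0, 1.4, 1.8, 0.8, 1.2, 1.6, 0.7, 1.1, 1.5,
                     0.9, 1.3, 1.7, 0.65, 1.05, 1.45, 1.75),
                   length.out = n)                                   # 17
  furniture <- rep(c(4, 16, 9, 22, 6, 13, 18, 8, 20, 5, 11, 15, 7, 19, 10,
                     21, 12, 17, 14), length.out = n)                # 19
  ## colour-complexity axis (13): palette density, the unique driver of
  ## the joint colour diversity; coverage (5), grain (7) and hue/sat span
  ## (11) vary on their own cycles and drive the channel-range indicators
  ci <- rep(c(0, 0.45, 0.9, 0.15, 0.75, 0.3, 1, 0.6, 0.05, 0.85, 0.35,
              0.7, 0.2), length.out = n)                             # 13
  coverage <- rep(c(0.2, 0.7, 0.45, 0.9, 0.3), length.out = n)       # 5
  grains <- rep(c(2, 8, 4, 16, 1, 6, 3), length.out = n)             # 7
  spans <- rep(c(0.3, 1, 0.6, 0.85, 0.45, 0.15, 0.75, 1, 0.5, 0.25,
                 0.9), length.out = n)                               # 11
  palettes <- pmax(2, round(2 * 4096^ci))
  targets <- seq(0, max_green, length.out = n)
  lapply(seq_len(n), function(i)
    scene_spec(greenery_target = targets[i], width = width, height = height,
               background = backgrounds[i], texture_exponent = exponents[i],
               n_furniture = furniture[i], colorfulness = spans[i],
               clutter_grain = grains[i], palette_size = palettes[i],
               clutter_coverage = coverage[i], hue_span = spans[i],
               seed = seed + i))
}

#' Specification of a rating simulation
#'
#' Parameters of the grouped Likert rating generator: the study-shaped
#' default is 60 photos in 12 groups of 5, each group rated by its own
#' raters on all 11 IRCS items. Latent photo means are
#' `mu_p = a + b * sqrt_greenery_p + c * color_fractal_p`; a participant
#' offset (SD `sigma/2`) and an item-level residual (SD `sigma`) are added
#' before round-then-clamp discretization onto the 1-5 response scale.
#'
#' @param n_photos,n_groups,photos_per_group Study geometry; must satisfy
#'   `n_photos = n_groups * photos_per_group`.
#' @param raters_per_group Raters per group (the study had ~100).
#' @param a Intercept of the latent mean (response-scale units).
#' @param b Slope on the square root of greenery (per unit sqrt-percent).
#' @param c Slope on the colour fractal dimension.
#' @param sigma Residual SD of a single item response; participant offsets
#'   use `sigma / 2`.
#' @param seed Integer seed.
#' @return An object of class `rating_sim_spec`.
#' @export
rating_sim_spec <- function(n_photos = 60, n_groups = 12, photos_per_group = 5,
                            raters_per_group = 100,
                            a = 2.8, b = 0.12, c = -0.10, sigma = 0.6,
                            seed = 1) {
  if (n_photos != n_groups * photos_per_group)
    stop("n_photos must equal n_groups * photos_per_group")
  if (raters_per_group < 1) stop("raters_per_group must be >= 1")
  if (sigma < 0) stop("sigma must be >= 0")
  structure(list(n_photos = n_photos, n_groups = n_groups,
                 photos_per_group = photos_per_group,
                 raters_per_group = raters_per_group,
                 a = a, b = b, c = c, sigma = sigma, seed = seed),
            class = "rating_sim_spec")
}

#' Simulate grouped IRCS ratings with planted effect structure
#'
#' Draws long-format ratings whose photo-level means depend linearly on the
#' square root of greenery and on the colour fractal dimension (see
#' [rating_sim_spec()]). Each rater belongs to one photo group and rates the
#' group's photos on all 11 items of the scale. Responses are
#' `clamp(round(mu_p + participant offset + residual), 1, 5)`.
#'
#' @param features Data frame with columns `photo_id`, `sqrt_greenery`,
#'   `color_fractal`, and optionally `group` (assigned round-robin by
#'   greenery when absent).
#' @param spec A [rating_sim_spec].
#' @param scale An [ircs_scale()] definition supplying the item ids.
#' @return Tibble with columns `participant_id`, `photo_id`, `item_id`,
#'   `response`.
#' @export
gen_ratings <- function(features, spec = rating_sim_spec(),
                        scale = ircs_scale()) {
  stopifnot(inherits(spec, "rating_sim_spec"))
  req <- c("photo_id", "sqrt_greenery", "color_fractal")
  if (!all(req %in% names(features)))
    stop("features must contain ", paste(req, collapse = ", "))
  if (nrow(features) != spec$n_photos)
    stop("features must have exactly n_photos rows")
  feats <- features
  if (!"group" %in% names(feats)) {
    grp <- integer(nrow(feats))
    grp[order(feats$sqrt_greenery)] <- rep_len(seq_len(spec$n_groups), nrow(feats))
    feats$group <- grp
  }
  mu <- spec$a + spec$b * feats$sqrt_greenery + spec$c * feats$color_fractal
  items <- scale$items$item_id
  n_items <- length(items)
  withr::with_seed(spec$seed, {
    out <- vector("list", spec$n_groups)
    for (g in seq_len(spec$n_groups)) {
      pidx <- which(feats$group == g)
      n_resp <- spec$raters_per_group * length(pidx) * n_items
      offsets <- stats::rnorm(spec$raters_per_group, 0, spec$sigma / 2)
      rater_id <- sprintf("g%02d_r%03d", g, seq_len(spec$raters_per_group))
      df <- tibble::tibble(
        participant_id = rep(rater_id, each = length(pidx) * n_items),
        photo_id = rep(rep(feats$photo_id[pidx], each = n_items),
                       times = spec$raters_per_group),
        item_id = rep(items, times = spec$raters_per_group * length(pidx)))
      latent <- rep(rep(mu[pidx], each = n_items), times = spec$raters_per_group) +
        rep(offsets, each = length(pidx) * n_items) +
        stats::rnorm(n_resp, 0, spec$sigma)
      rev_item <- scale$items$reverse[match(df$item_id, scale$items$item_id)]
      latent[rev_item] <- 6 - latent[rev_item]
      df$response <- as.integer(pmin(pmax(round(latent), 1), 5))
      out[[g]] <- df
    }
    dplyr::bind_rows(out)
  })
}
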