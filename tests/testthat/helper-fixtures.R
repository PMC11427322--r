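# Fixture builders and independent brute-force oracles shared by the suite.
# Everything is generated in code; no binary fixtures.

# Build a raster_image from per-pixel HSV matrices (hue degrees, sat/val %).
image_from_hsv <- function(hue, sat, val, source_id = "hsv_fixture") {
  stopifnot(all(dim(hue) == dim(sat)), all(dim(hue) == dim(val)))
  cols <- grDevices::hsv(pmin(as.vector(hue) / 360, 1 - 1e-9),
                         as.vector(sat) / 100, as.vector(val) / 100)
  rgb <- grDevices::col2rgb(cols)
  px <- array(0L, c(nrow(hue), ncol(hue), 3))
  for (ch in 1:3) px[, , ch] <- matrix(rgb[ch, ], nrow(hue), ncol(hue))
  raster_image(px, source_id)
}

uniform_image <- function(r, g, b, h = 32, w = 32, source_id = "uniform") {
  px <- array(0L, c(h, w, 3))
  px[, , 1] <- r; px[, , 2] <- g; px[, , 3] <- b
  raster_image(px, source_id)
}

random_image <- function(h, w, seed) {
  withr::with_seed(seed,
    raster_image(array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3)),
                 sprintf("random_%d", seed)))
}

# Naive per-pixel greenery oracle: explicit loop, scalar rgb2hsv per pixel.
naive_greenery <- function(img, crit = hsv_criteria()) {
  n_green <- 0L
  for (i in seq_len(img$height)) for (j in seq_len(img$width)) {
    hsv <- grDevices::rgb2hsv(img$pixels[i, j, 1], img$pixels[i, j, 2],
                              img$pixels[i, j, 3], maxColorValue = 255)
    hue <- (hsv[1] * 360) %% 360; sat <- hsv[2] * 100; val <- hsv[3] * 100
    if (hue >= crit$hue_min && hue <= crit$hue_max &&
        sat >= crit$sat_min && sat <= crit$sat_max &&
        val >= crit$val_min && val <= crit$val_max)
      n_green <- n_green + 1L
  }
  100 * n_green / (img$height * img$width)
}

# OLS slope of log N vs log(1/eps) computed longhand.
naive_loglog_slope <- function(eps, N) {
  x <- log(1 / eps); y <- log(N)
  xbar <- mean(x); ybar <- mean(y)
  sum((x - xbar) * (y - ybar)) / sum((x - xbar)^2)
}

# Brute-force box count: explicit loops over the box grid.
naive_box_count_dimension <- function(mask, window) {
  N <- numeric(length(window))
  for (k in seq_along(window)) {
    e <- window[k]; cnt <- 0L
    for (i0 in seq(1, nrow(mask), by = e)) for (j0 in seq(1, ncol(mask), by = e)) {
      cell <- mask[i0:min(i0 + e - 1, nrow(mask)),
                   j0:min(j0 + e - 1, ncol(mask)), drop = FALSE]
      if (any(cell)) cnt <- cnt + 1L
    }
    N[k] <- cnt
  }
  naive_loglog_slope(window, N)
}

# Brute-force differential box counting (same contract as the estimator).
naive_statistical_fractal <- function(m, window) {
  M <- min(dim(m))
  N <- numeric(length(window))
  for (k in seq_along(window)) {
    e <- window[k]; h_box <- e / M; tot <- 0
    for (i0 in seq(1, nrow(m), by = e)) for (j0 in seq(1, ncol(m), by = e)) {
      cell <- m[i0:min(i0 + e - 1, nrow(m)), j0:min(j0 + e - 1, ncol(m))]
      tot <- tot + ceiling((max(cell) - min(cell)) / h_box) + 1
    }
    N[k] <- tot
  }
  naive_loglog_slope(window, N)
}

# Brute-force spectral exponent: DFT by definition (per-frequency loop),
# explicit radial binning and longhand regression.
naive_one_over_f <- function(m, n_bins = 24) {
  h <- nrow(m); w <- ncol(m)
  x <- m - mean(m)
  P <- matrix(0, h, w)
  for (u in 0:(h - 1)) for (v in 0:(w - 1)) {
    ph <- -2i * pi * (u * (row(x) - 1) / h + v * (col(x) - 1) / w)
    P[u + 1, v + 1] <- Mod(sum(x * exp(ph)))^2
  }
  fy <- ifelse(0:(h - 1) <= h %/% 2, 0:(h - 1), 0:(h - 1) - h) / h
  fx <- ifelse(0:(w - 1) <= w %/% 2, 0:(w - 1), 0:(w - 1) - w) / w
  f <- sqrt(outer(fy^2, fx^2, `+`))
  fmin <- 2 / min(h, w); fmax <- 0.25
  keep <- f >= fmin & f <= fmax
  edges <- exp(seq(log(fmin), log(fmax), length.out = n_bins + 1))
  bin <- cut(f[keep], edges, include.lowest = TRUE, labels = FALSE)
  pbar <- tapply(P[keep], bin, mean)
  fbar <- tapply(f[keep], bin, function(z) exp(mean(log(z))))
  ok <- is.finite(pbar) & pbar > 0
  -naive_loglog_slope(1 / fbar[ok], pbar[ok]) / 2
}

# Koch snowflake polygon, rasterized by scanline fill; the boundary of the
# filled region has dimension log(4)/log(3).
koch_snowflake_image <- function(size = 729, level = 5) {
  subdivide <- function(pts) {
    out <- matrix(0, 0, 2)
    for (i in seq_len(nrow(pts) - 1)) {
      p <- pts[i, ]; q <- pts[i + 1, ]
      d <- q - p
      a <- p + d / 3; b <- p + 2 * d / 3
      rot <- c(d[1] / 3 * cos(-pi / 3) - d[2] / 3 * sin(-pi / 3),
               d[1] / 3 * sin(-pi / 3) + d[2] / 3 * cos(-pi / 3))
      out <- rbind(out, p, a, a + rot, b)
    }
    rbind(out, pts[nrow(pts), ])
  }
  s <- 0.62 * size
  cx <- size / 2; cy <- size / 2
  ang <- c(pi / 2, pi / 2 + 2 * pi / 3, pi / 2 + 4 * pi / 3, pi / 2)
  pts <- cbind(cx + s / sqrt(3) * cos(ang), cy + s / sqrt(3) * sin(ang))
  for (i in seq_len(level)) pts <- subdivide(pts)
  inside <- matrix(FALSE, size, size)
  xs <- pts[, 1]; ys <- pts[, 2]
  n <- nrow(pts) - 1
  for (r in seq_len(size)) {            # scanline y = r
    y <- r - 0.5
    cross <- c()
    for (i in seq_len(n)) {
      y1 <- ys[i]; y2 <- ys[i + 1]
      if ((y1 <= y && y2 > y) || (y2 <= y && y1 > y)) {
        t <- (y - y1) / (y2 - y1)
        cross <- c(cross, xs[i] + t * (xs[i + 1] - xs[i]))
      }
    }
    cross <- sort(cross)
    if (length(cross) >= 2)
      for (k in seq(1, length(cross) - 1, by = 2)) {
        j0 <- max(1, ceiling(cross[k])); j1 <- min(size, floor(cross[k + 1]))
        if (j0 <= j1) inside[r, j0:j1] <- TRUE
      }
  }
  px <- array(30L, c(size, size, 3))
  for (ch in 1:3) { tmp <- px[, , ch]; tmp[inside] <- 230L; px[, , ch] <- tmp }
  raster_image(px, "koch_snowflake")
}

# Half-green/half-red vertical split at the working resolution.
half_green_image <- function(h = 320, w = 640) {
  hue <- matrix(0, h, w); hue[, seq_len(w / 2)] <- 120
  image_from_hsv(hue, matrix(50, h, w), matrix(50, h, w), "half_green")
}

# Complete single-participant IRCS response, all items at `value`.
flat_response <- function(value, scale = ircs_scale()) {
  stats::setNames(rep(value, nrow(scale$items)), scale$items$item_id)
}
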