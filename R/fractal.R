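#' Box-size ladder for multi-scale fractal estimation
#'
#' Builds the ordered list of box edge lengths used by the box-counting
#' estimators. The full ladder is powers of 2 from 2 up to `min(H, W) / 4`;
#' the `"small"` window is the lower half of the ladder, `"large"` the upper
#' half, and `"overall"` the whole ladder. Every window keeps at least three
#' rungs so the log-log regression is determined.
#'
#' @param dims Integer vector `c(H, W)` (or a [raster_image] /
#'   [channel_field] whose dimensions are used).
#' @param label One of `"small"`, `"large"`, `"overall"`.
#' @return Integer vector of box sizes, strictly increasing.
#' @export
scale_window <- function(dims, label = c("overall", "small", "large")) {
  label <- match.arg(label)
  if (inherits(dims, "raster_image")) dims <- c(dims$height, dims$width)
  if (is.matrix(dims)) dims <- dim(dims)
  m <- min(dims)
  kmax <- floor(log2(m / 4))
  if (kmax < 1) stop("image too small for a box-size ladder")
  sizes <- 2^(1:kmax)
  n <- length(sizes)
  if (n < 3) stop("fewer than 3 box sizes available; image too small")
  half <- ceiling(n / 2)
  switch(label,
         overall = sizes,
         small = sizes[seq_len(max(3, half))],
         large = sizes[seq.int(n - max(3, n - half) + 1, n)])
}

## log-log OLS slope shared by all box-count estimators:
## slope of log(N) against log(1/eps).
loglog_slope <- function(eps, N) {
  x <- log(1 / eps)
  y <- log(N)
  stats::cov(x, y) / stats::var(x)
}

## Number of eps-boxes (grid anchored top-left, partial boxes counted)
## containing at least one TRUE cell.
count_boxes <- function(mask, eps) {
  occ <- which(mask, arr.ind = TRUE)
  bi <- (occ[, 1] - 1L) %/% eps
  bj <- (occ[, 2] - 1L) %/% eps
  nbi <- (nrow(mask) + eps - 1L) %/% eps
  length(unique(bi + nbi * bj))
}

#' Box-counting fractal dimension of a binary mask
#'
#' Classic box counting: for each box edge length \eqn{\epsilon} in the
#' window, the grid (anchored at the top-left corner, partial boxes at the
#' right/bottom edges counted) is scanned and \eqn{N(\epsilon)}, the number
#' of boxes containing at least one occupied cell, recorded. The dimension
#' is the ordinary-least-squares slope of \eqn{\log N(\epsilon)} against
#' \eqn{\log(1/\epsilon)}.
#'
#' @param mask Logical `H x W` matrix with at least one `TRUE` cell.
#' @param window Integer vector of box sizes (see [scale_window()]).
#' @return Estimated dimension (a point yields 0, a filled plane 2).
#' @export
box_count_dimension <- function(mask, window = scale_window(mask)) {
  if (!is.logical(mask)) mask <- mask != 0
  if (!any(mask)) stop("all-empty mask: box-counting dimension undefined")
  if (any(diff(window) <= 0) || any(window < 1) || max(window) > min(dim(mask)))
    stop("invalid scale window")
  if (length(window) < 3) stop("need at least 3 box sizes")
  N <- vapply(window, function(e) count_boxes(mask, e), numeric(1))
  loglog_slope(window, N)
}

## 3x3 shifts with edge replication; used by the gradient operators.
shift_pad <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(seq_len(h) + dr, 1L), h)
  ci <- pmin(pmax(seq_len(w) + dc, 1L), w)
  m[ri, ci, drop = FALSE]
}

sobel_gradient <- function(field) {
  gx <- (shift_pad(field, -1, 1) + 2 * shift_pad(field, 0, 1) + shift_pad(field, 1, 1)) -
        (shift_pad(field, -1, -1) + 2 * shift_pad(field, 0, -1) + shift_pad(field, 1, -1))
  gy <- (shift_pad(field, 1, -1) + 2 * shift_pad(field, 1, 0) + shift_pad(field, 1, 1)) -
        (shift_pad(field, -1, -1) + 2 * shift_pad(field, -1, 0) + shift_pad(field, -1, 1))
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

## Canny-style edge map: Sobel gradient, non-maximum suppression along the
## quantized gradient direction, then hysteresis. Thresholds are data-driven
## (high = `high_quantile` of the non-zero gradient magnitudes, low =
## `low_ratio` * high) so edge maps are comparable across photographs.
edge_map <- function(field, high_quantile = 0.9, low_ratio = 0.5) {
  g <- sobel_gradient(field)
  mag <- g$mag
  nz <- mag[mag > 0]
  if (length(nz) == 0) return(matrix(FALSE, nrow(field), ncol(field)))
  ang <- atan2(g$gy, g$gx)                  # [-pi, pi]
  sector <- (round(ang / (pi / 4)) %% 4)    # 0:E-W 1:NE-SW 2:N-S 3:NW-SE
  n1 <- mag; n2 <- mag
  for (s in 0:3) {
    d <- switch(as.character(s),
                "0" = c(0L, 1L), "1" = c(1L, 1L),
                "2" = c(1L, 0L), "3" = c(1L, -1L))
    idx <- sector == s
    n1[idx] <- shift_pad(mag, d[1], d[2])[idx]
    n2[idx] <- shift_pad(mag, -d[1], -d[2])[idx]
  }
  ## strict on one side so plateau ties keep a single-pixel ridge
  thin <- mag > n1 & mag >= n2
  high <- stats::quantile(nz, high_quantile, names = FALSE)
  low <- low_ratio * high
  strong <- thin & mag >= high
  weak <- thin & mag >= low
  ## hysteresis: grow strong edges through connected weak pixels
  cur <- strong
  repeat {
    grown <- cur
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      grown <- grown | shift_pad(cur, dr, dc)
    }
    grown <- grown & weak
    if (identical(grown, cur)) break
    cur <- grown
  }
  cur
}

#' Shape fractal dimension (edge complexity)
#'
#' Extracts a thin binary edge map from the brightness channel
#' (Sobel gradient, non-maximum suppression, hysteresis with data-driven
#' thresholds) and returns its box-counting dimension over the overall scale
#' window. Straight, sparse edges give values near 1; densely convoluted
#' edge structure pushes the value toward 2. A perfectly uniform image has
#' no edges and returns 0 with attribute `flagged = TRUE`.
#'
#' @param img A [raster_image].
#' @param window Box-size ladder; defaults to the overall window.
#' @param high_quantile,low_ratio Hysteresis threshold controls.
#' @return Dimension in `[0, 2]`; attribute `flagged` marks degenerate input.
#' @export
shape_fractal <- function(img, window = NULL,
                          high_quantile = 0.9, low_ratio = 0.5) {
  stopifnot(inherits(img, "raster_image"))
  val <- to_hsv(img)$val / 100
  edges <- edge_map(val, high_quantile, low_ratio)
  if (!any(edges)) {
    warning("uniform image: empty edge map, shape fractal undefined")
    return(structure(0, flagged = TRUE))
  }
  if (is.null(window)) window <- scale_window(dim(edges))
  structure(box_count_dimension(edges, window), flagged = FALSE)
}

#' Geometric fractal dimension of a channel field
#'
#' Binarizes the field at its median (occupied = value >= median, so the
#' occupied set holds roughly half the pixels) and returns the box-counting
#' dimension of the occupied set over the requested scale window. Reported
#' separately for small, large and overall windows in the feature vector.
#' A constant field binarizes degenerately to an all-occupied plane; it
#' returns 2 with attribute `flagged = TRUE`.
#'
#' @param field A [channel_field] or numeric matrix.
#' @param window Box sizes (see [scale_window()]).
#' @return Dimension in `[0, 2]`; attribute `flagged` marks degenerate input.
#' @export
geometric_fractal <- function(field, window = scale_window(dim(field))) {
  m <- as_field_matrix(field)
  if (max(m) == min(m)) {
    warning("constant field: degenerate median binarization")
    return(structure(2, flagged = TRUE))
  }
  occ <- m >= stats::median(m)
  structure(box_count_dimension(occ, window), flagged = FALSE)
}

## Per-cell max and min over an eps x eps spatial partition (top-left
## anchored, partial cells kept). Returns two (nI x nJ) matrices.
cell_minmax <- function(m, eps) {
  h <- nrow(m); w <- ncol(m)
  nI <- (h + eps - 1L) %/% eps
  nJ <- (w + eps - 1L) %/% eps
  padh <- nI * eps; padw <- nJ * eps
  mx <- matrix(-Inf, padh, padw); mn <- matrix(Inf, padh, padw)
  mx[1:h, 1:w] <- m; mn[1:h, 1:w] <- m
  ## fold rows: (eps, nI, padw) -> max/min over first dim via pmax/pmin loop
  dim(mx) <- c(eps, nI, padw); dim(mn) <- c(eps, nI, padw)
  rmx <- mx[1, , ]; rmn <- mn[1, , ]
  if (eps > 1) for (k in 2:eps) {
    rmx <- pmax(rmx, mx[k, , ]); rmn <- pmin(rmn, mn[k, , ])
  }
  rmx <- matrix(rmx, nI, padw); rmn <- matrix(rmn, nI, padw)
  ## fold columns
  rmx <- t(rmx); rmn <- t(rmn)
  dim(rmx) <- c(eps, nJ, nI); dim(rmn) <- c(eps, nJ, nI)
  cmx <- rmx[1, , ]; cmn <- rmn[1, , ]
  if (eps > 1) for (k in 2:eps) {
    cmx <- pmax(cmx, rmx[k, , ]); cmn <- pmin(cmn, rmn[k, , ])
  }
  list(max = t(matrix(cmx, nJ, nI)), min = t(matrix(cmn, nJ, nI)))
}

## Differential box count at one scale: height of the intensity boxes is
## eps * range / min(H, W), i.e. the unit intensity range [0, 1] is mapped
## onto the spatial grid. Per cell: ceil((max - min) / h) + 1 boxes.
dbc_count <- function(m, eps, intensity_range = 1) {
  h_box <- eps * intensity_range / min(dim(m))
  mm <- cell_minmax(m, eps)
  sum(ceiling((mm$max - mm$min) / h_box) + 1)
}

#' Statistical (differential box-counting) fractal dimension
#'
#' Treats the channel as an intensity surface over the pixel grid and
#' applies differential box counting: for box edge \eqn{\epsilon} the image
#' is partitioned into \eqn{\epsilon \times \epsilon} spatial cells, and the
#' cell's column of intensity boxes of height \eqn{h(\epsilon) =
#' \epsilon / \min(H, W)} (the unit intensity range mapped onto the spatial
#' grid) contributes \eqn{\lceil (\max - \min)/h(\epsilon) \rceil + 1}
#' occupied boxes. The dimension is the slope of \eqn{\log N} against
#' \eqn{\log(1/\epsilon)} and lies in `[2, 3]`: a flat surface gives 2,
#' rougher textures approach 3. For fractional Brownian surfaces with Hurst
#' exponent `H` the estimator recovers `D = 3 - H`.
#'
#' @param field A [channel_field] or numeric matrix in `[0, 1]`.
#' @param window Box sizes (see [scale_window()]).
#' @return Dimension, nominally in `[2, 3]`.
#' @export
statistical_fractal <- function(field, window = scale_window(dim(field))) {
  m <- as_field_matrix(field)
  if (min(dim(m)) < max(window)) stop("field smaller than largest box")
  if (min(window) < 1) stop("invalid scale window")
  N <- vapply(window, function(e) dbc_count(m, e), numeric(1))
  loglog_slope(window, N)
}

#' Box-size ladder for the 5-D colour fractal
#'
#' The joint spatial-colour box count saturates at small box sizes: once
#' there are far more 5-D boxes than pixels, every pixel occupies its own
#' box and \eqn{N(\epsilon)} stops scaling (the total box count is
#' \eqn{HW\,M^3/\epsilon^5}, so saturation sets in for
#' \eqn{\epsilon \lesssim M^{3/5}}). The colour-fractal window therefore
#' uses powers of 2 from roughly \eqn{M^{3/5}} up to `M/2`, always keeping
#' at least the top three rungs.
#'
#' @param dims `c(H, W)` or an object with dimensions.
#' @return Integer vector of box sizes.
#' @export
color_scale_window <- function(dims) {
  if (inherits(dims, "raster_image")) dims <- c(dims$height, dims$width)
  m <- min(dims)
  sizes <- 2^seq(1, floor(log2(m / 2)))
  unsat <- sizes[sizes >= m^0.6]
  if (length(unsat) < 3) unsat <- utils::tail(sizes, 3)
  if (length(unsat) < 3) stop("image too small for a colour-fractal ladder")
  unsat
}

#' Colour fractal dimension (5-D box counting)
#'
#' Box counting in the joint spatial-colour product space
#' \eqn{(x, y, R, G, B)}: at relative scale \eqn{\epsilon} the spatial axes
#' are cut into \eqn{\epsilon}-pixel boxes and each 8-bit colour axis into
#' boxes of the matched relative size \eqn{256\,\epsilon/\min(H, W)};
#' \eqn{N(\epsilon)} is the number of occupied 5-D boxes and the dimension
#' the slope of \eqn{\log N} against \eqn{\log(1/\epsilon)}. A constant
#' colour image collapses to the plane (dimension 2); abrupt, varied colour
#' transitions push the value up (theoretical ceiling 5). Green-rich natural
#' scenes, dominated by smooth colour gradients, tend to score low.
#'
#' @param img A [raster_image].
#' @param window Box sizes (see [scale_window()]).
#' @return Dimension in `[2, 5]`.
#' @export
color_fractal <- function(img, window = NULL) {
  stopifnot(inherits(img, "raster_image"))
  h <- img$height; w <- img$width
  if (is.null(window)) window <- color_scale_window(c(h, w))
  m <- min(h, w)
  row <- as.vector(row(matrix(0, h, w))) - 1L
  col <- as.vector(col(matrix(0, h, w))) - 1L
  R <- as.vector(img$pixels[, , 1]); G <- as.vector(img$pixels[, , 2])
  B <- as.vector(img$pixels[, , 3])
  N <- vapply(window, function(e) {
    cbox <- 256 * e / m                     # colour box edge, 8-bit levels
    bi <- row %/% e; bj <- col %/% e
    br <- floor(R / cbox); bg <- floor(G / cbox); bb <- floor(B / cbox)
    nbi <- (h + e - 1L) %/% e
    nbj <- (w + e - 1L) %/% e
    nc <- floor(255 / cbox) + 1
    code <- bi + nbi * (bj + nbj * (br + nc * (bg + nc * bb)))
    length(unique(code))
  }, numeric(1))
  loglog_slope(window, N)
}
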