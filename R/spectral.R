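## FFT frequencies (cycles per pixel) for an axis of length n.
fft_freq <- function(n) {
  k <- 0:(n - 1)
  ifelse(k <= n %/% 2, k, k - n) / n
}

## Radial frequency grid for an h x w spectrum.
radial_freq <- function(h, w) {
  fy <- fft_freq(h); fx <- fft_freq(w)
  sqrt(outer(fy^2, fx^2, `+`))
}

#' 1/f fluctuation index of a channel field
#'
#' Measures the balance between order and randomness in a channel via the
#' slope of its radially averaged power spectrum. The mean-removed field is
#' Fourier transformed, the power \eqn{|F|^2} averaged in log-spaced radial
#' frequency bins between the second radial bin and half the Nyquist
#' frequency (excluding DC leakage and the aliased top octave), and the
#' exponent \eqn{\beta} obtained as the least-squares slope of
#' \eqn{\log P} against \eqn{\log f}. The returned index is the
#' amplitude-spectrum exponent \eqn{\beta/2}: pink, 1/f-amplitude structure
#' scores 1; white noise scores 0; Brownian-like fields score 2. Values far
#' from 1 indicate excess randomness (below) or excess order (above).
#'
#' @param field A [channel_field] or numeric matrix, at least 32 x 32.
#' @param n_bins Number of log-spaced radial bins for spectrum averaging.
#' @return The amplitude-spectrum exponent (typically in `[0, 3]`).
#' @export
one_over_f_fluctuation <- function(field, n_bins = 24) {
  m <- as_field_matrix(field)
  if (min(dim(m)) < 32) stop("field must be at least 32 x 32")
  if (max(m) == min(m)) stop("constant field: spectrum undefined")
  P <- Mod(stats::fft(m - mean(m)))^2
  f <- radial_freq(nrow(m), ncol(m))
  fmin <- 2 / min(dim(m))       # second radial bin
  fmax <- 0.25                  # half the Nyquist frequency
  keep <- f >= fmin & f <= fmax
  edges <- exp(seq(log(fmin), log(fmax), length.out = n_bins + 1))
  bin <- cut(f[keep], edges, include.lowest = TRUE, labels = FALSE)
  pbar <- tapply(P[keep], bin, mean)
  fbar <- tapply(f[keep], bin, function(z) exp(mean(log(z))))
  ok <- is.finite(pbar) & pbar > 0
  if (sum(ok) < 3) stop("too few usable spectral bins")
  slope <- loglog_slope(1 / fbar[ok], pbar[ok])  # log P vs log f
  ## loglog_slope fits log N ~ log(1/eps); with eps = 1/f this is log P ~ log f
  -slope / 2
}
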