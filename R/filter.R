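#' Chebyshev Type I band-pass design in second-order sections
#'
#' Designs a digital Chebyshev Type I band-pass filter in zero-pole-gain
#' form (analog prototype -> low-pass-to-band-pass transform -> bilinear
#' transform) and returns it as a cascade of biquad sections. The cascade
#' form keeps the filter numerically stable for very narrow low-frequency
#' bands (e.g. 0.005-0.021 Hz at 16 Hz sampling), where the expanded
#' transfer-function polynomial is unusable in double precision.
#'
#' @param low,high Band edges in Hz.
#' @param fs Sampling rate in Hz; requires `high < fs/2`.
#' @param order Order of the analog low-pass prototype (the band-pass
#'   filter has `2*order` poles). Must be even. Default 4.
#' @param ripple Passband ripple in dB. Default 0.5.
#' @return Numeric matrix with `order` rows and columns
#'   `b0 b1 b2 a0 a1 a2` (one biquad per row, `a0 = 1`).
#' @export
cheby1_bandpass_sos <- function(low, high, fs, order = 4, ripple = 0.5) {
  if (high >= fs / 2)
    stop("band upper edge ", high, " Hz must be below the Nyquist frequency ",
         fs / 2, " Hz")
  if (low <= 0 || high <= low) stop("need 0 < low < high")
  if (order %% 2 != 0 || order < 2) stop("order must be a positive even integer")
  # analog Chebyshev-I low-pass prototype (cutoff 1 rad/s)
  eps <- sqrt(10^(ripple / 10) - 1)
  mu <- asinh(1 / eps) / order
  theta <- pi * (2 * seq_len(order) - 1) / (2 * order)
  p <- complex(real = -sinh(mu) * sin(theta),
               imaginary = cosh(mu) * cos(theta))
  gain <- Re(prod(-p)) / sqrt(1 + eps^2)  # order is even
  # prewarp edges and transform low-pass -> band-pass
  w1 <- 2 * fs * tan(pi * low / fs)
  w2 <- 2 * fs * tan(pi * high / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  ps <- p * bw / 2
  pbp <- c(ps + sqrt(ps^2 - w0^2), ps - sqrt(ps^2 - w0^2))
  gain <- gain * bw^order
  # bilinear transform; the band-pass zeros (order at s=0, order at s=Inf)
  # map to z = +1 and z = -1
  fs2 <- 2 * fs
  pz <- (fs2 + pbp) / (fs2 - pbp)
  gain <- gain * Re(prod(fs2 - rep(0 + 0i, order)) / prod(fs2 - pbp))
  # pair conjugate poles into biquads, each with zeros {+1, -1};
  # sections ordered so poles nearest the unit circle come last
  pu <- pz[Im(pz) >= 0]
  pu <- pu[order(Mod(pu))]
  sos <- matrix(0, order, 6)
  colnames(sos) <- c("b0", "b1", "b2", "a0", "a1", "a2")
  for (i in seq_len(order)) {
    b <- c(1, 0, -1)
    if (i == 1) b <- b * gain
    sos[i, ] <- c(b, 1, -2 * Re(pu[i]), Mod(pu[i])^2)
  }
  sos
}

# single forward pass of a biquad cascade, zero initial conditions;
# x is a time x series matrix, filtered column-wise (compiled loop)
sos_filter <- function(sos, x) {
  sos_filter_cpp(sos, x)
}

#' Zero-phase band-pass filtering
#'
#' Applies a Chebyshev Type I band-pass biquad cascade forward and backward
#' (zero net phase). Edge transients are suppressed by odd-symmetric
#' reflection padding of three periods of the band's low edge, capped at
#' the signal length minus one.
#'
#' @param x Numeric vector (or time x channel matrix; columns are filtered
#'   independently).
#' @param band A [band_spec()].
#' @param fs Sampling rate in Hz.
#' @param order,ripple Filter design parameters, see
#'   [cheby1_bandpass_sos()].
#' @return Filtered signal, same shape as `x`.
#' @examples
#' t <- seq(0, 2047, by = 1 / 16)
#' y <- bandpass(sin(2 * pi * 0.035 * t), band_spec("II", 0.021, 0.052), 16)
#' @export
bandpass <- function(x, band, fs, order = 4, ripple = 0.5) {
  stopifnot(inherits(band, "band_spec"))
  sos <- cheby1_bandpass_sos(band$low, band$high, fs, order, ripple)
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, ncol = 1)
  y <- bandpass_sos(x, sos, fs, band$low)
  dimnames(y) <- dimnames(x)
  if (vec) as.numeric(y) else y
}

bandpass_sos <- function(x, sos, fs, low) {
  n <- nrow(x)
  if (n <= 3 * (2 * nrow(sos) + 1))
    stop("signal too short to filter: length ", n)
  padlen <- min(n - 1, ceiling(3 * fs / low))
  # odd-symmetric reflection padding at both ends
  pre <- 2 * matrix(x[1, ], padlen, ncol(x), byrow = TRUE) -
    x[seq(padlen + 1, 2), , drop = FALSE]
  post <- 2 * matrix(x[n, ], padlen, ncol(x), byrow = TRUE) -
    x[seq(n - 1, n - padlen), , drop = FALSE]
  y <- sos_filter(sos, rbind(pre, x, post))
  y <- sos_filter(sos, y[nrow(y):1, , drop = FALSE])
  y <- y[nrow(y):1, , drop = FALSE]
  y[(padlen + 1):(padlen + n), , drop = FALSE]
}
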