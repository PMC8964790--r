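#' Entropy weights for channel fusion
#'
#' Computes the information-entropy weight of each channel within an ROI.
#' Each channel is min-max rescaled to `[0, 1]`, turned into a probability
#' distribution over time points, and scored by its normalized Shannon
#' entropy `e_j`; channels with lower entropy (higher divergence
#' `d_j = 1 - e_j`) carry more information and receive larger weights
#' `w_j = d_j / sum(d)`.
#'
#' Constant channels map to the uniform distribution (entropy 1, weight 0).
#' If every channel is constant the weights fall back to uniform.
#'
#' @param X Numeric matrix, time (N >= 2) x channels (M >= 1).
#' @return An `entropy_weights` object: list with `weights` (sums to 1)
#'   and per-channel `entropy`.
#' @examples
#' entropy_weights(cbind(a = c(0, 1, 2, 3), b = c(5, 5, 5, 5)))$weights
#' @export
entropy_weights <- function(X) {
  X <- as.matrix(X)
  N <- nrow(X)
  M <- ncol(X)
  if (N < 2) stop("entropy weights need at least 2 time points, got ", N)
  if (M < 1) stop("need at least one channel")
  if (anyNA(X)) stop("missing values in channel matrix")
  e <- numeric(M)
  for (j in seq_len(M)) {
    x <- X[, j]
    rng <- max(x) - min(x)
    if (rng == 0) {          # constant channel: uniform distribution
      e[j] <- 1
      next
    }
    z <- (x - min(x)) / rng
    p <- z / sum(z)
    p <- p[p > 0]            # 0 * log(0) := 0
    e[j] <- -sum(p * log(p)) / log(N)
  }
  d <- 1 - e
  w <- if (sum(d) == 0) rep(1 / M, M) else d / sum(d)
  names(w) <- names(e) <- colnames(X)
  structure(list(weights = w, entropy = e), class = "entropy_weights")
}

#' ROI time series for one (species, band) pair
#'
#' @param y Numeric matrix, time x ROI, columns ordered as
#'   `montage$roi_order`.
#' @param species Hemoglobin species.
#' @param band A [band_spec()].
#' @param fs Sampling rate in Hz.
#' @return A `band_roi_series` object.
#' @export
band_roi_series <- function(y, species, band, fs) {
  stopifnot(is.matrix(y), inherits(band, "band_spec"))
  structure(list(y = y, species = species, band = band, fs = fs),
            class = "band_roi_series")
}

#' @export
print.band_roi_series <- function(x, ...) {
  cat(sprintf("%s band %s ROI series: %d samples x %d ROIs @ %g Hz\n",
              x$species, x$band$name, nrow(x$y), ncol(x$y), x$fs))
  invisible(x)
}

#' Band decomposition and entropy-weighted ROI aggregation
#'
#' For each frequency band: band-pass filters every channel (zero-phase
#' Chebyshev, see [bandpass()]), then fuses each ROI's filtered channels
#' into one regional series with entropy weights computed on the filtered
#' submatrix. The fusion is a convex combination, so each ROI series lies
#' within its channels' pointwise envelope.
#'
#' @param recording A [channel_recording()].
#' @param montage A [montage()]; every referenced channel must exist in
#'   the recording.
#' @param bands List of [band_spec()]s; defaults to [default_bands()].
#' @param order,ripple Filter design parameters.
#' @return Named list of [band_roi_series()], one per band.
#' @export
roi_aggregate <- function(recording, montage = default_montage(),
                          bands = default_bands(), order = 4, ripple = 0.5) {
  stopifnot(inherits(recording, "channel_recording"),
            inherits(montage, "montage"))
  need <- montage_channels(montage)
  missing <- setdiff(need, recording$channel_ids)
  if (length(missing))
    stop("montage references channel(s) absent from recording: ",
         paste(missing, collapse = ", "))
  col_of <- match(need, recording$channel_ids)
  names(col_of) <- need
  out <- list()
  for (b in bands) {
    filt <- bandpass(recording$samples, b, recording$fs, order, ripple)
    y <- matrix(0, nrow(filt), length(montage$roi_order),
                dimnames = list(NULL, montage$roi_order))
    for (roi in montage$roi_order) {
      cols <- col_of[as.character(montage$roi_channels[[roi]])]
      sub <- filt[, cols, drop = FALSE]
      w <- entropy_weights(sub)$weights
      y[, roi] <- as.numeric(sub %*% w)
    }
    out[[b$name]] <- band_roi_series(y, recording$species, b, recording$fs)
  }
  out
}
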