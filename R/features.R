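#' Fifteen time-domain features of a signal
#'
#' The standard condition-monitoring feature set used for each ROI series:
#' mean; population standard deviation; coefficient of variation; energy;
#' range; skewness and excess kurtosis (biased Fisher forms); peak
#' (max absolute value); Hjorth mobility; Shannon entropy (nats) of the
#' 64-bin amplitude histogram; root mean square; kurtosis factor
#' (`mean(x^4)/RMS^4`); waveform factor (`RMS/mean|x|`); pulse factor
#' (`peak/mean|x|`); margin factor (`peak/mean(sqrt|x|)^2`).
#' Ratios that are undefined for a constant signal are returned as 0.
#'
#' @param x Numeric vector, length >= 4.
#' @param entropy_bins Histogram bin count for the entropy feature.
#' @return Named numeric vector of length 15.
#' @examples
#' time_domain_features(sin(2 * pi * 1 * seq(0, 99.9375, by = 1 / 16)))
#' @export
time_domain_features <- function(x, entropy_bins = 64) {
  if (length(x) < 4) stop("need at least 4 samples, got ", length(x))
  n <- length(x)
  mu <- mean(x)
  v <- mean((x - mu)^2)          # population variance
  sdev <- sqrt(v)
  absx <- abs(x)
  peak <- max(absx)
  rms <- sqrt(mean(x^2))
  rng <- max(x) - min(x)
  cv <- if (sdev == 0) 0 else sdev / (abs(mu) + 1e-12)
  skew <- if (sdev == 0) 0 else e1071::skewness(x, type = 1)
  kurt <- if (sdev == 0) 0 else e1071::kurtosis(x, type = 1)
  mob <- if (v == 0) 0 else {
    dx <- diff(x)
    sqrt(mean((dx - mean(dx))^2) / v)
  }
  ent <- if (rng == 0) 0 else {
    counts <- tabulate(pmin(floor((x - min(x)) / rng * entropy_bins) + 1,
                            entropy_bins), entropy_bins)
    p <- counts[counts > 0] / n
    -sum(p * log(p))
  }
  mabs <- mean(absx)
  msqrt <- mean(sqrt(absx))
  c(mean = mu,
    sd = sdev,
    cv = cv,
    energy = sum(x^2),
    range = rng,
    skewness = skew,
    kurtosis = kurt,
    peak = peak,
    mobility = mob,
    entropy = ent,
    rms = rms,
    kurtosis_factor = if (rms == 0) 0 else mean(x^4) / rms^4,
    waveform_factor = if (mabs == 0) 0 else rms / mabs,
    pulse_factor = if (mabs == 0) 0 else peak / mabs,
    margin_factor = if (msqrt == 0) 0 else peak / msqrt^2)
}

td_feature_names <- function() {
  c("mean", "sd", "cv", "energy", "range", "skewness", "kurtosis", "peak",
    "mobility", "entropy", "rms", "kurtosis_factor", "waveform_factor",
    "pulse_factor", "margin_factor")
}

#' Canonical names of the 2,250-feature vector
#'
#' Fixed ordering: 28 signed correlations per (species, band); then
#' characteristic path length `L` and clustering coefficient `C` per
#' (species, band); then 15 time-domain features per (species, band, ROI).
#' Names follow `species|band|kind|detail`.
#'
#' @param rois ROI ordering; defaults to the default montage's.
#' @return Character vector of length 2,250.
#' @export
feature_names <- function(rois = default_montage()$roi_order) {
  species <- hb_species()
  bands <- names(default_bands())
  pairs <- utils::combn(rois, 2)
  pair_names <- paste(pairs[1, ], pairs[2, ], sep = "~")
  fc <- as.vector(vapply(species, function(sp)
    vapply(bands, function(b) paste(sp, b, "fc", pair_names, sep = "|"),
           character(28)), matrix("", 28, 5)))
  net <- as.vector(vapply(species, function(sp)
    vapply(bands, function(b) paste(sp, b, "net", c("L", "C"), sep = "|"),
           character(2)), matrix("", 2, 5)))
  td <- as.vector(vapply(species, function(sp)
    vapply(bands, function(b)
      as.vector(vapply(rois, function(r)
        paste(sp, b, "td", r, td_feature_names(), sep = "|"),
        character(15))), character(120)), matrix("", 120, 5)))
  c(fc, net, td)
}

#' Assemble the per-session feature vector
#'
#' Concatenates, for every (species, band) pair: the 28 signed Pearson
#' correlations between ROIs, the weighted network's characteristic path
#' length and clustering coefficient, and the 15 time-domain features of
#' each of the 8 ROI series — 420 + 30 + 1,800 = 2,250 features.
#'
#' @param artifacts Nested list `artifacts[[species]][[band]]`, each
#'   element a list with `network` (a `connectivity_network`), `metrics`
#'   (with `L` and `C`) and `series` (a `band_roi_series`).
#' @return Named numeric vector of length 2,250, ordered as
#'   [feature_names()].
#' @export
assemble_features <- function(artifacts) {
  species <- hb_species()
  bands <- names(default_bands())
  for (sp in species) for (b in bands)
    if (is.null(artifacts[[sp]][[b]]))
      stop("missing artifacts for species ", sp, ", band ", b)
  pair_idx <- t(utils::combn(8, 2))   # same enumeration as feature_names()
  fc <- unlist(lapply(species, function(sp) lapply(bands, function(b) {
    r <- artifacts[[sp]][[b]]$network$r
    r[pair_idx]
  })))
  net <- unlist(lapply(species, function(sp) lapply(bands, function(b) {
    m <- artifacts[[sp]][[b]]$metrics
    c(m$L, m$C)
  })))
  td <- unlist(lapply(species, function(sp) lapply(bands, function(b) {
    y <- artifacts[[sp]][[b]]$series$y
    as.vector(apply(y, 2, time_domain_features))
  })))
  out <- c(fc, net, td)
  names(out) <- feature_names()
  out
}

#' Run preprocessing and networks for one session and assemble features
#'
#' Convenience wrapper: for every hemoglobin species and band, runs
#' [roi_aggregate()], [fc_matrix()] and the weighted `C`/`L` metrics, then
#' [assemble_features()].
#'
#' @param session A [participant_session()] with all three recordings.
#' @param montage A [montage()].
#' @param bands Band list.
#' @return Named numeric feature vector of length 2,250.
#' @export
session_features <- function(session, montage = default_montage(),
                             bands = default_bands()) {
  artifacts <- session_artifacts(session, montage, bands)
  assemble_features(artifacts)
}

#' @rdname session_features
#' @export
session_artifacts <- function(session, montage = default_montage(),
                              bands = default_bands()) {
  artifacts <- list()
  for (sp in hb_species()) {
    rec <- session$recordings[[sp]]
    if (is.null(rec)) stop("session ", session$participant_id,
                           " lacks a ", sp, " recording")
    series <- roi_aggregate(rec, montage, bands)
    artifacts[[sp]] <- lapply(series, function(s) {
      net <- fc_matrix(s)
      list(series = s, network = net,
           metrics = list(C = clustering_coefficient(net$w),
                          L = as.numeric(characteristic_path_length(net$w))))
    })
  }
  artifacts
}

#' Feature table for a whole study
#'
#' @param sessions List of [participant_session()]s.
#' @param montage,bands Passed to [session_features()].
#' @return Data frame: metadata columns (`participant_id`, `task`,
#'   `session`, `level`) followed by the 2,250 feature columns.
#' @export
study_features <- function(sessions, montage = default_montage(),
                           bands = default_bands()) {
  rows <- lapply(sessions, function(s) {
    fv <- session_features(s, montage, bands)
    meta <- data.frame(participant_id = s$participant_id, task = s$task,
                       session = s$session,
                       level = if (is.null(s$fatigue_level)) NA
                               else s$fatigue_level)
    cbind(meta, as.data.frame(as.list(fv), check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
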