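#' MFI-20 session score
#'
#' Arithmetic mean of the 20 item scores (items oriented so higher means
#' more fatigued), on the 1-5 scale.
#'
#' @param items Integer vector of exactly 20 values in 1..5.
#' @return Scalar mean item score.
#' @export
mfi_score <- function(items) {
  if (length(items) != 20) stop("MFI-20 has exactly 20 items, got ",
                                length(items))
  if (any(items < 1 | items > 5)) stop("MFI items must lie in 1..5")
  mean(items)
}

#' n-back behavioural score
#'
#' Mean reaction time of correct trials divided by the fraction of correct
#' trials; higher means worse performance.
#'
#' @param nback Data frame with columns `rt` (> 0) and `correct`.
#' @return Scalar behaviour score.
#' @export
behavior_score <- function(nback) {
  stopifnot(is.data.frame(nback), all(c("rt", "correct") %in% names(nback)))
  if (nrow(nback) < 1) stop("need at least one n-back trial")
  correct <- as.logical(nback$correct)
  acc <- mean(correct)
  if (acc == 0) stop("no correct n-back trials: behaviour score undefined")
  mean(nback$rt[correct]) / acc
}

#' Non-fatigue / fatigue split by 1-D k-means
#'
#' Clusters the MFI scores into two groups (k-means, k = 2, best of 20
#' restarts by within-cluster sum of squares) and returns the minimum
#' score of the higher-mean cluster, so that scores strictly below the
#' threshold are non-fatigue.
#'
#' @param scores Numeric MFI session scores; needs >= 4 values with >= 2
#'   distinct.
#' @param seed Integer seed for the restarts.
#' @return Scalar threshold.
#' @examples
#' kmeans_split(c(1.5, 1.6, 1.7, 3.5, 3.6, 3.7))  # 3.5
#' @export
kmeans_split <- function(scores, seed = 1) {
  if (length(scores) < 4) stop("need at least 4 scores")
  if (length(unique(scores)) < 2) stop("scores are all identical")
  km <- with_seed(seed, stats::kmeans(scores, centers = 2, nstart = 20))
  upper <- which.max(km$centers)
  min(scores[km$cluster == upper])
}

#' Moderate / severe threshold scan
#'
#' Scans candidate MFI thresholds over `[lo, hi]` in steps of `step`:
#' each candidate `t` splits the fatigue-class sessions into moderate
#' (`mfi < t`) and severe (`mfi >= t`); candidates leaving either group
#' smaller than `min_group` are skipped; the statistic is the strength of
#' the Welch test between the two groups' behaviour scores, scored as
#' `-log10(p)` so that the degrees of freedom discount unstable extreme
#' splits (a raw |t| criterion spikes at near-edge splits, where a handful
#' of sessions can have arbitrarily small variance). All thresholds between
#' two adjacent observed scores induce the same partition, so the maximizing
#' candidates form a plateau; the plateau midpoint is returned (the left
#' end would bias the threshold low by the width of the inter-score gap).
#' Ties between distinct plateaus go to the lowest. The full scan trace is
#' attached.
#'
#' @param mfi,behavior Aligned numeric vectors for fatigue-class sessions
#'   (`mfi >= lo`).
#' @param lo,hi,step Scan grid. Defaults 2.57, 5.00, 0.01.
#' @param min_group Minimum group size. Default 3.
#' @return Scalar threshold with attribute `trace`: data frame
#'   `(threshold, statistic, n_moderate, n_severe)`.
#' @export
severe_threshold_scan <- function(mfi, behavior, lo = 2.57, hi = 5.00,
                                  step = 0.01, min_group = 3) {
  stopifnot(length(mfi) == length(behavior))
  grid <- seq(lo, hi, by = step)
  trace <- data.frame(threshold = grid, statistic = NA_real_,
                      n_moderate = 0L, n_severe = 0L)
  for (i in seq_along(grid)) {
    sev <- mfi >= grid[i]
    trace$n_moderate[i] <- sum(!sev)
    trace$n_severe[i] <- sum(sev)
    if (sum(sev) < min_group || sum(!sev) < min_group) next
    trace$statistic[i] <- tryCatch(
      -log10(stats::t.test(behavior[sev], behavior[!sev])$p.value),
      error = function(e) NA_real_)  # e.g. both groups essentially constant
  }
  if (all(is.na(trace$statistic)))
    stop("no threshold yields two groups of size >= ", min_group)
  smax <- max(trace$statistic, na.rm = TRUE)
  at_max <- !is.na(trace$statistic) & trace$statistic >= smax - 1e-12
  first <- which.max(at_max)           # lowest maximizing plateau
  run_end <- first
  while (run_end < length(grid) && at_max[run_end + 1]) run_end <- run_end + 1
  best <- grid[round((first + run_end) / 2)]
  structure(best, trace = trace)
}

#' Label a study's sessions with fatigue levels
#'
#' Computes MFI and behaviour scores per session, finds the non-fatigue
#' threshold with [kmeans_split()], the severe threshold with
#' [severe_threshold_scan()], and assigns `L1` (below the non-fatigue
#' threshold), `L3` (at or above the severe threshold) or `L2` in between.
#'
#' @param sessions List of [participant_session()]s.
#' @param seed Seed for the k-means restarts.
#' @param lo,hi,step,min_group Scan parameters, see
#'   [severe_threshold_scan()]. `lo` defaults to the k-means threshold;
#'   `min_group` defaults to 10 percent of the fatigue-class sessions (at
#'   least 3), which keeps borderline sessions straddling the k-means
#'   threshold from anchoring a degenerate near-edge split.
#' @return A `fatigue_labeling` object: data frame `scores` (per session),
#'   thresholds, and the scan trace.
#' @export
label_fatigue <- function(sessions, seed = 1, lo = NULL, hi = 5.00,
                          step = 0.01, min_group = NULL) {
  scores <- data.frame(
    participant_id = vapply(sessions, `[[`, "", "participant_id"),
    task = vapply(sessions, `[[`, "", "task"),
    session = vapply(sessions, `[[`, "", "session"),
    mfi = vapply(sessions, function(s) mfi_score(s$mfi_items), 0),
    behavior = vapply(sessions, function(s) behavior_score(s$nback), 0),
    true_level = vapply(sessions, function(s)
      if (is.null(s$fatigue_level)) NA_character_ else s$fatigue_level, "")
  )
  thr_nf <- kmeans_split(scores$mfi, seed)
  if (is.null(lo)) lo <- thr_nf
  fat <- scores$mfi >= thr_nf
  if (is.null(min_group)) min_group <- max(3, ceiling(0.1 * sum(fat)))
  thr_sev <- severe_threshold_scan(scores$mfi[fat], scores$behavior[fat],
                                   lo = lo, hi = hi, step = step,
                                   min_group = min_group)
  scores$level <- ifelse(scores$mfi < thr_nf, "L1",
                         ifelse(scores$mfi >= as.numeric(thr_sev),
                                "L3", "L2"))
  structure(list(scores = scores,
                 threshold_nonfatigue = thr_nf,
                 threshold_severe = as.numeric(thr_sev),
                 trace = attr(thr_sev, "trace")),
            class = "fatigue_labeling")
}

#' @export
print.fatigue_labeling <- function(x, ...) {
  cat(sprintf("fatigue labelling: thresholds %.3f (fatigue) / %.3f (severe)\n",
              x$threshold_nonfatigue, x$threshold_severe))
  print(table(x$scores$level))
  invisible(x)
}
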