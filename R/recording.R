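#' Multichannel hemoglobin recording
#'
#' Container for one session's raw time series of a single hemoglobin
#' species: a numeric time x channel matrix sampled at `fs` Hz with
#' 1-based channel ids as column labels.
#'
#' @param samples Numeric matrix, time x channel, no missing values.
#' @param fs Sampling rate in Hz, > 0.
#' @param species One of `"HbO"`, `"HbR"`, `"HbT"`.
#' @param channel_ids Integer channel labels; defaults to column names or
#'   `1:ncol(samples)`. Columns are reordered so ids ascend.
#' @return A `channel_recording` object.
#' @export
channel_recording <- function(samples, fs, species,
                              channel_ids = NULL) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) stop("samples must be numeric")
  if (anyNA(samples)) {
    bad <- which(is.na(samples), arr.ind = TRUE)[1, ]
    stop("missing value in samples at row ", bad[1], ", column ", bad[2])
  }
  if (nrow(samples) < 2) stop("recording needs at least 2 time points")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("fs must be a positive number, got ", fs)
  species <- match.arg(species, hb_species())
  if (is.null(channel_ids)) {
    cn <- colnames(samples)
    channel_ids <- if (!is.null(cn)) as.integer(cn) else seq_len(ncol(samples))
  }
  channel_ids <- as.integer(channel_ids)
  if (length(channel_ids) != ncol(samples) || anyNA(channel_ids))
    stop("channel_ids must label every column")
  ord <- order(channel_ids)
  samples <- samples[, ord, drop = FALSE]
  channel_ids <- channel_ids[ord]
  colnames(samples) <- channel_ids
  structure(list(samples = samples, fs = fs, species = species,
                 channel_ids = channel_ids),
            class = "channel_recording")
}

#' @export
print.channel_recording <- function(x, ...) {
  cat(sprintf("%s recording: %d samples x %d channels @ %g Hz (%.1f s)\n",
              x$species, nrow(x$samples), length(x$channel_ids), x$fs,
              nrow(x$samples) / x$fs))
  invisible(x)
}

#' Read a recording from CSV + JSON sidecar
#'
#' The signal file is a delimited numeric matrix whose one-line header
#' holds the channel ids; the metadata file is JSON with at least
#' `fs` and `species`.
#'
#' @param signal_path CSV of the time x channel matrix.
#' @param meta_path JSON sidecar with `fs`, `species` (and optionally
#'   `participant_id`, `task`, `session`).
#' @param montage Optional `montage`; if given, the channel set must cover
#'   it exactly.
#' @return A `channel_recording`; sidecar fields are attached as the
#'   `"meta"` attribute.
#' @export
read_recording <- function(signal_path, meta_path, montage = NULL) {
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$fs) || !is.numeric(meta$fs) || meta$fs <= 0)
    stop("metadata ", meta_path, ": fs must be a positive number")
  if (is.null(meta$species)) stop("metadata ", meta_path, ": species missing")
  raw <- utils::read.csv(signal_path, check.names = FALSE)
  for (j in seq_along(raw)) {
    if (!is.numeric(raw[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(raw[[j]]))))[1]
      stop("non-numeric cell in ", signal_path, " at row ", bad,
           ", column ", names(raw)[j])
    }
  }
  rec <- channel_recording(as.matrix(raw), fs = meta$fs, species = meta$species,
                           channel_ids = as.integer(names(raw)))
  if (!is.null(montage)) {
    need <- montage_channels(montage)
    missing <- setdiff(need, rec$channel_ids)
    if (length(missing))
      stop("recording ", signal_path, " is missing montage channel(s): ",
           paste(missing, collapse = ", "))
  }
  attr(rec, "meta") <- meta
  rec
}

#' Write a recording as CSV + JSON sidecar
#'
#' Values are written with 12 significant digits, which round-trips the
#' matrix exactly through [read_recording()] at double precision for
#' signals in the generator's amplitude range.
#'
#' @param rec A `channel_recording`.
#' @param signal_path,meta_path Output paths.
#' @param meta Extra metadata fields to merge into the sidecar.
#' @return `signal_path`, invisibly.
#' @export
write_recording <- function(rec, signal_path, meta_path, meta = list()) {
  df <- as.data.frame(signif(rec$samples, 12))
  names(df) <- rec$channel_ids
  utils::write.csv(df, signal_path, row.names = FALSE, quote = FALSE)
  side <- utils::modifyList(list(fs = rec$fs, species = rec$species), meta)
  jsonlite::write_json(side, meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(signal_path)
}

#' One participant-session with signals, questionnaire and behaviour
#'
#' @param participant_id Character id.
#' @param task One of `"PVT"`, `"cognitive"`, `"driving"`.
#' @param session One of `"morning"`, `"afternoon"`, `"evening"`.
#' @param recordings Named list of `channel_recording`s, one per species.
#' @param mfi_items Integer vector of the 20 MFI-20 item scores (1..5,
#'   oriented so that higher means more fatigued).
#' @param nback Data frame with columns `rt` (reaction time, s, > 0) and
#'   `correct` (logical or 0/1).
#' @param fatigue_level Optional `"L1"`, `"L2"` or `"L3"` ground truth /
#'   assigned label.
#' @return A `participant_session` object.
#' @export
participant_session <- function(participant_id, task, session, recordings,
                                mfi_items, nback, fatigue_level = NULL) {
  task <- match.arg(task, c("PVT", "cognitive", "driving"))
  session <- match.arg(session, c("morning", "afternoon", "evening"))
  mfi_items <- as.integer(mfi_items)
  if (length(mfi_items) != 20)
    stop("mfi_items must have exactly 20 entries, got ", length(mfi_items))
  if (any(mfi_items < 1 | mfi_items > 5))
    stop("MFI items must be integers in 1..5")
  stopifnot(is.data.frame(nback), all(c("rt", "correct") %in% names(nback)))
  if (any(nback$rt <= 0)) stop("n-back reaction times must be > 0")
  nback$correct <- as.logical(nback$correct)
  if (!is.null(fatigue_level))
    fatigue_level <- match.arg(fatigue_level, c("L1", "L2", "L3"))
  if (length(recordings) &&
      !all(vapply(recordings, inherits, TRUE, "channel_recording")))
    stop("recordings must be channel_recording objects")
  structure(list(participant_id = participant_id, task = task,
                 session = session, recordings = recordings,
                 mfi_items = mfi_items, nback = nback,
                 fatigue_level = fatigue_level),
            class = "participant_session")
}

#' @export
print.participant_session <- function(x, ...) {
  cat(sprintf("session %s / %s / %s: %d recording(s), MFI mean %.2f, %d n-back trials%s\n",
              x$participant_id, x$task, x$session, length(x$recordings),
              mean(x$mfi_items), nrow(x$nback),
              if (is.null(x$fatigue_level)) "" else paste0(", level ", x$fatigue_level)))
  invisible(x)
}

#' Write / read a study's MFI-20 and n-back tables
#'
#' Tabular interchange formats: the MFI table has one row per session with
#' columns `participant_id, task, session, level, item_01..item_20`; the
#' n-back table one row per trial with columns
#' `participant_id, task, session, rt, correct`.
#'
#' @param sessions List of `participant_session`s.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_mfi_table <- function(sessions, path) {
  rows <- lapply(sessions, function(s) {
    items <- as.list(s$mfi_items)
    names(items) <- sprintf("item_%02d", 1:20)
    c(list(participant_id = s$participant_id, task = s$task,
           session = s$session,
           level = if (is.null(s$fatigue_level)) NA else s$fatigue_level),
      items)
  })
  utils::write.csv(do.call(rbind, lapply(rows, as.data.frame)), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mfi_table
#' @export
write_nback_table <- function(sessions, path) {
  rows <- lapply(sessions, function(s) {
    data.frame(participant_id = s$participant_id, task = s$task,
               session = s$session, rt = s$nback$rt,
               correct = as.integer(s$nback$correct))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mfi_table
#' @export
read_mfi_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("participant_id", "task", "session", sprintf("item_%02d", 1:20))
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("MFI table missing column(s): ",
                            paste(missing, collapse = ", "))
  df
}

#' @rdname write_mfi_table
#' @export
read_nback_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("participant_id", "task", "session", "rt", "correct")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("n-back table missing column(s): ",
                            paste(missing, collapse = ", "))
  df
}
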