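#' Channel-to-ROI montage
#'
#' A montage maps measurement channels to named cortical regions of
#' interest (ROIs) and records each ROI's hemisphere. The default montage
#' covers the prefrontal cortex (PFC), frontal eye fields (FEF),
#' supplementary motor area (SMA) and premotor cortex (PMC) with 24
#' channels in 8 ROIs.
#'
#' @param roi_channels Named list: ROI name -> integer vector of channel ids.
#' @param hemisphere Named character vector: ROI name -> one of
#'   `"left"`, `"right"`, `"medial"`.
#' @param roi_order Character vector fixing the ROI ordering used in all
#'   downstream matrices; defaults to `names(roi_channels)`.
#' @return A `montage` object.
#' @seealso [default_montage()]
#' @export
montage <- function(roi_channels, hemisphere, roi_order = names(roi_channels)) {
  stopifnot(is.list(roi_channels), length(roi_channels) >= 1)
  if (!setequal(names(roi_channels), roi_order) ||
      length(roi_order) != length(roi_channels))
    stop("roi_order must be a permutation of names(roi_channels)")
  chans <- unlist(roi_channels, use.names = FALSE)
  if (anyDuplicated(chans))
    stop("ROI channel lists must be disjoint; duplicated channel(s): ",
         paste(unique(chans[duplicated(chans)]), collapse = ", "))
  if (!all(names(roi_channels) %in% names(hemisphere)))
    stop("hemisphere map missing ROI(s): ",
         paste(setdiff(names(roi_channels), names(hemisphere)), collapse = ", "))
  if (!all(hemisphere %in% c("left", "right", "medial")))
    stop("hemisphere values must be left/right/medial")
  roi_channels <- lapply(roi_channels[roi_order], function(v) sort(as.integer(v)))
  structure(list(
    roi_channels = roi_channels,
    roi_order = roi_order,
    hemisphere = hemisphere[roi_order]
  ), class = "montage")
}

#' Default 24-channel, 8-ROI montage
#'
#' The standard montage of the pipeline: left/medial/right prefrontal
#' cortex, left/right frontal eye field, supplementary motor area and
#' left/right premotor cortex, with channels 1..24 assigned as in the
#' 4x4 optode layout.
#'
#' @return A `montage` object with 8 ROIs covering channels 1..24.
#' @examples
#' m <- default_montage()
#' m$roi_channels[["R-FEF"]]  # 13, 14
#' @export
default_montage <- function() {
  montage(
    roi_channels = list(
      "L-PFC" = c(1, 4, 8),
      "M-PFC" = c(2, 5, 6, 9),
      "R-PFC" = c(3, 7, 10),
      "L-FEF" = c(11, 12),
      "R-FEF" = c(13, 14),
      "SMA"   = c(15, 18, 22),
      "L-PMC" = c(16, 19, 20, 23),
      "R-PMC" = c(17, 21, 24)
    ),
    hemisphere = c(
      "L-PFC" = "left", "M-PFC" = "medial", "R-PFC" = "right",
      "L-FEF" = "left", "R-FEF" = "right", "SMA" = "medial",
      "L-PMC" = "left", "R-PMC" = "right"
    )
  )
}

#' @export
print.montage <- function(x, ...) {
  cat("montage:", length(x$roi_order), "ROIs,",
      length(montage_channels(x)), "channels\n")
  for (r in x$roi_order)
    cat(sprintf("  %-6s [%6s] %s\n", r, x$hemisphere[[r]],
                paste(x$roi_channels[[r]], collapse = ", ")))
  invisible(x)
}

#' All channel ids referenced by a montage, sorted
#' @param m A `montage`.
#' @return Sorted integer vector of channel ids.
#' @export
montage_channels <- function(m) {
  sort(unlist(m$roi_channels, use.names = FALSE))
}

#' Read / write a montage as JSON
#'
#' @param path File path.
#' @param m A `montage`.
#' @return `read_montage` returns a `montage`; `write_montage` returns
#'   `path` invisibly.
#' @export
read_montage <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$roi_channels) || is.null(obj$hemisphere))
    stop("montage JSON must contain roi_channels and hemisphere")
  hemi <- unlist(obj$hemisphere)
  ord <- if (!is.null(obj$roi_order)) unlist(obj$roi_order) else names(obj$roi_channels)
  montage(lapply(obj$roi_channels, as.integer), hemi, ord)
}

#' @rdname read_montage
#' @export
write_montage <- function(m, path) {
  jsonlite::write_json(
    list(roi_channels = m$roi_channels,
         roi_order = m$roi_order,
         hemisphere = as.list(m$hemisphere)),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
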