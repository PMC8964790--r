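#' Physiological frequency bands
#'
#' The five canonical hemodynamic-oscillation bands used throughout the
#' pipeline. From slow to fast they reflect endogenic (I), neurogenic (II),
#' myogenic (III), respiratory (IV) and cardiac (V) activity.
#'
#' @param name Band name, one of `"I"`..`"V"`.
#' @param low,high Band edges in Hz; `0 < low < high`.
#' @return A `band_spec` object: list with `name`, `low`, `high`.
#' @examples
#' band_spec("II", 0.021, 0.052)
#' default_bands()
#' @export
band_spec <- function(name, low, high) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.numeric(low) || !is.numeric(high) || low <= 0 || high <= low)
    stop("band edges must satisfy 0 < low < high, got [", low, ", ", high, "]")
  structure(list(name = name, low = low, high = high), class = "band_spec")
}

#' @rdname band_spec
#' @export
default_bands <- function() {
  list(
    I   = band_spec("I",   0.005, 0.021),
    II  = band_spec("II",  0.021, 0.052),
    III = band_spec("III", 0.052, 0.145),
    IV  = band_spec("IV",  0.145, 0.600),
    V   = band_spec("V",   0.600, 2.000)
  )
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("band %s: %.3f-%.3f Hz\n", x$name, x$low, x$high))
  invisible(x)
}

#' Names of the three hemoglobin species
#' @return Character vector `c("HbO", "HbR", "HbT")`.
#' @export
hb_species <- function() c("HbO", "HbR", "HbT")
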