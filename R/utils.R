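#' Derive a reproducible sub-seed
#'
#' Deterministically maps a master seed plus any number of string/numeric
#' tags to a 31-bit integer seed via a polynomial rolling hash. Used so
#' that every cell of a simulated study (and every pipeline stage) gets
#' its own stable seed: changing the study composition never reshuffles
#' the seeds of existing cells.
#'
#' @param master Integer master seed.
#' @param ... Tags (coerced to character) identifying the consumer.
#' @return Integer in `[1, 2^31 - 2]`.
#' @examples
#' derive_seed(1, "PVT", "L1", 3)
#' @export
derive_seed <- function(master, ...) {
  tags <- paste(vapply(list(...), as.character, ""), collapse = "")
  h <- as.double(master) %% 2147483647
  for (code in utf8ToInt(tags)) h <- (h * 31 + code) %% 2147483647
  as.integer(h + 1)
}

# evaluate expr under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# symmetric positive-semidefinite matrix square root
sqrtm_psd <- function(R, tol = -1e-10) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < tol * max(abs(e$values), 1))
    stop("matrix is not positive semidefinite (min eigenvalue ",
         signif(min(e$values), 3), ")")
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

# nearest correlation-like PSD repair: clip eigenvalues, rescale diagonal
psd_repair <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= 0) return(R)
  R2 <- e$vectors %*% (pmax(e$values, 1e-8) * t(e$vectors))
  d <- sqrt(diag(R2))
  R2 <- R2 / tcrossprod(d)
  diag(R2) <- 1
  (R2 + t(R2)) / 2
}
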