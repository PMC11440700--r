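#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor median rnorm rpois runif setNames
#' @importFrom utils read.delim write.table head tail
NULL

# Deterministic 31-bit hash of a character key (Horner scheme, prime modulus).
# Used to derive per-locus / per-stage RNG seeds from a single master seed so
# that adding loci or stages never perturbs draws made for earlier ones.
key_hash <- function(key) {
  m <- 2147483647
  h <- 0
  for (x in utf8ToInt(key)) h <- (h * 31 + x) %% m
  as.integer(h)
}

derive_seed <- function(seed, ...) {
  key <- paste(c(format(seed), as.character(list(...))), collapse = "/")
  key_hash(key)
}

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Format a percentage for display tables
#'
#' Renders `100 * count / total` with two decimals, matching the bracketed
#' percentage style used in the package's summary tables. A zero count prints
#' as `0%` and a zero total as an empty string.
#'
#' @param count numerator count.
#' @param total denominator count.
#' @return character scalar, e.g. `"9.33%"`.
#' @export
format_percent <- function(count, total) {
  if (length(count) > 1L || length(total) > 1L) {
    return(mapply(format_percent, count, total, USE.NAMES = FALSE))
  }
  if (is.na(total) || total == 0) return("")
  if (count == 0) return("0%")
  sprintf("%.2f%%", 100 * count / total)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
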