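#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used at all reporting boundaries in the
#' body-size chain. Base [round()] rounds half to even, which would print the
#' midpoint of a 4.0--6.3 m range as 5.1 m instead of the conventional 5.2 m.
#'
#' @param x numeric vector.
#' @param digits integer; decimal places to keep.
#' @return `x` rounded half away from zero to `digits` decimals.
#' @examples
#' round_half_up(5.15, 1) # 5.2
#' round_half_up(2.5, 0)  # 3
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # tiny guard against binary representations sitting just under .5
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Derive a reproducible substream seed
#'
#' Each stochastic routine draws its seed from a master seed plus a fixed
#' per-routine offset, so adding a new generator never perturbs the stream of
#' an existing one. Kept below 2^31 - 1 to stay a valid R integer.
#'
#' @param seed master integer seed.
#' @param stream character; name of the consuming routine.
#' @return an integer seed.
#' @keywords internal
substream_seed <- function(seed, stream) {
  offsets <- c(
    clasts = 101L, orientations = 211L, matrix = 307L, skeleton = 401L,
    search = 503L, bootstrap = 601L, montecarlo = 701L, pipeline = 811L
  )
  off <- offsets[[stream]]
  if (is.null(off)) stop("unknown substream: ", stream)
  as.integer((as.double(seed) * 977L + off) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
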