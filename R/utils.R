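# Internal helpers shared across modules.

#' Derive a reproducible substream seed
#'
#' Maps a master seed plus a character tag to a deterministic integer seed,
#' so that independent stages (or independent panel evaluations) draw from
#' independent, order-insensitive random substreams.
#'
#' @param seed Master integer seed.
#' @param tag Character scalar identifying the substream.
#' @return A single integer below 2^31.
#' @keywords internal
substreamSeed <- function(seed, tag) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(tag) == 1L)
  m <- 2147483563
  h <- 0
  for (code in utf8ToInt(as.character(tag))) {
    h <- (h * 31 + code) %% m
  }
  as.integer((abs(as.numeric(seed)) * 69069 + h) %% m) + 1L
}

#' @keywords internal
assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("'%s' must be a single finite number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}
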