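#' Derive a stage-specific seed from a run seed
#'
#' One global seed fans out to per-stage seeds through a small multiplicative
#' hash so that individual pipeline stages can be re-run reproducibly on their
#' own. Results stay below 2^31.
#'
#' @param seed integer run seed.
#' @param stage character stage tag (e.g. "simulate", "split").
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (ch in utf8ToInt(as.character(stage))) h <- (h * 131 + ch) %% 1000003
  as.integer((abs(seed) * 7919 + h * 104729 + 17) %% 2147483647)
}

# trapezoidal integral of y over x
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# population moments used by the time-domain block
pop_var <- function(x) mean((x - mean(x))^2)

`%||%` <- function(a, b) if (is.null(a)) b else a
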