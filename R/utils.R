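# Internal helpers shared across modules.

#' Derive a reproducible child seed from a master seed
#'
#' All stochastic components (simulator, ELM weights, forests, fold shuffles)
#' draw their seeds from one master seed through this map, so that a single
#' integer reproduces an entire run while components stay independently
#' re-runnable.
#'
#' @param master integer master seed.
#' @param stream character label of the consumer (e.g. "sim", "elm", "rf").
#' @param index optional integer sub-index (e.g. subject or fold number).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(master, stream, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  val <- (as.double(master) * 48271 + h * 7919 + as.double(index) * 104729)
  as.integer(val %% 2147483647)
}

# stop() with a consistent prefix
abort <- function(...) stop(sprintf(...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# population standard deviation (divisor n)
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}
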