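#' Round half-up to a fixed number of decimals
#'
#' Display rounding used throughout reports: exact halves round away from
#' zero (0.155 -> 0.16), unlike [base::round()]'s round-half-even rule.
#' Full precision is always kept internally; this is display-only.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-12) / scale
}

#' Derive a stage-specific random seed from a global seed
#'
#' Stable string hash of the stage name folded into the global seed so that
#' adding pipeline stages never shifts the random streams of existing ones.
#' Result is kept inside the 32-bit integer range R requires of a seed.
#'
#' @param global_seed integer global seed.
#' @param stage character stage name.
#' @return integer seed.
#' @export
derive_seed <- function(global_seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- 0
  for (b in utf8ToInt(stage)) h <- (h * 31 + b) %% 2147480009
  as.integer((as.numeric(global_seed) %% 2147480009 + h) %% 2147480009)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_hb <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "hybridband_error")))
}
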