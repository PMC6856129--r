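#' @useDynLib kinstr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rgamma rnorm runif sd setNames rbeta rmultinom
#' @importFrom utils read.csv write.csv head combn
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Decimal rounding in which exact halves move away from zero (the convention
#' of most forensic reporting software), unlike [round()], which rounds halves
#' to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` places, halves away from zero.
#' @examples
#' round_half_up(0.0025, 3) # 0.003
#' round(0.0025, 3)         # 0.002 (banker's rounding)
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## sum of logs -> log of product complement etc. helpers
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

stop_kinstr <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "kinstr_error")))
}

## deterministic child seeds below 2^31, derived from one master seed
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + 11 * as.numeric(index)) %% 2147483647L)
}
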