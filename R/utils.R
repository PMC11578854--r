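#' @importFrom stats plogis qlogis rbinom rpois rgamma runif dpois dbinom
#'   dgamma qgamma qpois quantile lm coef
#' @importFrom utils read.csv write.csv
NULL

logit <- function(p) qlogis(p)
ilogit <- function(x) plogis(x)

#' Numerically stable log-sum-exp
#' @param x numeric vector of log values
#' @return log(sum(exp(x)))
#' @keywords internal
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# single check used by all constructors
check_prob <- function(x, name, open = TRUE) {
  if (any(!is.finite(x))) stopf("%s must be finite", name)
  if (open) {
    if (any(x <= 0 | x >= 1)) stopf("%s must lie strictly in (0, 1)", name)
  } else {
    if (any(x < 0 | x > 1)) stopf("%s must lie in [0, 1]", name)
  }
  invisible(x)
}
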