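# internal helpers: typed conditions, fast OLS, small shared utilities

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("tscmr_input_error", "tscmr_error")))
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("tscmr_config_error", "tscmr_error")))
}

Z95 <- stats::qnorm(0.975)

#' Simple-regression slope and standard error
#'
#' Closed-form OLS of `y` on `x` (with intercept), returning the slope and its
#' standard error. Used by the individual-level simulation engine where calling
#' [stats::lm()] per repetition would dominate the runtime.
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @return named numeric vector with elements `beta` and `se`.
#' @keywords internal
#' @noRd
ols_slope <- function(x, y) {
  n <- length(x)
  xc <- x - mean(x)
  yc <- y - mean(y)
  sxx <- sum(xc * xc)
  beta <- sum(xc * yc) / sxx
  rss <- sum((yc - beta * xc)^2)
  se <- sqrt(rss / (n - 2) / sxx)
  c(beta = beta, se = se)
}

# two-sided normal p-value from an estimate and its SE
z_pvalue <- function(beta, se) 2 * stats::pnorm(-abs(beta / se))

`%||%` <- function(a, b) if (is.null(a)) b else a
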