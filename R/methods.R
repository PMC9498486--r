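#' @export
print.mr_estimate <- function(x, digits = 4, ...) {
  cat("MR estimate (", x$method, "), ", x$n_snps, " variant(s)\n", sep = "")
  cat(sprintf("  beta = %.*g (se %.*g), 95%% CI [%.*g, %.*g]\n",
              digits, x$beta, digits, x$se,
              digits, x$ci_low, digits, x$ci_high))
  if (!is.na(x$intercept))
    cat(sprintf("  intercept = %.*g (se %.*g)\n",
                digits, x$intercept, digits, x$intercept_se))
  invisible(x)
}

#' @export
coef.mr_estimate <- function(object, ...) {
  out <- c(beta = object$beta)
  if (!is.na(object$intercept)) out <- c(out, intercept = object$intercept)
  out
}

#' @export
confint.mr_estimate <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- coef(object)
  se <- c(object$se, if (!is.na(object$intercept)) object$intercept_se)
  out <- cbind(est - z * se, est + z * se)
  dimnames(out) <- list(names(est),
                        sprintf("%.1f %%", c((1 - level) / 2,
                                             1 - (1 - level) / 2) * 100))
  out
}

#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  cat("MR estimator suite, ", x$n_snps, " variant(s)\n", sep = "")
  print(format(as.data.frame(x), digits = digits), ...)
  if (!is.na(x$Q$Q))
    cat(sprintf("Cochran Q = %.*g on %d df (p = %.3g)\n",
                digits, x$Q$Q, x$Q$df, x$Q$p))
  cat("primary estimator:", x$primary, "\n")
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  coef(object$estimates[[object$primary]])
}

#' @export
plot.mr_fit <- function(x, ...) {
  d <- x$data
  plot(d$b_gx, d$b_gy, pch = 19,
       xlab = "variant-exposure association",
       ylab = "variant-outcome association", ...)
  graphics::segments(d$b_gx, d$b_gy - Z95 * d$se_gy,
                     d$b_gx, d$b_gy + Z95 * d$se_gy, col = "grey60")
  for (nm in names(x$estimates)) {
    e <- x$estimates[[nm]]
    graphics::abline(a = if (is.na(e$intercept)) 0 else e$intercept,
                     b = e$beta,
                     lty = if (nm == x$primary) 1 else 2)
  }
  invisible(x)
}

#' @export
print.tscmr_adjustment <- function(x, digits = 4, ...) {
  cat("two-step cis-MR adjusted association\n")
  cat(sprintf("  crude beta = %.*g (se %.*g)\n", digits, x$b_go,
              digits, x$se_go))
  cat(sprintf("  subtracted pathway(s): %s\n",
              paste(signif(x$subtracted, digits), collapse = ", ")))
  cat(sprintf("  adjusted beta = %.*g, PE se = %.*g", digits, x$b_adj,
              digits, x$se_pe))
  if (!is.na(x$se_bs))
    cat(sprintf(", bootstrap se = %.*g (n_boot = %d)", digits, x$se_bs,
                x$n_boot))
  cat("\n")
  invisible(x)
}

#' @export
coef.tscmr_adjustment <- function(object, ...) c(b_adj = object$b_adj)

#' @export
print.sim_config <- function(x, ...) {
  cat("simulation config: scenario ", x$scenario,
      ", n_per_sample ", x$n_per_sample, ", n_reps ", x$n_reps,
      ", engine ", x$engine, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' @export
print.tscmr_simulation <- function(x, digits = 4, ...) {
  s <- x$summary
  cat("two-step cis-MR simulation (", x$config$scenario, ", ",
      x$config$n_reps, " repetitions, n = ", x$config$n_per_sample,
      " per sample)\n", sep = "")
  line <- function(label, m, se_, mc) {
    cat(sprintf("  %-9s mean %.*g (mean se %.*g, MC se %.2g)\n", label,
                digits, s[[m]], digits, s[[se_]], s[[mc]]))
  }
  line("crude", "mean_crude", "mean_se_crude", "mcse_crude")
  line("adjusted", "mean_adjusted", "mean_se_pe", "mcse_adjusted")
  cat(sprintf("  bias: crude %.*g, adjusted %.*g (true effect %g)\n",
              digits, s[["bias_crude"]], digits, s[["bias_adjusted"]],
              x$config$true_effect))
  if (x$n_resampled > 0)
    cat("  ", x$n_resampled, " repetition(s) resampled by the ",
        "weak-instrument guard\n", sep = "")
  invisible(x)
}

#' @export
summary.tscmr_simulation <- function(object, ...) object$summary

#' @export
plot.tscmr_simulation <- function(x, breaks = 60, ...) {
  graphics::hist(x$reps$adjusted, breaks = breaks, main = "",
                 xlab = "adjusted estimate", ...)
  graphics::abline(v = x$config$true_effect, lwd = 2)
  graphics::abline(v = x$summary[["mean_adjusted"]], lty = 2)
  invisible(x)
}

#' @export
print.tscmr_pipeline <- function(x, digits = 4, ...) {
  cat("two-step cis-MR pipeline\n")
  cp <- x$crude_fit$estimates[[x$crude_fit$primary]]
  ap <- x$adjusted_fit$estimates[[x$adjusted_fit$primary]]
  cat(sprintf("  crude (%s):    %.*g [%.*g, %.*g]\n", x$crude_fit$primary,
              digits, cp$beta, digits, cp$ci_low, digits, cp$ci_high))
  cat(sprintf("  adjusted (%s): %.*g [%.*g, %.*g]\n",
              x$adjusted_fit$primary,
              digits, ap$beta, digits, ap$ci_low, digits, ap$ci_high))
  cat(sprintf("  percent difference (%s): %s\n", x$comparison_method,
              ifelse(is.na(x$percent_difference), "NA",
                     paste0(round(x$percent_difference), "%"))))
  cat("  outputs in ", dirname(x$files[["report"]]), "\n", sep = "")
  invisible(x)
}
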