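#' Assemble per-variant ratio inputs
#'
#' Bundles the variant-exposure and variant-outcome associations (crude or
#' adjusted) that every MR estimator consumes. All vectors are recycled to a
#' common length.
#'
#' @param b_gx,se_gx variant-exposure associations and standard errors.
#' @param b_gy,se_gy variant-outcome associations and standard errors.
#' @param snp_id variant identifiers (defaults to `snp1`, `snp2`, ...).
#' @return a `data.frame` of class `ratio_input`.
#' @export
ratio_input <- function(b_gx, se_gx, b_gy, se_gy, snp_id = NULL) {
  n <- max(length(b_gx), length(b_gy))
  out <- data.frame(snp_id = snp_id %||% paste0("snp", seq_len(n)),
                    b_gx = b_gx, se_gx = se_gx, b_gy = b_gy, se_gy = se_gy,
                    stringsAsFactors = FALSE)
  if (any(!is.finite(out$b_gx)) || any(!is.finite(out$b_gy)))
    stop_input("associations must be finite")
  if (any(out$se_gx <= 0) || any(out$se_gy <= 0))
    stop_input("standard errors must be positive")
  class(out) <- c("ratio_input", "data.frame")
  out
}

new_mr_estimate <- function(method, beta, se, n_snps,
                            intercept = NA_real_, intercept_se = NA_real_,
                            n_boot = NA_integer_, seed = NA_integer_) {
  structure(list(method = method, beta = beta, se = se,
                 ci_low = beta - Z95 * se, ci_high = beta + Z95 * se,
                 intercept = intercept, intercept_se = intercept_se,
                 n_snps = as.integer(n_snps),
                 n_boot = n_boot, seed = seed),
            class = "mr_estimate")
}

.check_rs <- function(rs, min_snps, caller) {
  if (!is.data.frame(rs) ||
      !all(c("b_gx", "se_gx", "b_gy", "se_gy") %in% names(rs)))
    stop_input(caller, " expects a ratio_input table")
  if (nrow(rs) < min_snps)
    stop_input(caller, " needs at least ", min_snps, " variants",
               if (min_snps > 1) " (use wald_ratio for a single variant)")
  rs
}

# per-variant ratios and first-order inverse-variance weights
.ratios <- function(rs) rs$b_gy / rs$b_gx
.fo_weights <- function(rs) rs$b_gx^2 / rs$se_gy^2

#' Wald ratio causal estimate for a single variant
#'
#' The variant-outcome association divided by the variant-exposure
#' association. The default first-order standard error `se_gy / |b_gx|`
#' ignores the uncertainty of the denominator; `se_method = "delta"` adds the
#' second-order term `b_gy^2 se_gx^2 / b_gx^4` and is never smaller.
#'
#' @param r a one-row [ratio_input()] (or a list with elements `b_gx`,
#'   `se_gx`, `b_gy`, `se_gy`).
#' @param se_method `"first_order"` (default) or `"delta"`.
#' @return an `mr_estimate`.
#' @export
wald_ratio <- function(r, se_method = c("first_order", "delta")) {
  se_method <- match.arg(se_method)
  if (is.data.frame(r)) {
    if (nrow(r) != 1L) stop_input("wald_ratio takes a single variant")
    r <- as.list(r)
  }
  if (r$b_gx == 0) stop_input("undefined ratio: b_gx is zero")
  beta <- r$b_gy / r$b_gx
  se <- switch(se_method,
    first_order = r$se_gy / abs(r$b_gx),
    delta = sqrt(r$se_gy^2 / r$b_gx^2 + r$b_gy^2 * r$se_gx^2 / r$b_gx^4))
  new_mr_estimate("wald", beta, se, 1L)
}

#' Inverse-variance weighted estimate
#'
#' Fixed-effect inverse-variance weighted mean of the per-variant Wald
#' ratios, with first-order weights `b_gx^2 / se_gy^2`; algebraically
#' identical to a zero-intercept regression of `b_gy` on `b_gx` weighted by
#' `1 / se_gy^2`.
#'
#' @param rs a [ratio_input()] table with at least two variants.
#' @return an `mr_estimate`.
#' @export
mr_ivw <- function(rs) {
  rs <- .check_rs(rs, 2L, "mr_ivw")
  w <- .fo_weights(rs)
  beta <- sum(w * .ratios(rs)) / sum(w)
  new_mr_estimate("ivw", beta, sqrt(1 / sum(w)), nrow(rs))
}

#' MR-Egger regression
#'
#' Weighted regression of the variant-outcome on the variant-exposure
#' associations with an unconstrained intercept (weights `1 / se_gy^2`),
#' after orienting every variant so that `b_gx >= 0`. The slope estimates the
#' causal effect under the InSIDE assumption (instrument strength independent
#' of direct effects); the intercept estimates directional pleiotropy.
#'
#' @param rs a [ratio_input()] table with at least three variants.
#' @return an `mr_estimate` with `intercept` and `intercept_se`.
#' @export
mr_egger <- function(rs) {
  rs <- .check_rs(rs, 3L, "mr_egger")
  flip <- sign(rs$b_gx)
  flip[flip == 0] <- 1
  bx <- rs$b_gx * flip
  by <- rs$b_gy * flip
  if (diff(range(bx)) == 0)
    stop_input("mr_egger is undefined when all |b_gx| are equal ",
               "(no variation to regress on)")
  fit <- stats::lm(by ~ bx, weights = 1 / rs$se_gy^2)
  cf <- summary(fit)$coefficients
  new_mr_estimate("egger", cf["bx", 1], cf["bx", 2], nrow(rs),
                  intercept = cf["(Intercept)", 1],
                  intercept_se = cf["(Intercept)", 2])
}

# weighted 50th percentile with the S_j - w_j/2 interpolation scheme
weighted_median_point <- function(ratios, w) {
  ord <- order(ratios)
  r <- ratios[ord]
  ws <- w[ord] / sum(w)
  pivot <- cumsum(ws) - ws / 2
  if (pivot[1] >= 0.5) return(r[1])
  k <- max(which(pivot < 0.5))
  if (k == length(r)) return(r[length(r)])
  r[k] + (r[k + 1] - r[k]) * (0.5 - pivot[k]) / (pivot[k + 1] - pivot[k])
}

#' Weighted median estimate
#'
#' The inverse-variance weighted 50th percentile of the per-variant Wald
#' ratios: consistent when variants carrying at least half the weight are
#' valid instruments. Ratios are sorted, cumulative standardized weights
#' formed, and the point where `S_j - w_j/2` crosses 0.5 interpolated
#' linearly. The SE comes from a seeded parametric bootstrap that redraws the
#' per-variant associations from their sampling distributions (weights held
#' fixed).
#'
#' @param rs a [ratio_input()] table with at least three variants.
#' @param n_boot bootstrap replicates. Default 2000.
#' @param seed integer seed.
#' @return an `mr_estimate`.
#' @export
mr_weighted_median <- function(rs, n_boot = 2000L, seed = 1L) {
  rs <- .check_rs(rs, 3L, "mr_weighted_median")
  w <- .fo_weights(rs)
  beta <- weighted_median_point(.ratios(rs), w)
  se <- with_seed(seed, {
    reps <- vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(nrow(rs), rs$b_gx, rs$se_gx)
      by <- stats::rnorm(nrow(rs), rs$b_gy, rs$se_gy)
      weighted_median_point(by / bx, w)
    }, numeric(1))
    stats::sd(reps)
  })
  new_mr_estimate("weighted_median", beta, se, nrow(rs),
                  n_boot = as.integer(n_boot), seed = as.integer(seed))
}

# argmax of the weighted normal-kernel density of the ratios
weighted_mode_point <- function(ratios, w, h) {
  if (h <= 0 || diff(range(ratios)) == 0) return(ratios[which.max(w)])
  ws <- w / sum(w)
  dens <- function(t) {
    vapply(t, function(ti) sum(ws * stats::dnorm((ti - ratios) / h)), numeric(1))
  }
  grid <- seq(min(ratios) - 3 * h, max(ratios) + 3 * h, length.out = 512L)
  d <- dens(grid)
  k <- which.max(d)
  lo <- grid[max(1L, k - 1L)]
  hi <- grid[min(length(grid), k + 1L)]
  stats::optimize(dens, c(lo, hi), maximum = TRUE, tol = 1e-10)$maximum
}

# rule-of-thumb kernel scale from the spread of the ratios (MAD-guarded)
mode_bandwidth <- function(ratios, bandwidth_factor) {
  s <- min(stats::sd(ratios), stats::mad(ratios, constant = 1.4826))
  if (!is.finite(s)) s <- 0
  bandwidth_factor * 0.9 * s * length(ratios)^(-1 / 5)
}

#' Weighted mode estimate
#'
#' The mode of the inverse-variance weighted normal-kernel density of the
#' per-variant Wald ratios: consistent when the most common ratio value comes
#' from valid instruments (the ZEMPA assumption), however many variants are
#' invalid. Bandwidth is `bandwidth_factor` times a rule-of-thumb scale,
#' `0.9 min(sd, mad) n^{-1/5}`, from the ratio spread. SE by seeded
#' parametric bootstrap (bandwidth and weights held fixed).
#'
#' @param rs a [ratio_input()] table with at least three variants.
#' @param bandwidth_factor positive multiplier on the rule-of-thumb
#'   bandwidth. Default 1.
#' @param n_boot bootstrap replicates. Default 2000.
#' @param seed integer seed.
#' @return an `mr_estimate`.
#' @export
mr_weighted_mode <- function(rs, bandwidth_factor = 1, n_boot = 2000L,
                             seed = 1L) {
  rs <- .check_rs(rs, 3L, "mr_weighted_mode")
  if (bandwidth_factor <= 0) stop_input("bandwidth_factor must be positive")
  w <- .fo_weights(rs)
  r <- .ratios(rs)
  h <- mode_bandwidth(r, bandwidth_factor)
  beta <- weighted_mode_point(r, w, h)
  se <- with_seed(seed, {
    reps <- vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(nrow(rs), rs$b_gx, rs$se_gx)
      by <- stats::rnorm(nrow(rs), rs$b_gy, rs$se_gy)
      weighted_mode_point(by / bx, w, h)
    }, numeric(1))
    stats::sd(reps)
  })
  new_mr_estimate("weighted_mode", beta, se, nrow(rs),
                  n_boot = as.integer(n_boot), seed = as.integer(seed))
}

#' Cochran's Q heterogeneity statistic of the Wald ratios
#'
#' Weighted sum of squared deviations of the per-variant ratios from the IVW
#' estimate, with first-order weights. Under homogeneity Q follows a
#' chi-square distribution with `n - 1` degrees of freedom; a small p-value
#' is a falsification signal for horizontal pleiotropy. Note Q is not
#' invariant to rescaling the weights: it is defined with the same
#' `b_gx^2 / se_gy^2` weights as the IVW estimator.
#'
#' @param rs a [ratio_input()] table with at least two variants.
#' @return a list with elements `Q`, `df` and `p`.
#' @export
cochran_q <- function(rs) {
  rs <- .check_rs(rs, 2L, "cochran_q")
  w <- .fo_weights(rs)
  ivw_beta <- sum(w * .ratios(rs)) / sum(w)
  Q <- sum(w * (.ratios(rs) - ivw_beta)^2)
  df <- nrow(rs) - 1L
  list(Q = Q, df = df, p = stats::pchisq(Q, df, lower.tail = FALSE))
}

#' Instrument-strength F-statistic
#'
#' The squared z-score of the variant-exposure association,
#' `b_gx^2 / se_gx^2`; weak-instrument bias is inversely proportional to it.
#' Vectorized.
#'
#' @param b_gx variant-exposure association(s).
#' @param se_gx standard error(s), positive.
#' @return numeric vector of F-statistics.
#' @export
f_statistic <- function(b_gx, se_gx) {
  if (any(se_gx <= 0)) stop_input("se_gx must be positive")
  b_gx^2 / se_gx^2
}

#' Run the full MR estimator suite
#'
#' Computes IVW, MR-Egger, weighted median and weighted mode (plus the single
#' Wald ratio when only one variant is supplied), together with Cochran's Q,
#' and selects the primary estimator by the heterogeneity rule: IVW unless
#' Q's p-value falls below `q_pvalue_threshold`, in which case the weighted
#' median (robust to up to half the weight coming from invalid instruments)
#' is promoted.
#'
#' @param rs a [ratio_input()] table.
#' @param q_pvalue_threshold p-value below which heterogeneity switches the
#'   primary estimator to the weighted median. Default 0.05.
#' @param n_boot,seed bootstrap controls passed to the median/mode.
#' @return an object of class `mr_fit`: list with `estimates` (named list of
#'   `mr_estimate`), `Q` (from [cochran_q()]), `primary` (method name), and
#'   `n_snps`.
#' @export
mr_fit <- function(rs, q_pvalue_threshold = 0.05, n_boot = 2000L, seed = 1L) {
  if (q_pvalue_threshold <= 0 || q_pvalue_threshold >= 1)
    stop_input("q_pvalue_threshold must be in (0, 1)")
  est <- list()
  if (nrow(rs) == 1L) {
    est$wald <- wald_ratio(rs)
    q <- list(Q = NA_real_, df = NA_integer_, p = NA_real_)
    primary <- "wald"
  } else {
    est$ivw <- mr_ivw(rs)
    if (nrow(rs) >= 3L) {
      est$egger <- mr_egger(rs)
      est$weighted_median <- mr_weighted_median(rs, n_boot = n_boot,
                                                seed = seed)
      est$weighted_mode <- mr_weighted_mode(rs, n_boot = n_boot,
                                            seed = seed + 1L)
    }
    q <- cochran_q(rs)
    primary <- if (!is.na(q$p) && q$p < q_pvalue_threshold &&
                   !is.null(est$weighted_median)) "weighted_median" else "ivw"
  }
  structure(list(estimates = est, Q = q, primary = primary,
                 n_snps = nrow(rs), data = rs,
                 q_pvalue_threshold = q_pvalue_threshold),
            class = "mr_fit")
}
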