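#' Configure the Monte Carlo simulation study
#'
#' Defines the data-generating mechanism used to study the bias and precision
#' of the two-step adjustment. All nodes are standard-normal variables; every
#' structural arrow has coefficient `structural_effect` and the exposure
#' affects the outcome with coefficient `true_effect`. The variant is a
#' three-level genotype, `binomial(2, p)` per individual, with the allele
#' frequency `p` redrawn each repetition from `normal(maf_mean, maf_sd)`
#' truncated to (0.01, 0.99), and the per-allele variant effects (on the
#' exposure and on each confounder) redrawn each repetition from
#' `normal(effect_mean, effect_sd)`. Each association is estimated by OLS in
#' its own independent sample of `n_per_sample` individuals; the
#' confounder-outcome effect is the Wald ratio of the genome-wide liability
#' score's association with the outcome over its association with the
#' confounder, each again from its own sample.
#'
#' Scenarios: `single_pathway` has one pleiotropic confounder;
#' `two_independent` adds a second confounder with its own variant effect and
#' liability; `two_dependent` additionally makes the first confounder a
#' cause of the second (unit structural effect), so the two biasing pathways
#' share a segment and sequential adjustment over-corrects.
#'
#' Repetitions whose estimated variant-exposure z-score falls below
#' `resample_z` are discarded and redrawn (the Wald ratio is undefined at a
#' null instrument and its moments do not exist without such a guard); the
#' count of resampled repetitions is reported in the result.
#'
#' @param n_per_sample individuals per estimation sample. Default 200000.
#' @param n_reps repetitions. Default 5000.
#' @param maf_mean,maf_sd allele-frequency sampling distribution. Defaults
#'   0.5 and 0.1.
#' @param effect_mean,effect_sd variant effect-size sampling distribution.
#'   Defaults 0.1 and 0.05.
#' @param structural_effect coefficient of every non-variant arrow. Default 1.
#' @param true_effect exposure-outcome causal effect (the estimand). Default 1.
#' @param scenario one of `"single_pathway"`, `"two_independent"`,
#'   `"two_dependent"`.
#' @param seed integer seed; the whole run is reproducible given the seed.
#' @param engine `"summary"` (default) draws the OLS estimates directly from
#'   their exact joint sampling distribution (normal slopes with
#'   model-implied residual variances, chi-square noise on the estimated
#'   SEs, var(G) = 2p(1-p)); `"individual"` generates every individual and
#'   runs the regressions. The two agree to Monte Carlo error (see the
#'   methods vignette); only `"summary"` is tractable at paper scale.
#' @param n_boot parametric-bootstrap replicates for the bootstrap SE of the
#'   adjusted association (0 disables the bootstrap). Default 10000.
#' @param resample_z weak-instrument guard threshold on the estimated
#'   variant-exposure z-score. Default 2.
#' @param split_liability estimate the liability-confounder and
#'   liability-outcome associations in two separate samples (default) or one.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_per_sample = 200000L, n_reps = 5000L,
                       maf_mean = 0.5, maf_sd = 0.1,
                       effect_mean = 0.1, effect_sd = 0.05,
                       structural_effect = 1, true_effect = 1,
                       scenario = c("single_pathway", "two_independent",
                                    "two_dependent"),
                       seed = 1L,
                       engine = c("summary", "individual"),
                       n_boot = 10000L, resample_z = 2,
                       split_liability = TRUE) {
  scenario <- match.arg(scenario)
  engine <- match.arg(engine)
  if (n_per_sample < 100) stop_input("n_per_sample must be at least 100")
  if (n_reps < 1) stop_input("n_reps must be at least 1")
  if (maf_sd < 0 || effect_sd < 0) stop_input("SDs must be non-negative")
  structure(list(n_per_sample = as.integer(n_per_sample),
                 n_reps = as.integer(n_reps),
                 maf_mean = maf_mean, maf_sd = maf_sd,
                 effect_mean = effect_mean, effect_sd = effect_sd,
                 structural_effect = structural_effect,
                 true_effect = true_effect,
                 scenario = scenario, seed = as.integer(seed),
                 engine = engine, n_boot = as.integer(n_boot),
                 resample_z = resample_z,
                 split_liability = isTRUE(split_liability)),
            class = "sim_config")
}

n_confounders <- function(scenario) {
  if (scenario == "single_pathway") 1L else 2L
}

# truncated normal draw for allele frequencies
draw_maf <- function(m, mean, sd) {
  p <- stats::rnorm(m, mean, sd)
  bad <- p <= 0.01 | p >= 0.99
  while (any(bad)) {
    p[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- p <= 0.01 | p >= 0.99
  }
  p
}

#' Simulate one repetition at the individual level
#'
#' Draws one repetition's allele frequency and variant effects, generates the
#' independent estimation samples individual by individual, and returns the
#' OLS summary estimates that the two-step adjustment consumes. Advances the
#' session RNG; seed externally (e.g. via [run_simulation()]) for
#' reproducibility. No weak-instrument guard is applied here — the caller
#' decides (see [run_simulation()]).
#'
#' @param config a [sim_config()].
#' @return a list with elements `b_gx`, `se_gx`, `b_gy`, `se_gy`, and
#'   per-confounder vectors `b_gc`, `se_gc`, `b_co`, `se_co` (first-order
#'   Wald SE), plus the underlying liability regressions `b_zc`, `se_zc`,
#'   `b_zy`, `se_zy`, and the drawn truth `maf`, `eff_x`, `eff_c`.
#' @export
simulate_repetition <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  K <- n_confounders(config$scenario)
  p <- draw_maf(1L, config$maf_mean, config$maf_sd)
  eff_x <- stats::rnorm(1L, config$effect_mean, config$effect_sd)
  eff_c <- stats::rnorm(K, config$effect_mean, config$effect_sd)

  gen <- function() .generate_sample(config, p, eff_x, eff_c)

  s <- gen()
  fx <- ols_slope(s$G, s$X)
  s <- gen()
  fy <- ols_slope(s$G, s$Y)
  b_gc <- se_gc <- b_zc <- se_zc <- b_zy <- se_zy <- numeric(K)
  for (k in seq_len(K)) {
    s <- gen()
    fc <- ols_slope(s$G, s$C[[k]])
    b_gc[k] <- fc["beta"]; se_gc[k] <- fc["se"]
    s <- gen()
    fzc <- ols_slope(s$Z[[k]], s$C[[k]])
    if (config$split_liability) s <- gen()
    fzy <- ols_slope(s$Z[[k]], s$Y)
    b_zc[k] <- fzc["beta"]; se_zc[k] <- fzc["se"]
    b_zy[k] <- fzy["beta"]; se_zy[k] <- fzy["se"]
  }
  list(b_gx = unname(fx["beta"]), se_gx = unname(fx["se"]),
       b_gy = unname(fy["beta"]), se_gy = unname(fy["se"]),
       b_gc = b_gc, se_gc = se_gc,
       b_zc = b_zc, se_zc = se_zc, b_zy = b_zy, se_zy = se_zy,
       b_co = b_zy / b_zc, se_co = se_zy / abs(b_zc),
       maf = p, eff_x = eff_x, eff_c = eff_c)
}

# one estimation sample of the full causal graph
.generate_sample <- function(config, p, eff_x, eff_c) {
  n <- config$n_per_sample
  s <- config$structural_effect
  K <- length(eff_c)
  G <- stats::rbinom(n, 2L, p)
  X <- eff_x * G + stats::rnorm(n)
  Z <- C <- vector("list", K)
  for (k in seq_len(K)) {
    Z[[k]] <- stats::rnorm(n)
    C[[k]] <- eff_c[k] * G + Z[[k]] + stats::rnorm(n)
  }
  if (config$scenario == "two_dependent") {
    C[[2L]] <- C[[2L]] + s * C[[1L]]
  }
  Y <- config$true_effect * X + stats::rnorm(n)
  for (k in seq_len(K)) Y <- Y + s * C[[k]]
  list(G = G, X = X, Z = Z, C = C, Y = Y)
}

# --- summary engine -------------------------------------------------------

# draw m repetitions' worth of OLS estimates from their exact joint sampling
# distribution under the scenario's causal graph
.draw_estimates <- function(config, m) {
  s <- config$structural_effect
  t <- config$true_effect
  n <- config$n_per_sample
  K <- n_confounders(config$scenario)
  dep <- config$scenario == "two_dependent"

  p <- draw_maf(m, config$maf_mean, config$maf_sd)
  vG <- 2 * p * (1 - p)
  x <- stats::rnorm(m, config$effect_mean, config$effect_sd)
  cc <- matrix(stats::rnorm(m * K, config$effect_mean, config$effect_sd), m, K)

  # true slopes on G and residual variances given the regressor
  if (!dep) {
    b_gy <- t * x + s * rowSums(cc)
    v_y_g <- t^2 + 2 * K * s^2 + 1
    b_gc <- cc                                   # slope of C_k on G
    v_c_g <- matrix(2, m, K)
    b_zy <- matrix(s, m, K)                      # slope of Y on Z_k
    var_y <- b_gy^2 * vG + v_y_g
    v_y_z <- var_y - s^2
    v_y_z <- cbind(v_y_z, if (K == 2L) v_y_z)[, seq_len(K), drop = FALSE]
    var_c <- cc^2 * vG + 2
  } else {
    # C1 -> C2 with unit-scale structural effect; both confound the outcome
    b_gc <- cbind(cc[, 1L], cc[, 2L] + s * cc[, 1L])
    b_gy <- t * x + s * b_gc[, 1L] + s * b_gc[, 2L]
    v_c1_g <- 2
    v_c2_g <- 2 * s^2 + 2
    v_y_g <- t^2 + (2 * s^2 + s^2 * v_c2_g + 4 * s^3) + 1
    v_c_g <- cbind(rep(v_c1_g, m), rep(v_c2_g, m))
    var_y <- b_gy^2 * vG + v_y_g
    b_zy <- cbind(rep(s + s^2, m), rep(s, m))    # Z1 reaches Y via C1 and C1->C2
    v_y_z <- cbind(var_y - (s + s^2)^2, var_y - s^2)
    var_c <- cbind(cc[, 1L]^2 * vG + 2, b_gc[, 2L]^2 * vG + v_c2_g)
  }

  se_of <- function(resid_var, reg_var) sqrt(resid_var / (n * reg_var))
  noisy_se <- function(se) se * sqrt(stats::rchisq(length(se), n - 2) / (n - 2))

  se_gx <- se_of(1, vG)
  se_gy <- se_of(v_y_g, vG)
  bhx <- stats::rnorm(m, x, se_gx)
  bhy <- stats::rnorm(m, b_gy, se_gy)
  out <- list(maf = p, eff_x = x, eff_c = cc,
              b_gx = bhx, se_gx = noisy_se(se_gx),
              b_gy = bhy, se_gy = noisy_se(se_gy))
  b_gc_h <- se_gc_h <- b_zc_h <- se_zc_h <- b_zy_h <- se_zy_h <-
    matrix(NA_real_, m, K)
  for (k in seq_len(K)) {
    se_gc <- se_of(v_c_g[, k], vG)
    se_zc <- se_of(var_c[, k] - 1, 1)            # Z has unit variance
    se_zy <- se_of(v_y_z[, k], 1)
    b_gc_h[, k] <- stats::rnorm(m, b_gc[, k], se_gc)
    b_zc_h[, k] <- stats::rnorm(m, 1, se_zc)
    b_zy_h[, k] <- stats::rnorm(m, b_zy[, k], se_zy)
    se_gc_h[, k] <- noisy_se(se_gc)
    se_zc_h[, k] <- noisy_se(se_zc)
    se_zy_h[, k] <- noisy_se(se_zy)
  }
  out$b_gc <- b_gc_h; out$se_gc <- se_gc_h
  out$b_zc <- b_zc_h; out$se_zc <- se_zc_h
  out$b_zy <- b_zy_h; out$se_zy <- se_zy_h
  out$b_co <- b_zy_h / b_zc_h
  out$se_co <- se_zy_h / abs(b_zc_h)
  out
}

.bind_estimates <- function(a, b) {
  for (nm in names(a)) {
    a[[nm]] <- if (is.matrix(a[[nm]])) rbind(a[[nm]], b[[nm]])
               else c(a[[nm]], b[[nm]])
  }
  a
}

.subset_estimates <- function(e, keep) {
  for (nm in names(e)) {
    e[[nm]] <- if (is.matrix(e[[nm]])) e[[nm]][keep, , drop = FALSE]
               else e[[nm]][keep]
  }
  e
}

# repetition-level estimates with the weak-instrument guard applied
.draw_guarded <- function(config) {
  m <- config$n_reps
  attempts <- 0L
  got <- NULL
  need <- m
  repeat {
    e <- if (config$engine == "summary") {
      .draw_estimates(config, need)
    } else {
      reps <- replicate(need, simulate_repetition(config), simplify = FALSE)
      .collate_reps(reps)
    }
    z_ok <- abs(e$b_gx / e$se_gx) >= config$resample_z
    attempts <- attempts + need
    got <- if (is.null(got)) .subset_estimates(e, z_ok)
           else .bind_estimates(got, .subset_estimates(e, z_ok))
    n_ok <- length(got$b_gx)
    if (n_ok >= m) break
    if (attempts > 100L * m + 1000L)
      stop_input("weak-instrument guard rejected nearly every repetition; ",
                 "the configured effect sizes cannot instrument the exposure")
    need <- m - n_ok
  }
  got <- .subset_estimates(got, seq_len(m))
  got$n_resampled <- attempts - m
  got
}

.collate_reps <- function(reps) {
  scal <- c("b_gx", "se_gx", "b_gy", "se_gy", "maf", "eff_x")
  vec <- c("b_gc", "se_gc", "b_zc", "se_zc", "b_zy", "se_zy", "b_co", "se_co")
  out <- list()
  for (nm in scal) out[[nm]] <- vapply(reps, `[[`, numeric(1), nm)
  out$eff_c <- do.call(rbind, lapply(reps, `[[`, "eff_c"))
  for (nm in vec) out[[nm]] <- do.call(rbind, lapply(reps, `[[`, nm))
  out
}

# chunked parametric bootstrap SE of the adjusted association, one SD per rep
.boot_se_vec <- function(e, n_boot, chunk = 256L) {
  m <- length(e$b_gy)
  K <- ncol(e$b_gc)
  out <- numeric(m)
  for (start in seq(1L, m, by = chunk)) {
    idx <- start:min(start + chunk - 1L, m)
    mm <- length(idx)
    draws <- matrix(stats::rnorm(n_boot * mm,
                                 rep(e$b_gy[idx], each = n_boot),
                                 rep(e$se_gy[idx], each = n_boot)),
                    n_boot, mm)
    for (k in seq_len(K)) {
      gc_d <- matrix(stats::rnorm(n_boot * mm,
                                  rep(e$b_gc[idx, k], each = n_boot),
                                  rep(e$se_gc[idx, k], each = n_boot)),
                     n_boot, mm)
      co_d <- matrix(stats::rnorm(n_boot * mm,
                                  rep(e$b_co[idx, k], each = n_boot),
                                  rep(e$se_co[idx, k], each = n_boot)),
                     n_boot, mm)
      draws <- draws - gc_d * co_d
    }
    mu <- colMeans(draws)
    out[idx] <- sqrt((colSums(draws^2) - n_boot * mu^2) / (n_boot - 1))
  }
  out
}

#' Run the simulation study
#'
#' For each repetition the crude estimate is the Wald ratio of the estimated
#' variant-outcome over variant-exposure association, and the adjusted
#' estimate is the same ratio after subtracting every biasing pathway's
#' product ([adjust_association()] / [sequential_adjust()] arithmetic, with
#' propagation-of-error and optional bootstrap SEs). Results are aggregated
#' with [summarize_simulation()]. Fully deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return an object of class `tscmr_simulation`: list with `config`, `reps`
#'   (per-repetition data.frame), `summary` (named numeric vector of means,
#'   biases, and Monte Carlo SEs), and `n_resampled`.
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    e <- .draw_guarded(config)
    crude <- e$b_gy / e$b_gx
    se_crude <- e$se_gy / abs(e$b_gx)
    subtract <- rowSums(e$b_gc * e$b_co)
    var_add <- rowSums(product_variance(e$b_gc, e$se_gc, e$b_co, e$se_co))
    b_adj <- e$b_gy - subtract
    se_pe <- sqrt(e$se_gy^2 + var_add)
    adjusted <- b_adj / e$b_gx
    se_adj <- se_pe / abs(e$b_gx)
    se_bs <- if (config$n_boot > 0)
      .boot_se_vec(e, config$n_boot) / abs(e$b_gx) else rep(NA_real_, length(crude))
    reps <- data.frame(crude = crude, adjusted = adjusted,
                       se_crude = se_crude, se_pe = se_adj, se_bs = se_bs,
                       b_gx = e$b_gx, f_stat = f_statistic(e$b_gx, e$se_gx))
    structure(list(config = config, reps = reps,
                   summary = summarize_simulation(reps, config$true_effect),
                   n_resampled = e$n_resampled),
              class = "tscmr_simulation")
  })
}

#' Summarize per-repetition simulation estimates
#'
#' Means, biases against the true effect, mean reported standard errors,
#' mean 95% confidence limits, and a Monte Carlo standard error
#' (sample SD / sqrt(n_reps)) for every reported mean.
#'
#' @param reps data.frame with columns `crude`, `adjusted`, `se_crude`,
#'   `se_pe` and optionally `se_bs` (one row per repetition).
#' @param true_effect the estimand, for the bias columns. Default 1.
#' @return named numeric vector: `mean_*`, `bias_*`, and `mcse_*` entries.
#' @export
summarize_simulation <- function(reps, true_effect = 1) {
  if (!is.data.frame(reps) || nrow(reps) == 0L)
    stop_input("'reps' must be a non-empty data.frame")
  n <- nrow(reps)
  mcse <- function(v) stats::sd(v) / sqrt(n)
  cols <- list(
    crude = reps$crude, adjusted = reps$adjusted,
    se_crude = reps$se_crude, se_pe = reps$se_pe,
    se_bs = reps$se_bs %||% NA_real_,
    ci_low_crude = reps$crude - Z95 * reps$se_crude,
    ci_high_crude = reps$crude + Z95 * reps$se_crude,
    ci_low_adjusted = reps$adjusted - Z95 * reps$se_pe,
    ci_high_adjusted = reps$adjusted + Z95 * reps$se_pe)
  out <- c()
  for (nm in names(cols)) {
    v <- cols[[nm]]
    if (all(is.na(v))) {
      out[paste0("mean_", nm)] <- NA_real_
      out[paste0("mcse_", nm)] <- NA_real_
    } else {
      out[paste0("mean_", nm)] <- mean(v)
      out[paste0("mcse_", nm)] <- if (n > 1L) mcse(v) else 0
    }
  }
  out["bias_crude"] <- out[["mean_crude"]] - true_effect
  out["bias_adjusted"] <- out[["mean_adjusted"]] - true_effect
  out["mcse_bias_crude"] <- out[["mcse_crude"]]
  out["mcse_bias_adjusted"] <- out[["mcse_adjusted"]]
  out
}
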