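test_that("the Wald ratio and its two SEs follow the closed forms", {
  expect_equal(wald_ratio(list(b_gx = 0.1, se_gx = 0.01, b_gy = 0,
                               se_gy = 0.05))$beta, 0)
  w <- wald_ratio(list(b_gx = 0.1, se_gx = 0.01, b_gy = 0.2, se_gy = 0.05))
  expect_equal(w$beta, 2)
  expect_equal(w$se, 0.5)
  expect_equal(w$ci_low, 2 - qnorm(0.975) * 0.5)
  # the delta SE adds a non-negative term
  set.seed(3)
  for (i in 1:20) {
    r <- list(b_gx = rnorm(1, 0, 0.2), se_gx = runif(1, 0.01, 0.1),
              b_gy = rnorm(1), se_gy = runif(1, 0.01, 0.1))
    if (r$b_gx == 0) next
    expect_gte(wald_ratio(r, "delta")$se, wald_ratio(r, "first_order")$se)
  }
  expect_error(wald_ratio(list(b_gx = 0, se_gx = 0.01, b_gy = 1,
                               se_gy = 0.1)),
               class = "tscmr_input_error")
})

test_that("IVW equals the weighted mean of ratios and the zero-intercept
           weighted regression", {
  # two identical variants: pooled beta is the shared ratio, SE shrinks 1/sqrt(2)
  rs <- ratio_input(c(0.1, 0.1), 0.01, c(0.2, 0.2), 0.05)
  est <- mr_ivw(rs)
  expect_equal(est$beta, 2)
  expect_equal(est$se, 0.5 / sqrt(2))

  # ratios {2, 4} with equal weights average to 3
  rs2 <- ratio_input(c(1, 1), 0.01, c(2, 4), 1)
  expect_equal(mr_ivw(rs2)$beta, 3)

  # dual route on random fixtures: weighted-mean form vs regression form
  for (seed in 1:5) {
    rs3 <- random_ratios(8, seed)
    est3 <- mr_ivw(rs3)
    fit <- lm(b_gy ~ 0 + b_gx, data = rs3, weights = 1 / rs3$se_gy^2)
    expect_equal(est3$beta, unname(coef(fit)), tolerance = 1e-12)
    # hand weighted mean
    w <- rs3$b_gx^2 / rs3$se_gy^2
    expect_equal(est3$beta, sum(w * rs3$b_gy / rs3$b_gx) / sum(w),
                 tolerance = 1e-12)
  }
  expect_error(mr_ivw(ratio_input(0.1, 0.01, 0.2, 0.05)),
               class = "tscmr_input_error")
})

test_that("MR-Egger recovers exact fits and matches the normal-equations
           closed form", {
  # collinear data: slope = theta, intercept = 0
  rs <- ratio_input(c(0.05, 0.1, 0.2), 0.01, 2 * c(0.05, 0.1, 0.2), 0.02)
  e <- suppressWarnings(mr_egger(rs))   # exact fit: summary.lm grumbles
  expect_equal(e$beta, 2, tolerance = 1e-10)
  expect_equal(e$intercept, 0, tolerance = 1e-10)
  # constant directional shift lands in the intercept
  rs2 <- ratio_input(c(0.05, 0.1, 0.2), 0.01,
                     2 * c(0.05, 0.1, 0.2) + 0.03, 0.02)
  e2 <- suppressWarnings(mr_egger(rs2))
  expect_equal(e2$beta, 2, tolerance = 1e-10)
  expect_equal(e2$intercept, 0.03, tolerance = 1e-10)

  # normal-equations oracle on a random fixture, including the orientation
  for (seed in 1:5) {
    rs3 <- random_ratios(9, seed)
    flip <- ifelse(rs3$b_gx < 0, -1, 1)
    X <- cbind(1, rs3$b_gx * flip)
    y <- rs3$b_gy * flip
    W <- diag(1 / rs3$se_gy^2)
    xtwx <- solve(t(X) %*% W %*% X)
    coefs <- xtwx %*% t(X) %*% W %*% y
    resid <- y - X %*% coefs
    sigma2 <- sum(resid^2 / rs3$se_gy^2) / (nrow(rs3) - 2)
    ses <- sqrt(diag(xtwx) * sigma2)
    e3 <- mr_egger(rs3)
    expect_equal(e3$beta, coefs[2], tolerance = 1e-10)
    expect_equal(e3$intercept, coefs[1], tolerance = 1e-10)
    expect_equal(e3$se, ses[2], tolerance = 1e-10)
    expect_equal(e3$intercept_se, ses[1], tolerance = 1e-10)
  }
  expect_error(mr_egger(ratio_input(c(0.1, 0.2), 0.01, c(0.2, 0.4), 0.05)),
               class = "tscmr_input_error")
})

test_that("the weighted median interpolates the cumulative weights and
           matches a grid-search oracle", {
  # equal weights: the plain median
  rs <- ratio_input(c(1, 1, 1), 0.01, c(1, 2, 9), 1)
  expect_equal(mr_weighted_median(rs, n_boot = 100, seed = 1)$beta, 2)
  # > 50% of the weight on one variant pins the estimate to its ratio
  rs2 <- ratio_input(c(1, 1, 1), 0.01, c(1, 2, 9),
                     c(3, 0.1, 3))   # se_gy: middle variant dominates
  expect_equal(mr_weighted_median(rs2, n_boot = 100, seed = 1)$beta, 2)

  # oracle: numerically invert the piecewise-linear cumulative-weight
  # interpolant through (ratio_j, S_j - w_j/2) at probability 0.5
  for (seed in 1:5) {
    rs3 <- random_ratios(5, seed)
    w <- rs3$b_gx^2 / rs3$se_gy^2
    r <- rs3$b_gy / rs3$b_gx
    ord <- order(r)
    ws <- w[ord] / sum(w)
    pivot <- cumsum(ws) - ws / 2
    grid <- seq(min(r), max(r), length.out = 2e6)
    cdf <- approx(r[ord], pivot, xout = grid, rule = 2)$y
    oracle <- grid[which.min(abs(cdf - 0.5))]
    est <- mr_weighted_median(rs3, n_boot = 100, seed = 1)$beta
    expect_equal(est, oracle, tolerance = 1e-5)
  }
  expect_error(mr_weighted_median(ratio_input(c(1, 1), 0.01, c(1, 2), 1)),
               class = "tscmr_input_error")
})

test_that("the weighted mode maximizes the weighted kernel density", {
  # identical ratios: the common value, any bandwidth
  rs <- ratio_input(c(0.1, 0.2, 0.4), 0.01, 1.5 * c(0.1, 0.2, 0.4), 0.05)
  for (bf in c(0.3, 1, 3))
    expect_equal(mr_weighted_mode(rs, bandwidth_factor = bf, n_boot = 100,
                                  seed = 1)$beta, 1.5)
  # dominant cluster beats a lone outlier
  rs2 <- ratio_input(c(1, 1, 1, 1), 0.01, c(1.0, 1.01, 0.99, 5), 1)
  m <- mr_weighted_mode(rs2, n_boot = 100, seed = 1)$beta
  expect_equal(m, 1.0, tolerance = 0.02)

  # grid oracle: argmax of the explicitly evaluated density
  for (seed in 1:4) {
    rs3 <- random_ratios(7, seed)
    r <- rs3$b_gy / rs3$b_gx
    w <- rs3$b_gx^2 / rs3$se_gy^2
    ws <- w / sum(w)
    h <- 0.9 * min(sd(r), mad(r, constant = 1.4826)) * length(r)^(-1 / 5)
    grid <- seq(min(r) - 3 * h, max(r) + 3 * h, by = 1e-4)
    dens <- vapply(grid,
                   function(t) sum(ws * dnorm((t - r) / h)), numeric(1))
    oracle <- grid[which.max(dens)]
    est <- mr_weighted_mode(rs3, n_boot = 100, seed = 1)$beta
    expect_equal(est, oracle, tolerance = 1e-3)
  }
  expect_error(mr_weighted_mode(ratio_input(c(1, 1), 0.01, c(1, 2), 1)),
               class = "tscmr_input_error")
})

test_that("Cochran's Q measures weighted heterogeneity about the IVW
           estimate", {
  # homogeneous ratios: Q = 0, p = 1
  rs <- ratio_input(c(0.1, 0.2, 0.4), 0.01, 2 * c(0.1, 0.2, 0.4),
                    0.02 * c(1, 2, 4))
  q <- cochran_q(rs)
  expect_equal(q$Q, 0, tolerance = 1e-20)
  expect_equal(q$p, 1)
  # hand example: ratios 0 and 2 with unit weights
  rs2 <- ratio_input(c(1, 1), 0.01, c(0, 2), 1)
  q2 <- cochran_q(rs2)
  expect_equal(q2$Q, 2)
  expect_equal(q2$df, 1L)
  # chi-square tail probability against a numerical-integration oracle
  oracle_p <- integrate(function(x) dchisq(x, 1), 2, Inf,
                        rel.tol = 1e-12)$value
  expect_equal(q2$p, oracle_p, tolerance = 1e-8)
})

test_that("the F-statistic is the squared instrument z-score", {
  expect_equal(f_statistic(0.1, 0.05), 4)
  expect_equal(f_statistic(0, 0.05), 0)
  # cross-check with the p-value route used for instrument selection
  b <- 0.07; se <- 0.02
  f <- f_statistic(b, se)
  expect_equal(2 * pnorm(-sqrt(f)), 2 * pnorm(-abs(b / se)))
  expect_error(f_statistic(0.1, 0), class = "tscmr_input_error")
})

test_that("pooled estimators are equivariant under outcome negation and
           IVW stays inside the ratio range", {
  for (seed in 1:4) {
    rs <- random_ratios(8, seed)
    neg <- rs; neg$b_gy <- -neg$b_gy
    expect_equal(mr_ivw(neg)$beta, -mr_ivw(rs)$beta)
    e1 <- mr_egger(rs); e2 <- mr_egger(neg)
    expect_equal(e2$beta, -e1$beta)
    expect_equal(e2$intercept, -e1$intercept)
    expect_equal(mr_weighted_median(neg, n_boot = 50, seed = 1)$beta,
                 -mr_weighted_median(rs, n_boot = 50, seed = 1)$beta)
    expect_equal(mr_weighted_mode(neg, n_boot = 50, seed = 1)$beta,
                 -mr_weighted_mode(rs, n_boot = 50, seed = 1)$beta,
                 tolerance = 1e-6)
    ratios <- rs$b_gy / rs$b_gx
    ivw <- mr_ivw(rs)$beta
    expect_gte(ivw, min(ratios)); expect_lte(ivw, max(ratios))
  }
})

test_that("bootstrap SEs are bit-reproducible and mr_fit applies the
           heterogeneity switching rule", {
  rs <- random_ratios(6, 42)
  m1 <- mr_weighted_median(rs, n_boot = 300, seed = 5)
  m2 <- mr_weighted_median(rs, n_boot = 300, seed = 5)
  expect_identical(m1$se, m2$se)
  k1 <- mr_weighted_mode(rs, n_boot = 300, seed = 5)
  k2 <- mr_weighted_mode(rs, n_boot = 300, seed = 5)
  expect_identical(k1$se, k2$se)

  # homogeneous data keep IVW primary
  fit_hom <- suppressWarnings(          # exact fit: summary.lm grumbles
    mr_fit(ratio_input(c(0.1, 0.2, 0.4), 0.01,
                       2 * c(0.1, 0.2, 0.4), 0.02 * c(1, 2, 4)),
           n_boot = 50, seed = 1))
  expect_equal(fit_hom$primary, "ivw")
  # gross heterogeneity promotes the weighted median
  fit_het <- mr_fit(ratio_input(c(0.10, 0.11, 0.12, 0.10), 0.01,
                                c(0.10, 0.13, 0.12, 0.90), 0.01),
                    n_boot = 50, seed = 1)
  expect_lt(fit_het$Q$p, 0.05)
  expect_equal(fit_het$primary, "weighted_median")
  # a single variant degrades to the Wald ratio
  fit1 <- mr_fit(ratio_input(0.1, 0.01, 0.2, 0.05))
  expect_equal(fit1$primary, "wald")
  expect_equal(coef(fit1), c(beta = 2))
})
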