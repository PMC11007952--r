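# Soft-bound calibration densities, the birth-death node-age prior, the
# four rate processes, and the branch observation model.

test_that("soft-bound densities place the stated mass outside the bounds", {
  two <- list(min_age = 1030, max_age = 1060, tail_low = 0.025,
              tail_high = 0.025)
  f <- function(x) exp(calibration_logdensity(x, two))
  expect_equal(stats::integrate(f, 1060, Inf, rel.tol = 1e-10)$value,
               0.025, tolerance = 1e-6)
  expect_equal(stats::integrate(f, -Inf, 1030, rel.tol = 1e-10)$value,
               0.025, tolerance = 1e-6)
  core <- stats::integrate(f, 1030, 1060, rel.tol = 1e-10)$value
  expect_equal(core, 0.95, tolerance = 1e-6)
  # density continuous at the bounds
  eps <- 1e-9
  expect_equal(f(1030 - eps), f(1030 + eps), tolerance = 1e-4)
  expect_equal(f(1060 + eps), f(1060 - eps), tolerance = 1e-4)

  mo <- list(min_age = 350, max_age = NA, tail_low = 0.05, tail_high = 0)
  g <- function(x) exp(calibration_logdensity(x, mo))
  expect_equal(stats::integrate(g, -Inf, 350, rel.tol = 1e-10)$value,
               0.05, tolerance = 1e-6)
  expect_equal(stats::integrate(g, -Inf, Inf, rel.tol = 1e-10)$value,
               1, tolerance = 1e-6)
})

test_that("zero tail masses recover hard bounds", {
  hard <- list(min_age = 100, max_age = 120, tail_low = 0, tail_high = 0)
  expect_identical(calibration_logdensity(99, hard), -Inf)
  expect_identical(calibration_logdensity(121, hard), -Inf)
  expect_equal(exp(calibration_logdensity(110, hard)), 1 / 20)
})

test_that("birth-death node-age density matches closed forms", {
  # critical case lambda = mu: kernel 1/(1 + lambda t)^2, normalized
  lam <- 0.05; t1 <- 40
  direct <- function(t) (lam / (1 + lam * t)^2) /
    (lam * t1 / (1 + lam * t1))
  ts <- seq(0.5, 39.5, by = 0.5)
  expect_equal(bd_age_density(ts, t1, lam, lam), direct(ts),
               tolerance = 1e-9)
  # general case integrates to 1 and the quantile function inverts the CDF
  for (pars in list(c(0.1, 0.05), c(0.08, 0), c(0.2, 0.15))) {
    f <- function(t) bd_age_density(t, t1, pars[1L], pars[2L])
    expect_equal(stats::integrate(f, 0, t1, rel.tol = 1e-10)$value, 1,
                 tolerance = 1e-7)
    for (p in c(0.1, 0.5, 0.9)) {
      q <- bd_age_quantile(p, t1, pars[1L], pars[2L])
      expect_equal(stats::integrate(f, 0, q, rel.tol = 1e-10)$value, p,
                   tolerance = 1e-7)
    }
  }
  # log-density finite across a grid (sanity on the log form)
  lp <- bd_age_density(ts, t1, 0.1, 0.05, log = TRUE)
  expect_true(all(is.finite(lp)))
})

test_that("rate processes validate parameters and factorize as stated", {
  expect_error(rate_process("CIR", nu = 0.001, sigma2 = 1, theta = 1),
               "stationarity")
  expect_error(rate_process("CIR", nu = 0.001, sigma2 = 1e-4),
               "theta")
  tr <- rand_time_tree(6, seed = 2)
  dur <- tr$edge.length
  p <- rate_process("UGAM", nu = 0.002, sigma2 = 1e-6)
  r <- sim_rates(tr, p, seed = 3)
  # UGAM joint density equals the product of per-branch marginals
  joint <- rate_prior_logdensity(tr, r, dur, p)
  marg <- sum(stats::dgamma(r, shape = 0.002^2 / 1e-6,
                            rate = 0.002 / 1e-6, log = TRUE))
  expect_equal(joint, marg, tolerance = 1e-10)
})

test_that("autocorrelated processes concentrate on the parent rate as
           sigma2 vanishes", {
  tr <- rand_time_tree(5, seed = 6)
  dur <- tr$edge.length
  nu <- 0.002
  equal_r <- rep(nu, nrow(tr$edge))
  off_r <- equal_r * stats::runif(length(equal_r), 0.9, 1.1)
  for (mk in list(function(s2) rate_process("LN", nu, s2),
                  function(s2) rate_process("CIR", nu, s2, theta = 1))) {
    d_small <- rate_prior_logdensity(tr, equal_r, dur, mk(1e-6)) -
      rate_prior_logdensity(tr, off_r, dur, mk(1e-6))
    d_large <- rate_prior_logdensity(tr, equal_r, dur, mk(1e-3)) -
      rate_prior_logdensity(tr, off_r, dur, mk(1e-3))
    expect_gt(d_small, d_large)   # shrinking sigma2 favours the strict clock
    expect_gt(d_small, 0)
  }
})

test_that("CIR forward simulation reaches its stationary gamma law", {
  nu <- 0.002; s2 <- 2e-6; th <- 0.8
  shape <- 2 * th * nu / s2; rate <- 2 * th / s2
  n <- 1e5
  set.seed(77)
  r <- nu
  dt <- 0.5
  cc <- 2 * th / (s2 * (1 - exp(-th * dt)))
  df <- 4 * th * nu / s2
  out <- numeric(n)
  for (i in seq_len(n)) {
    r <- stats::rchisq(1, df = df, ncp = 2 * cc * r * exp(-th * dt)) /
      (2 * cc)
    out[i] <- r
  }
  out <- out[-(1:1000)]
  m_exp <- shape / rate
  v_exp <- shape / rate^2
  # 3 SE bands with an effective-sample-size correction for autocorrelation
  ess <- unname(coda::effectiveSize(out))
  expect_lt(abs(mean(out) - m_exp), 3 * stats::sd(out) / sqrt(ess))
  expect_lt(abs(stats::var(out) - v_exp) / v_exp, 0.15)
})

test_that("the branch observation model behaves analytically", {
  # rate 0.001/My, duration 100 My, 1000 sites -> Poisson mean 100
  bd <- branch_data("poisson", counts = 100L, sites = 1000L)
  expect_equal(branch_loglik(0.001, 100, bd),
               stats::dpois(100, 100, log = TRUE))
  # Poisson MLE of rate*duration equals count/sites
  bd2 <- branch_data("poisson", counts = 73L, sites = 1000L)
  opt <- stats::optimize(function(m) -branch_loglik(m, 1, bd2),
                         c(1e-4, 1), tol = 1e-12)
  expect_equal(opt$minimum, 73 / 1000, tolerance = 1e-6)
  # normal mode with tiny SE pins rate*duration at the observed length
  bdn <- branch_data("normal", lengths = 0.05, se = 1e-9)
  optn <- stats::optimize(function(m) -branch_loglik(m, 1, bdn),
                          c(0.049, 0.051), tol = 1e-12)
  expect_equal(optn$minimum, 0.05, tolerance = 1e-7)
  # zero-duration branch with a nonzero count is impossible
  bd3 <- branch_data("poisson", counts = c(0L, 5L), sites = 100L)
  expect_equal(branch_loglik(c(0.1, 0.1), c(1, 0), bd3), -Inf)
  # default SE floor
  bn <- branch_data("normal", lengths = c(0, 0.04), sites = 1000L)
  expect_equal(bn$se, c(1e-6, sqrt(0.04 / 1000)))
})
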