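test_that("cline value matches the sigmoid closed form", {
  m <- cline_model("I_fixed_none", c = 600, w = 150)
  expect_equal(cline_value(m, 600), 0.5)
  expect_equal(cline_value(m, 600 + 75), (1 + tanh(1)) / 2)
  expect_equal(cline_value(m, 600 + 75), 0.88080, tolerance = 1e-5)
  # odd symmetry: p(c+d) + p(c-d) = pmin + pmax
  d <- c(3, 40, 200, 1000)
  expect_equal(cline_value(m, 600 + d) + cline_value(m, 600 - d),
               rep(1, length(d)))
  m2 <- cline_model("II_free_none", c = 600, w = 150, pmin = 0.1, pmax = 0.7)
  expect_equal(cline_value(m2, 600 + d) + cline_value(m2, 600 - d),
               rep(0.8, length(d)))
  expect_error(cline_model("I_fixed_none", c = 0, w = -1), "width")
})

test_that("exponential tails are value-continuous and slope-continuous at tau = 1", {
  m <- cline_model("III_free_both", c = 500, w = 120, pmin = 0.05, pmax = 0.9,
                   deltaL = 80, tauL = 0.6, deltaR = 50, tauR = 1)
  xL <- 500 - 80
  xR <- 500 + 50
  eps <- 1e-7
  expect_lt(abs(cline_value(m, xL - eps) - cline_value(m, xL + eps)), 1e-6)
  expect_lt(abs(cline_value(m, xR - eps) - cline_value(m, xR + eps)), 1e-6)
  # slope continuity at the right junction where tau = 1
  slope_out <- (cline_value(m, xR + 2 * eps) - cline_value(m, xR + eps)) / eps
  slope_in <- (cline_value(m, xR - eps) - cline_value(m, xR - 2 * eps)) / eps
  expect_equal(slope_out, slope_in, tolerance = 1e-3)
})

test_that("cline value is monotone for random parameters including tails", {
  set.seed(31)
  grid <- seq(-500, 1500, length.out = 400)
  for (i in 1:25) {
    pm <- sort(runif(2))
    m <- cline_model("III_free_both", c = runif(1, 200, 800),
                     w = runif(1, 10, 400), pmin = pm[1], pmax = pm[2],
                     deltaL = runif(1, 0, 300), tauL = runif(1),
                     deltaR = runif(1, 0, 300), tauR = runif(1))
    p <- cline_value(m, grid)
    expect_true(all(diff(p) >= -1e-12))
    expect_true(all(p >= pm[1] - 1e-12 & p <= pm[2] + 1e-12))
  }
})

test_that("log-likelihoods match closed forms", {
  m <- cline_model("I_fixed_none", c = 100, w = 50)
  expect_equal(cline_log_likelihood(m, 100, 1, "bernoulli"), log(0.5))
  # gaussian with y exactly on the cline: logL = n log(1/(sigma sqrt(2 pi)))
  x <- seq(0, 200, by = 10)
  y <- cline_value(m, x)
  expect_equal(cline_log_likelihood(m, x, y, "gaussian", sigma = 0.1),
               length(x) * log(1 / (0.1 * sqrt(2 * pi))))
  expect_error(cline_log_likelihood(m, numeric(0), numeric(0)), "non-empty")
  expect_error(cline_log_likelihood(m, 1, 0.5, "bernoulli"), "\\{0, 1\\}")
})

test_that("step-like fits drive the bernoulli log-likelihood towards zero", {
  x <- c(seq(0, 450, length.out = 25), seq(550, 1000, length.out = 25))
  y <- rep(c(0, 1), each = 25)
  ll_wide <- cline_log_likelihood(cline_model("I_fixed_none", c = 500, w = 300), x, y)
  ll_sharp <- cline_log_likelihood(cline_model("I_fixed_none", c = 500, w = 1), x, y)
  expect_gt(ll_sharp, ll_wide)
  expect_gt(ll_sharp, -1e-6)
})

test_that("bernoulli likelihood pools to the binomial form at shared positions", {
  m <- cline_model("I_fixed_none", c = 300, w = 100)
  x <- rep(c(250, 350), c(6, 4))
  y <- c(rep(1, 2), rep(0, 4), rep(1, 3), 0)
  p <- cline_value(m, c(250, 350))
  binom <- 2 * log(p[1]) + 4 * log(1 - p[1]) + 3 * log(p[2]) + log(1 - p[2])
  expect_equal(cline_log_likelihood(m, x, y, "bernoulli"), binom)
})

test_that("AICc follows its closed form and limits", {
  expect_equal(aicc(-100, 2, 125), 204 + 12 / 122)
  expect_equal(aicc(-100, 2, 125), 204.0984, tolerance = 1e-4)
  expect_equal(aicc(-50, 0, 30), 100)
  # approaches plain AIC as n grows
  expect_equal(aicc(-100, 3, 1e9), 2 * 3 + 200, tolerance = 1e-6)
  expect_error(aicc(-10, 5, 6), "n > k")
})

test_that("MCMC fits are reproducible and respond to signal", {
  set.seed(71)
  x <- runif(120, 0, 1000)
  y <- rbinom(120, 1, cline_value(cline_model("I_fixed_none", c = 480, w = 120), x))
  f1 <- fit_cline(x, y, "I_fixed_none", iterations = 4000, seed = 3)
  f2 <- fit_cline(x, y, "I_fixed_none", iterations = 4000, seed = 3)
  expect_identical(f1$samples, f2$samples)
  expect_identical(f1$model$c, f2$model$c)
  # truth well inside the credible interval at this n
  expect_gt(f1$center_ci[2], 400)
  expect_lt(f1$center_ci[1], 560)
  expect_equal(f1$aicc, aicc(f1$logL_max, f1$k, f1$n))
  expect_equal(f1$width_inv_max_slope, f1$model$w / (f1$model$pmax - f1$model$pmin))
})

test_that("signal-free data leave the centre unidentified", {
  set.seed(72)
  x <- runif(60, 0, 1000)
  y <- rep(0, 60)
  f <- fit_cline(x, y, "II_free_none", iterations = 4000, seed = 4)
  # posterior for c roams over most of the prior (data) range
  expect_gt(diff(f$center_ci), 0.5 * diff(range(x)))
})

test_that("fit preconditions are enforced", {
  expect_error(fit_cline(rep(5, 20), rbinom(20, 1, 0.5), "I_fixed_none"),
               "span")
  expect_error(fit_cline(c(1, 2, 3), c(0, 1, 0), "I_fixed_none"),
               "at least 10")
})

test_that("model selection prefers parsimony and demands shared data", {
  set.seed(73)
  x <- runif(150, 0, 1000)
  y <- rbinom(150, 1, cline_value(cline_model("I_fixed_none", c = 500, w = 150), x))
  f1 <- fit_cline(x, y, "I_fixed_none", iterations = 4000, seed = 5)
  f2 <- fit_cline(x, y, "II_free_none", iterations = 4000, seed = 5)
  sel <- select_model(list(f1, f2))
  expect_equal(nrow(sel$table), 2)
  expect_equal(min(sel$table$delta_aicc), 0)
  # single fit passes through unchanged
  expect_identical(select_model(list(f1))$best, f1)
  # ties break towards fewer parameters
  f2_tied <- f2
  f2_tied$aicc <- f1$aicc
  expect_equal(select_model(list(f2_tied, f1))$best$k, f1$k)
  other <- fit_cline(x[1:100], y[1:100], "I_fixed_none",
                     iterations = 2000, seed = 6)
  expect_error(select_model(list(f1, other)), "identical data")
})

test_that("a fit compared against itself shows zero shift", {
  set.seed(74)
  x <- runif(100, 0, 1000)
  y <- rbinom(100, 1, cline_value(cline_model("I_fixed_none", c = 500, w = 150), x))
  f <- fit_cline(x, y, "I_fixed_none", iterations = 3000, seed = 7)
  cmp <- compare_clines(f, f)
  expect_equal(cmp$center_shift_km, 0)
  expect_equal(cmp$width_diff_km, 0)
  expect_true(all(cmp$shift_posterior == 0))
})
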