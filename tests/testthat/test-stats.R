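test_that("peak detection handles monotone, constant and rise-and-fall traces", {
  tt <- seq(0, 10, by = 0.1)
  mono <- list(time = tt, open = exp(-tt))
  expect_equal(peak_open(mono), list(value = 1, time = 0))
  const <- list(time = tt, open = rep(0.4, length(tt)))
  expect_equal(peak_open(const), list(value = 0.4, time = 0))
  expect_warning(pk0 <- peak_open(list(time = tt, open = rep(0, length(tt)))),
                 "degenerate")
  expect_equal(pk0$value, 0)
  # 2-state activation-like rise and fall vs dense-grid oracle
  a <- 2; b <- 0.4; k <- 1.1
  f <- function(t) (exp(-b * t) - exp(-a * t)) * k
  coarse <- list(time = tt, open = f(tt))
  dense_t <- seq(0, 10, by = 1e-4)
  oracle <- max(f(dense_t))
  pk <- peak_open(coarse, refine = f)
  expect_equal(pk$value, oracle, tolerance = 1e-8)
})

test_that("half-decay time matches the exponential closed form", {
  tt <- seq(0, 20, by = 0.05)
  k <- 0.6931
  tr <- list(time = tt, open = exp(-k * tt))
  expect_equal(time_to_half_decay(tr, refine = function(t) exp(-k * t)),
               log(2) / k, tolerance = 1e-8)
  expect_equal(time_to_half_decay(tr), log(2) / k, tolerance = 1e-3)
  # never decays below half -> undefined
  flat <- list(time = tt, open = rep(1, length(tt)))
  expect_error(time_to_half_decay(flat), "undefined")
})

test_that("half-decay of a full model trace matches a dense-grid oracle", {
  Q <- build_generator(nav_scheme(), eval_rates(true_params(), -20))
  p0 <- equilibrium_distribution(
    build_generator(nav_scheme(), eval_rates(true_params(), -120)))
  prop <- make_propagator(Q)
  f <- function(t) as.numeric(prop(p0, t)["O", 1])
  tr <- propagate(Q, p0, 25, sample_dt = 0.05)
  got <- time_to_half_decay(tr, refine = f)
  # linear interpolation on a very dense grid
  dt <- 1e-4
  dense <- propagate(Q, p0, 25, sample_dt = dt)
  y <- dense$p["O", ]
  ipk <- which.max(y)
  half <- y[ipk] / 2
  j <- which(seq_along(y) > ipk & y <= half)[1]
  tcross <- dense$time[j - 1] +
    (half - y[j - 1]) * dt / (y[j] - y[j - 1])
  expect_equal(got, tcross - dense$time[ipk], tolerance = 1e-4)
})

test_that("half-decay time is invariant to uniform trace rescaling", {
  tt <- seq(0, 30, by = 0.05)
  y <- (exp(-0.2 * tt) - exp(-3 * tt))
  t1 <- time_to_half_decay(list(time = tt, open = y))
  t2 <- time_to_half_decay(list(time = tt, open = 17 * y))
  expect_equal(t1, t2, tolerance = 1e-12)
})

test_that("exponential fits recover generating coefficients on clean data", {
  tt <- seq(0, 500, length.out = 200)
  y2 <- 1 - 0.7 * exp(-tt / 5) - 0.3 * exp(-tt / 50)
  fit <- fit_exponential(tt, y2, n_components = 2)
  expect_equal(fit$C1, 1, tolerance = 1e-4)
  expect_equal(fit$A1, 0.7, tolerance = 1e-4)
  expect_equal(fit$tau1, 5, tolerance = 1e-4)
  expect_equal(fit$A2, 0.3, tolerance = 1e-4)
  expect_equal(fit$tau2, 50, tolerance = 1e-4)
  expect_lte(fit$tau1, fit$tau2)
  expect_lt(fit$residual_norm, 1e-8)
  y1 <- 0.9 - 0.5 * exp(-tt / 12)
  fit1 <- fit_exponential(tt, y1, n_components = 1)
  expect_equal(fit1$tau1, 12, tolerance = 1e-6)
  # constant data: zero-amplitude solution with zero residual
  fitc <- fit_exponential(tt, rep(0.8, 200), n_components = 1)
  expect_equal(fitc$A1, 0)
  expect_equal(fitc$residual_norm, 0)
})

test_that("recovery-rate regression inverts the generating voltage dependence", {
  a <- 3.7933e-7; b <- 7.7
  V <- c(-80, -100, -120)
  tau1 <- 1 / (a * exp(-V / b))
  est <- rate_from_recovery(tau1, V)
  expect_equal(est$a, a, tolerance = 1e-10)
  expect_equal(est$b, b, tolerance = 1e-10)
  # two points determine the two coefficients exactly
  est2 <- rate_from_recovery(tau1[1:2], V[1:2])
  expect_equal(est2$b, b, tolerance = 1e-10)
  # no voltage dependence -> infinite b with a warning
  expect_warning(flat <- rate_from_recovery(c(10, 10), c(-80, -120)), "slope")
  expect_true(is.infinite(flat$b))
  expect_error(rate_from_recovery(c(1, 2), c(-80, -80)), "degenerate")
})

test_that("mean open time is the reciprocal total exit rate", {
  # single exit path k -> 1/k; 0.1 + 0.05 + 0.05 -> 5 ms
  expect_equal(1 / (0.1 + 0.05 + 0.05), 5)
  p <- unclass(true_params())
  r <- eval_rates(true_params(), -30)
  expect_equal(mean_open_time(true_params(), -30),
               1 / (r[["b13"]] + r[["a2"]] + r[["ax"]]))
  # monotone decreasing in any exit rate
  p2 <- p; p2["ax"] <- p["ax"] * 2
  expect_lt(mean_open_time(rate_params(p2), -30),
            mean_open_time(true_params(), -30))
  p3 <- p; p3["b13"] <- p["b13"] * 3
  expect_lt(mean_open_time(rate_params(p3), -30),
            mean_open_time(true_params(), -30))
})
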