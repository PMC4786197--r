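test_that("bounded simplex finds interior and boundary optima", {
  r <- minimize_bounded(function(x) (x - 3)^2, 1,
                        optimizer_options(tol_cost = 1e-8, tol_par = 1e-6,
                                          lower = 0, upper = 10,
                                          max_iter = 500))
  expect_equal(unname(r$par), 3, tolerance = 1e-3)
  expect_true(r$converged)
  r2 <- minimize_bounded(function(x) x, 5,
                         optimizer_options(tol_cost = 1e-9, tol_par = 1e-7,
                                           lower = 1, upper = 10,
                                           max_iter = 500))
  expect_equal(unname(r2$par), 1, tolerance = 1e-6)
})

test_that("the simplex minimizes Rosenbrock to the reference optimum", {
  rb <- function(x) 100 * (x[2] - x[1]^2)^2 + (1 - x[1])^2
  r <- minimize_bounded(rb, c(-1.2, 1),
                        optimizer_options(tol_cost = 1e-10, tol_par = 1e-8,
                                          lower = -5, upper = 5,
                                          max_iter = 2000))
  expect_equal(unname(r$par), c(1, 1), tolerance = 1e-2)
  # cross-check against an independent Nelder-Mead implementation
  ref <- stats::optim(c(-1.2, 1), rb, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  expect_equal(unname(r$value), ref$value, tolerance = 1e-4)
})

test_that("best-so-far cost never increases and bad starts are rejected", {
  rb <- function(x) 100 * (x[2] - x[1]^2)^2 + (1 - x[1])^2
  r <- minimize_bounded(rb, c(-1.2, 1),
                        optimizer_options(tol_cost = 1e-10, tol_par = 1e-8,
                                          lower = -5, upper = 5,
                                          max_iter = 500))
  expect_true(all(diff(r$history$cost) <= 1e-14))
  expect_error(minimize_bounded(function(x) Inf, 1, optimizer_options()),
               "invalid start")
})

test_that("parameter perturbation is bounded, centered and reproducible", {
  p <- true_params()
  expect_equal(perturb_parameters(p, 0), p)
  q1 <- perturb_parameters(p, 25, seed = 9)
  q2 <- perturb_parameters(p, 25, seed = 9)
  expect_identical(q1, q2)
  fac <- unclass(q1) / unclass(p)
  expect_true(all(fac >= 0.75 & fac <= 1.25))
  expect_error(perturb_parameters(p, 100), "positive|100")
  # uniform symmetry: the mean factor over many draws is 1
  set.seed(123)
  fac <- stats::runif(1e5, 0.75, 1.25)
  se <- stats::sd(fac) / sqrt(length(fac))
  expect_lt(abs(mean(fac) - 1), 3 * se)
})

test_that("perturbation restarts can escape a shallow well", {
  # shallow well at 1, deeper well at 1.15, barrier at 1.07
  f <- function(x) {
    if (x <= 1.07) (x - 1)^2 else (x - 1.15)^2 - 0.0015
  }
  opts <- optimizer_options(tol_cost = 1e-10, tol_par = 1e-8,
                            lower = 0, upper = 2, max_iter = 300)
  stuck <- minimize_bounded(f, 0.95, opts)
  expect_equal(unname(stuck$par), 1, tolerance = 1e-3)
  escaped <- FALSE
  for (s in 1:20) {
    r <- restart_perturbed(f, stuck, pct = 10, seed = s, options = opts)
    if (r$value < -0.001) { escaped <- TRUE; break }
  }
  expect_true(escaped)
  # pct = 0 restarts exactly at the previous optimum
  r0 <- restart_perturbed(f, stuck, pct = 0, seed = 1, options = opts)
  expect_equal(attr(r0, "start"), stuck$par)
  # a fixed seed reproduces the perturbed start
  ra <- restart_perturbed(f, stuck, pct = 10, seed = 4, options = opts)
  rb2 <- restart_perturbed(f, stuck, pct = 10, seed = 4, options = opts)
  expect_identical(attr(ra, "start"), attr(rb2, "start"))
})

test_that("factorial scheduling enumerates every ordering", {
  expect_equal(nrow(navfit:::permutations(4)), 24)
  expect_equal(nrow(unique(navfit:::permutations(4))), 24)
  expect_equal(nrow(navfit:::permutations(1)), 1)
})

test_that("sequential scheduling runs cumulative blocks and continues the best", {
  # cheap two-group problem built from the analytic mean-open-time readout
  p <- true_params()
  prs <- list(
    MOT1 = protocol("MOT1", "mot", sweep = -30),
    MOT2 = protocol("MOT2", "mot", sweep = c(-40, -20))
  )
  ds <- generate_datasets(fixture_spec(p, prs))
  groups <- list(g1 = ds["MOT1"], g2 = ds["MOT2"])
  start <- perturb_parameters(p, 10, seed = 2)
  res <- sequential_schedule(groups, prs, start,
                             options = optimizer_options(max_iter = 50),
                             block_iter = 10, orderings = "factorial")
  expect_length(res$orderings, 2)      # 2! orderings
  expect_true(all(vapply(res$orderings, function(o) is.finite(o$cost),
                         logical(1))))
  expect_lte(res$best$value,
             min(vapply(res$orderings, function(o) o$cost, numeric(1))))
  # one group degenerates to a plain bounded search
  res1 <- sequential_schedule(groups["g1"], prs, start,
                              options = optimizer_options(max_iter = 30))
  expect_true(is.finite(res1$best$value))
})
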