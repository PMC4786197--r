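test_that("Henderson-Hasselbalch charged fraction behaves as expected", {
  expect_equal(charged_fraction(7.4, 7.4), 0.5)
  expect_equal(charged_fraction(9.3, 7.4), 1 / (1 + 10^(7.4 - 9.3)))
  expect_gt(charged_fraction(9.3, 0.1), 1 - 1e-9)   # very low pH limit
  # charged + neutral fractions partition exactly
  f <- charged_fraction(9.3, 7.4)
  expect_identical(f + (1 - f), 1)
})

test_that("Eyring Kd has the right anchors and monotonicity", {
  expect_equal(eyring_kd(11.2e-6, 0, 0.7, 295), 11.2e-6)
  expect_equal(eyring_kd(5e-6, -80, 0, 310), 5e-6)   # d = 0: flat in V
  V <- seq(-120, 40, by = 20)
  kd <- eyring_kd(11.2e-6, V, 0.7, 295)
  expect_true(all(diff(kd) < 0))  # hyperpolarization weakens affinity
})

test_that("binding rates are diffusion-limited arithmetic", {
  br <- binding_rates(10e-6, 5500, 11.2e-6)
  expect_equal(br$kon, 0.055)
  expect_equal(br$koff, 0.0616)
  br2 <- binding_rates(11.2e-6, 5500, 11.2e-6)
  expect_equal(br2$kon, br2$koff)
})

test_that("the extended scheme satisfies detailed balance after closure", {
  p <- true_params()
  spec <- flecainide_spec(10e-6)
  sc <- flecainide_scalars(spec)
  ext <- build_drug_scheme(nav_scheme(), eval_rates(p, -40), spec, sc, -40)
  expect_equal(length(ext$scheme$states), 25)
  res <- cycle_residuals(ext$scheme, ext$rates)
  expect_lt(max(abs(res)), 1e-10)
  expect_lt(max(abs(colSums(ext$Q))), 1e-9)
  # closure is independent of concentration (binding cycles cross the
  # interface an even number of times)
  ext2 <- build_drug_scheme(nav_scheme(), eval_rates(p, -40),
                            flecainide_spec(100e-6), sc, -40)
  mr <- grep("\\.mr$", names(ext$rates), value = TRUE)
  expect_equal(ext$rates[mr], ext2$rates[mr], tolerance = 1e-12)
})

test_that("zero concentration leaves drug-bound states unoccupied", {
  p <- true_params()
  ext0 <- build_drug_scheme(nav_scheme(), eval_rates(p, -100),
                            flecainide_spec(0), flecainide_scalars(), -100)
  eq <- equilibrium_distribution(ext0$Q)
  bound <- setdiff(names(eq), nav_scheme()$states)
  expect_equal(sum(eq[bound]), 0)
  tr <- propagate(ext0$Q, eq, 100, sample_dt = 10)
  expect_lt(max(abs(tr$p[bound, ])), 1e-12)
})

test_that("unit scalars with very weak affinities produce negligible block", {
  p <- true_params()
  spec <- flecainide_spec(10e-6)
  spec$kd0_charged_open <- 100    # 100 M: essentially no binding
  spec$kd_neutral_open <- 100
  spec$kd_neutral_closed <- 100
  spec$kd_neutral_inactivated <- 100
  sc <- drug_scalars(
    charged = c(ax1 = 1, bx1 = 1, a13c = 1, a22 = 1, b33 = 1, a33 = 1,
                a44 = 1, b44 = 1),
    neutral = c(ax2 = 1, a13n = 1, a_22 = 1, b_33 = 1, a_44 = 1, b_44 = 1,
                ki_on = spec$diffusion,
                ki_off = 100 * spec$diffusion)  # Kd 100 M for that row too
  )
  m <- drug_model(p, spec, sc)
  pr <- drug_protocols(10e-6)$UDB
  pr$sweep <- 10e-6
  y <- run_protocol(m, pr)$readouts$y
  # comparison: the same train with zero drug (the sweep axis is the
  # concentration, so a 0 sweep value is the drug-free limit)
  pr0 <- pr; pr0$sweep <- 0
  y0 <- run_protocol(m, pr0)$readouts$y
  expect_equal(y, y0, tolerance = 1e-5)
})

test_that("drug file parsing round-trips the bundled flecainide constants", {
  f <- system.file("extdata", "flecainide.yaml", package = "navfit")
  dg <- read_drug(f)
  expect_s3_class(dg$spec, "drug_spec")
  expect_equal(dg$spec$pKa, 9.3)
  expect_equal(dg$spec$kd0_charged_open, 11.2e-6)
  expect_equal(dg$spec$diffusion, 5500)
  expect_equal(unname(dg$scalars$charged["a44"]), 2.5183)
})

test_that("misallocated free scalars are rejected as over-constrained", {
  # assigning a free value to a reversibility-constrained direction must
  # raise a reversibility error, not silently break detailed balance
  p <- true_params()
  em <- navfit:::drug_edge_map()
  em$neutral$rev_scalar[em$neutral$from == "NC1" & em$neutral$to == "NO"] <- "a_44"
  expect_error(
    build_drug_scheme(nav_scheme(), eval_rates(p, -40), flecainide_spec(1e-6),
                      flecainide_scalars(), -40, edge_map = em),
    "over-constrained")
})
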