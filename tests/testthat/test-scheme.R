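test_that("the sodium channel scheme has the expected topology", {
  sch <- nav_scheme()
  expect_setequal(sch$states,
                  c("IC3", "IC2", "IF", "IS", "C3", "C2", "C1", "O"))
  expect_equal(nrow(sch$edges), 10)
  expect_identical(sch$conducting, "O")
  # hand-enumerated reversible edge list
  want <- c("IC3|IC2", "IC2|IF", "C3|C2", "C2|C1", "C1|O",
            "IC3|C3", "IC2|C2", "IF|C1", "O|IF", "O|IS")
  got <- paste(sch$edges$from, sch$edges$to, sep = "|")
  norm <- function(k) vapply(strsplit(k, "|", fixed = TRUE),
                             function(x) paste(sort(x), collapse = "|"), "")
  expect_setequal(norm(got), norm(want))
})

test_that("scheme validation rejects malformed input", {
  expect_error(channel_scheme(c("A", "A"),
                              data.frame(from = "A", to = "A",
                                         fwd = "f", rev = "r")),
               "duplicate state")
  expect_error(channel_scheme(c("A", "B"),
                              data.frame(from = "A", to = "C",
                                         fwd = "f", rev = "r")),
               "unknown state")
  expect_error(channel_scheme(c("A", "B"),
                              data.frame(from = c("A", "B"), to = c("B", "A"),
                                         fwd = c("f", "g"),
                                         rev = c("r", "s"))),
               "duplicate edge")
})

test_that("generator assembly matches the toy closed form and conserves probability", {
  toy <- channel_scheme(c("S1", "S2"),
                        data.frame(from = "S1", to = "S2",
                                   fwd = "a", rev = "b"))
  Q <- build_generator(toy, c(a = 3, b = 1))
  expect_equal(unname(Q), matrix(c(-3, 3, 1, -1), 2, 2))
  sch <- nav_scheme()
  for (V in c(-140, -80, -20, 20, 60)) {
    Qv <- build_generator(sch, eval_rates(true_params(), V))
    expect_lt(max(abs(colSums(Qv))), 1e-12 * max(1, max(abs(Qv))))
    off <- Qv; diag(off) <- 0
    expect_true(all(off >= 0))
  }
  Qv <- build_generator(sch, eval_rates(true_params(), -30))
  expect_equal(sum(Qv != 0 & row(Qv) != col(Qv)), 20) # 2 x 10 reversible edges
})

test_that("unresolved rate labels are reported", {
  sch <- nav_scheme()
  r <- eval_rates(true_params(), -30)
  r2 <- unclass(r)[setdiff(names(r), "ax")]
  expect_error(build_generator(sch, r2), "ax")
})

test_that("cycle residuals agree with a brute-force product oracle", {
  square <- channel_scheme(
    c("A", "B", "C", "D"),
    data.frame(from = c("A", "B", "C", "D"),
               to = c("B", "C", "D", "A"),
               fwd = c("f1", "f2", "f3", "f4"),
               rev = c("r1", "r2", "r3", "r4"))
  )
  set.seed(11)
  for (k in 1:10) {
    rates <- stats::setNames(stats::runif(8, 0.1, 5),
                             c(paste0("f", 1:4), paste0("r", 1:4)))
    res <- cycle_residuals(square, rates)
    expect_length(res, 1)
    brute <- log(prod(rates[paste0("f", 1:4)]) /
                   prod(rates[paste0("r", 1:4)]))
    expect_equal(abs(res[1]), abs(brute), tolerance = 1e-12)
  }
})

test_that("the constrained rate closes every drug-free cycle and doubling it breaks one", {
  sch <- nav_scheme()
  r <- eval_rates(true_params(), -40)
  expect_lt(max(abs(cycle_residuals(sch, r))), 1e-12)
  r2 <- unclass(r)
  r2["b2"] <- 2 * r2["b2"]
  res <- cycle_residuals(sch, r2)
  expect_equal(max(abs(res)), log(2), tolerance = 1e-10)
  expect_equal(sum(abs(res) > 1e-10), 1) # only the C1-O-IF loop is affected
})

test_that("cycle closure solves the single free rate of a square cycle", {
  square <- channel_scheme(
    c("A", "B", "C", "D"),
    data.frame(from = c("A", "B", "C", "D"),
               to = c("B", "C", "D", "A"),
               fwd = c("f1", "f2", "f3", "f4"),
               rev = c("r1", "r2", "r3", "r4"))
  )
  rates <- stats::setNames(rep(1, 8), c(paste0("f", 1:4), paste0("r", 1:4)))
  rates["r4"] <- NA
  out <- close_cycles(square, rates)
  expect_equal(unname(out["r4"]), 1)
  # forward product 6, assigned reverse product 2 -> dependent rate 3
  rates <- stats::setNames(c(1, 2, 3, 1, 1, 2, 1, NA),
                           c(paste0("f", 1:4), paste0("r", 1:4)))
  out <- close_cycles(square, rates)
  expect_equal(unname(out["r4"]), 3)
  # idempotent
  expect_equal(close_cycles(square, out), out)
  # over-constrained cycle is rejected
  bad <- stats::setNames(c(1, 1, 1, 1, 1, 1, 1, 2),
                         c(paste0("f", 1:4), paste0("r", 1:4)))
  expect_error(close_cycles(square, bad), "over-constrained")
})
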