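test_that("noise-free fixtures give zero cost at the generating truth", {
  ds <- drugfree_data()
  expect_equal(total_cost(attr(ds, "generating_params"), ds,
                          default_protocols())$total, 0)
})

test_that("fixture generation is deterministic by seed", {
  prs <- default_protocols()["MOT"]
  a <- generate_datasets(fixture_spec(true_params(), prs, noise_sd = 0.05,
                                      seed = 7))
  b <- generate_datasets(fixture_spec(true_params(), prs, noise_sd = 0.05,
                                      seed = 7))
  cc <- generate_datasets(fixture_spec(true_params(), prs, noise_sd = 0.05,
                                       seed = 8))
  expect_identical(a$MOT$y, b$MOT$y)
  expect_false(identical(a$MOT$y, cc$MOT$y))
})

test_that("the normalized cost of noisy fixtures at truth matches its chi-square expectation", {
  # 9-point availability with sd = 0.01: E[SSE/n] = sd^2
  sdn <- 0.01
  prs <- default_protocols()["SSA"]
  base <- generate_datasets(fixture_spec(true_params(), prs))  # noise-free
  y0 <- base$SSA$y
  n <- length(y0)
  reps <- 200
  costs <- numeric(reps)
  for (k in seq_len(reps)) {
    set.seed(k)
    yk <- y0 + stats::rnorm(n, 0, sdn)
    costs[k] <- protocol_cost(experiment_dataset("SSA", base$SSA$x, yk), y0)
  }
  # mean of costs ~ sd^2 with SE = sd^2 * sqrt(2 / (n * reps))
  se <- sdn^2 * sqrt(2 / (n * reps))
  expect_lt(abs(mean(costs) - sdn^2), 3 * se)
  # the generator itself draws from the same distribution
  one <- generate_datasets(fixture_spec(true_params(), prs, noise_sd = sdn,
                                        seed = 1))
  expect_equal(protocol_cost(one$SSA, y0) < 10 * sdn^2, TRUE)
})

test_that("dataset files round-trip exactly and malformed rows are located", {
  ds <- drugfree_data()[c("SSA", "MOT")]
  f <- tempfile(fileext = ".csv")
  write_dataset(ds, f)
  back <- read_dataset(f)
  expect_setequal(names(back), c("SSA", "MOT"))
  expect_equal(back$SSA$y, ds$SSA$y)
  expect_equal(back$SSA$x, ds$SSA$x)
  lines <- readLines(f)
  lines[7] <- paste0(lines[7], ",extra")
  f2 <- tempfile(fileext = ".csv")
  writeLines(lines, f2)
  expect_error(read_dataset(f2), "row 7")
})

test_that("parameter files round-trip and reject incomplete sets", {
  f <- tempfile(fileext = ".json")
  write_params(true_params(), f)
  expect_identical(unclass(read_params(f)), unclass(true_params()))
  x <- jsonlite::read_json(f, simplifyVector = TRUE)
  x$b12 <- NULL
  f2 <- tempfile(fileext = ".json")
  jsonlite::write_json(x, f2, auto_unbox = TRUE)
  expect_error(read_params(f2), "b12")
  x2 <- jsonlite::read_json(f, simplifyVector = TRUE)
  x2$mystery <- 1
  jsonlite::write_json(x2, f2, auto_unbox = TRUE)
  expect_error(read_params(f2), "mystery")
})

test_that("bundled assets load and reproduce the in-code defaults", {
  pf <- system.file("extdata", "default_params.json", package = "navfit")
  expect_identical(unclass(read_params(pf)), unclass(default_params()))
  yf <- system.file("extdata", "protocols.yaml", package = "navfit")
  prs <- read_protocols(yf)
  expect_setequal(names(prs),
                  c("SSA", "ACT", "RFI", "RUDB", "TAU50", "MOT"))
  df <- system.file("extdata", "drug_protocols.yaml", package = "navfit")
  dprs <- read_protocols(df)
  expect_setequal(names(dprs),
                  c("SSA_DRUG", "TB", "UDB", "RUDB_DRUG", "FDUDB"))
})
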