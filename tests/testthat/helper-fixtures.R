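# Shared fixtures, memoized so expensive simulations run once per suite.
.fix_env <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (!exists(name, envir = .fix_env, inherits = FALSE))
    assign(name, make(), envir = .fix_env)
  get(name, envir = .fix_env, inherits = FALSE)
}

true_params <- function() default_params()

drugfree_data <- function() {
  fixture("drugfree_data", function()
    generate_datasets(fixture_spec(true_params(), default_protocols())))
}

# A random positive parameter draw: the reference set scaled by independent
# uniform factors in [0.5, 2].
random_params <- function() {
  p <- unclass(true_params())
  rate_params(p * stats::runif(length(p), 0.5, 2))
}

random_drug_scalars <- function(spec = flecainide_spec()) {
  s <- flecainide_scalars(spec)
  drug_scalars(
    charged = s$charged * stats::runif(8, 0.5, 2),
    neutral = s$neutral * stats::runif(8, 0.5, 2)
  )
}

# Independent fine-step integration oracle for the master equation.
ode_oracle <- function(Q, p0, duration, n_out = 5) {
  times <- seq(0, duration, length.out = n_out)
  sol <- deSolve::ode(
    y = p0, times = times,
    func = function(t, y, parms) list(as.numeric(Q %*% y)),
    parms = NULL, method = "lsoda", rtol = 1e-10, atol = 1e-12
  )
  t(unname(sol[, -1, drop = FALSE]))
}
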