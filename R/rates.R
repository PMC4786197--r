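#' Free parameters of the drug-free sodium channel model
#'
#' Constructs and validates the 16 free scalar parameters behind the 11
#' independent voltage-dependent transition rates (the twelfth rate, `b2`,
#' is constrained by microscopic reversibility and is never a parameter).
#' All parameters must be strictly positive and finite. Units: `a11_v1` and
#' `b11_v1` are ms, `a11_v2`, `b11_v2`, `a3_v2`, `b3_v2`, `a2_v2` are mV,
#' `a3_v1`, `b3_v1`, `a2_v1` are ms^-1, and `a12`, `a13`, `b12`, `b13`,
#' `ax`, `bx` are dimensionless multipliers.
#'
#' @param ... Either a single named numeric vector/list, or the 16 named
#'   parameters individually.
#' @return A named numeric vector of class `rate_params`, in canonical order.
#' @seealso [eval_rates()], [default_params()]
#' @export
rate_params <- function(...) {
  dots <- list(...)
  x <- if (length(dots) == 1L && is.null(names(dots)) &&
           (is.numeric(dots[[1]]) || is.list(dots[[1]]))) {
    unlist(dots[[1]])
  } else {
    unlist(dots)
  }
  nm <- param_names()
  unknown <- setdiff(names(x), nm)
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(nm, names(x))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  x <- as.numeric(x[nm])
  names(x) <- nm
  if (any(!is.finite(x)) || any(x <= 0))
    stop("all rate parameters must be strictly positive and finite; offending: ",
         paste(nm[!is.finite(x) | x <= 0], collapse = ", "))
  structure(x, class = c("rate_params", "numeric"))
}

#' @rdname rate_params
#' @export
param_names <- function() {
  c("a11_v1", "a11_v2", "a12", "a13",
    "b11_v1", "b11_v2", "b12", "b13",
    "a3_v1", "a3_v2", "b3_v1", "b3_v2",
    "a2_v1", "a2_v2", "ax", "bx")
}

#' Default drug-free parameter set
#'
#' A reference parameter set giving physiological wild-type Nav1.5 kinetics:
#' steady-state availability midpoint near -72 mV, fast activation, mean open
#' time of ~0.3 ms at -30 mV, and double-exponential recovery from
#' inactivation at -100 mV (fast component ~6 ms, slow component several
#' hundred ms via the slow-inactivated state). The linked activation
#' multipliers `a12`, `a13`, `b12`, `b13` are 1 (equal to the principal
#' activation/deactivation rates), slow inactivation is `ax = 1/20` of open
#' inactivation and its recovery `bx = 1/45` of closed recovery. This set is
#' used as the generating truth in synthetic-data studies.
#'
#' @return A [rate_params()] vector.
#' @export
default_params <- function() {
  rate_params(
    a11_v1 = 0.1027, a11_v2 = 17.0, a12 = 1.0, a13 = 1.0,
    b11_v1 = 40.0, b11_v2 = 20.0, b12 = 1.0, b13 = 1.0,
    a3_v1 = 3.7933e-7, a3_v2 = 7.7, b3_v1 = 8.4e-3, b3_v2 = 100.0,
    a2_v1 = 9.178, a2_v2 = 29.68, ax = 0.05, bx = 1 / 45
  )
}

# exp with a cap so that extreme voltages visited during optimization yield
# large-but-finite rates instead of overflow.
exp_capped <- function(logx, what) {
  if (any(!is.finite(logx)))
    stop("rate evaluation failed for ", what, ": non-finite exponent")
  exp(pmin(logx, 700))
}

#' Evaluate the 12 voltage-dependent transition rates
#'
#' Evaluates all transition rates of the 8-state scheme at a membrane
#' potential `V` (mV):
#' \deqn{\alpha_{11} = 1/(a11\_v1\, e^{-V/a11\_v2}), \quad
#'       \beta_{11} = 1/(b11\_v1\, e^{V/b11\_v2})}
#' \deqn{\alpha_{12} = a12\,\alpha_{11},\ \alpha_{13} = a13\,\alpha_{11},\
#'       \beta_{12} = b12\,\beta_{11},\ \beta_{13} = b13\,\beta_{11}}
#' \deqn{\alpha_3 = a3\_v1\, e^{-V/a3\_v2}, \quad
#'       \beta_3 = b3\_v1\, e^{V/b3\_v2}, \quad
#'       \alpha_2 = a2\_v1\, e^{V/a2\_v2}}
#' \deqn{\alpha_x = ax\,\alpha_2, \quad \beta_x = bx\,\alpha_3}
#' and the microscopic-reversibility constraint
#' \deqn{\beta_2 = \alpha_{13}\,\alpha_2\,\alpha_3 / (\beta_{13}\,\beta_3)}
#' which closes the C1-O-IF loop exactly. `b2` is always derived here, never
#' a free parameter. Exponentials are evaluated in log space with a cap at
#' `exp(700)` so extreme voltages during optimization cannot overflow.
#'
#' @param params A [rate_params()] vector (validated if not already).
#' @param V Membrane potential in mV (finite scalar).
#' @return Named numeric vector of class `rate_set` with elements
#'   `a11, a12, a13, b11, b12, b13, a3, b3, a2, b2, ax, bx` (all ms^-1),
#'   carrying `V` as an attribute.
#' @export
eval_rates <- function(params, V) {
  if (!inherits(params, "rate_params")) params <- rate_params(params)
  if (!is.numeric(V) || length(V) != 1L || !is.finite(V))
    stop("V must be a finite scalar (mV)")
  p <- as.list(params)
  a11 <- exp_capped(-log(p$a11_v1) + V / p$a11_v2, "a11")
  b11 <- exp_capped(-log(p$b11_v1) - V / p$b11_v2, "b11")
  a12 <- p$a12 * a11
  a13 <- p$a13 * a11
  b12 <- p$b12 * b11
  b13 <- p$b13 * b11
  a3 <- exp_capped(log(p$a3_v1) - V / p$a3_v2, "a3")
  b3 <- exp_capped(log(p$b3_v1) + V / p$b3_v2, "b3")
  a2 <- exp_capped(log(p$a2_v1) + V / p$a2_v2, "a2")
  ax <- p$ax * a2
  bx <- p$bx * a3
  b2 <- a13 * a2 * a3 / (b13 * b3)
  r <- c(a11 = a11, a12 = a12, a13 = a13,
         b11 = b11, b12 = b12, b13 = b13,
         a3 = a3, b3 = b3, a2 = a2, b2 = b2, ax = ax, bx = bx)
  if (any(!is.finite(r)))
    stop("rate evaluation overflow in: ",
         paste(names(r)[!is.finite(r)], collapse = ", "))
  structure(r, V = V, class = c("rate_set", "numeric"))
}
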