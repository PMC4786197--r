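#' Peak open-state occupancy of a trace
#'
#' Maximum of the open occupancy over a trace and the time at which it is
#' attained. If an analytic occupancy function `refine` (time -> occupancy)
#' is supplied, the grid maximum is refined by golden-section search in the
#' bracketing grid interval, making the result insensitive to the sampling
#' grid.
#'
#' @param trace An `occupancy_trace` (see [propagate()]) or a list with
#'   `time` and a numeric vector `open`.
#' @param state Open state name if `trace` is an `occupancy_trace`.
#' @param refine Optional function `f(t)` returning the exact occupancy.
#' @param deriv Optional function `f'(t)` (the analytic time derivative of
#'   the occupancy); when supplied, an interior peak is located by root
#'   bisection on the derivative, which is considerably more precise than a
#'   direct search on `f`.
#' @return List `value`, `time` (ms).
#' @export
peak_open <- function(trace, state = "O", refine = NULL, deriv = NULL) {
  tt <- trace$time
  y <- if (!is.null(trace$p)) as.numeric(trace$p[state, ]) else trace$open
  if (length(y) == 0L) stop("empty trace")
  if (all(y <= 0)) {
    warning("degenerate trace: occupancy never positive")
    return(list(value = 0, time = 0))
  }
  i <- which.max(y)
  value <- y[i]; tpk <- tt[i]
  if (!is.null(refine) && length(tt) > 2L && i > 1L && i < length(tt)) {
    lo <- tt[i - 1L]; hi <- tt[i + 1L]
    done <- FALSE
    if (!is.null(deriv) && deriv(lo) > 0 && deriv(hi) < 0) {
      root <- stats::uniroot(deriv, c(lo, hi), tol = 1e-12)$root
      v <- refine(root)
      if (v >= value) { value <- v; tpk <- root; done <- TRUE }
    }
    if (!done) {
      opt <- stats::optimize(refine, c(lo, hi), maximum = TRUE,
                             tol = .Machine$double.eps^0.5)
      if (opt$objective >= value) {
        value <- opt$objective
        tpk <- opt$maximum
      }
    }
  }
  list(value = value, time = tpk)
}

#' Time to 50% decay of the open occupancy
#'
#' First time after the peak at which the open occupancy falls to half its
#' peak value. With an analytic `refine` function the crossing is located
#' by root bisection on the exact segment solution; otherwise by linear
#' interpolation between grid samples.
#'
#' @inheritParams peak_open
#' @return Tau50 in ms, measured from the peak time.
#' @export
time_to_half_decay <- function(trace, state = "O", refine = NULL,
                               deriv = NULL) {
  tt <- trace$time
  y <- if (!is.null(trace$p)) as.numeric(trace$p[state, ]) else trace$open
  pk <- peak_open(trace, state = state, refine = refine, deriv = deriv)
  if (pk$value <= 0) stop("readout undefined: trace has no positive peak")
  half <- pk$value / 2
  after <- which(tt >= pk$time & y <= half)
  if (length(after) == 0L)
    stop("readout undefined: trace never decays below half of its peak")
  j <- after[1L]
  if (!is.null(refine)) {
    lo <- max(pk$time, tt[max(1L, j - 1L)])
    root <- stats::uniroot(function(t) refine(t) - half, c(lo, tt[j]),
                           tol = 1e-10, extendInt = "no")$root
  } else {
    if (j == 1L) return(0)
    t0 <- tt[j - 1L]; t1 <- tt[j]
    y0 <- y[j - 1L]; y1 <- y[j]
    root <- t0 + (half - y0) * (t1 - t0) / (y1 - y0)
  }
  root - pk$time
}

#' Exponential fit of recovery/decay data
#'
#' Least-squares fit of `y = C1 - A1*exp(-t/tau1)` (single) or
#' `y = C1 - A1*exp(-t/tau1) - A2*exp(-t/tau2)` (double) by
#' Levenberg-Marquardt ([minpack.lm::nlsLM]). For double fits the
#' components are reported with `tau1 <= tau2`.
#'
#' @param t,y Numeric vectors (ms, dimensionless).
#' @param n_components 1 or 2.
#' @param start Optional named list of starting values (`C1, A1, tau1`,
#'   and for double fits `A2, tau2`).
#' @return List of class `exp_fit`: `C1, A1, tau1` (+ `A2, tau2`),
#'   `residual_norm`, `fitted`.
#' @export
fit_exponential <- function(t, y, n_components = 1, start = NULL) {
  stopifnot(length(t) == length(y), n_components %in% c(1, 2))
  n_par <- if (n_components == 1) 3L else 5L
  if (length(t) < 2L * n_par)
    stop("need at least ", 2L * n_par, " points for a ", n_components,
         "-component fit")
  if (stats::sd(y) == 0) {
    out <- list(C1 = y[1], A1 = 0, tau1 = 1)
    if (n_components == 2) out <- c(out, list(A2 = 0, tau2 = 2))
    out$residual_norm <- 0
    out$fitted <- y
    class(out) <- "exp_fit"
    return(out)
  }
  rng <- diff(range(t[t > 0 | t >= 0]))
  if (is.null(start)) {
    C1 <- max(y)
    A <- C1 - y[which.min(t)]
    if (n_components == 1) {
      start <- list(C1 = C1, A1 = A, tau1 = rng / 5)
    } else {
      start <- list(C1 = C1, A1 = 0.7 * A, tau1 = rng / 20,
                    A2 = 0.3 * A, tau2 = rng / 2)
    }
  }
  df <- data.frame(t = t, y = y)
  form <- if (n_components == 1) {
    y ~ C1 - A1 * exp(-t / tau1)
  } else {
    y ~ C1 - A1 * exp(-t / tau1) - A2 * exp(-t / tau2)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = df, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("exponential fit failed: ", conditionMessage(e),
                             " (best starting values: ",
                             paste(names(start), unlist(start), sep = "=",
                                   collapse = ", "), ")")
  )
  cf <- as.list(stats::coef(fit))
  if (n_components == 2 && cf$tau1 > cf$tau2) {
    cf <- list(C1 = cf$C1, A1 = cf$A2, tau1 = cf$tau2,
               A2 = cf$A1, tau2 = cf$tau1)
  }
  out <- cf
  out$residual_norm <- sqrt(sum(stats::resid(fit)^2))
  out$fitted <- as.numeric(stats::fitted(fit))
  class(out) <- "exp_fit"
  out
}

#' Recover the voltage dependence of the recovery rate
#'
#' The closed-state recovery rate has the form `a * exp(-V/b)` and is
#' proportional to `1/tau1` of double-exponential recovery fits. Given fast
#' time constants at two or more voltages, a log-linear regression of
#' `log(prop/tau1)` on V yields `b` (from the slope `-1/b`) and `a` (from
#' the intercept).
#'
#' @param tau1 Fast time constants (ms) or a list of [fit_exponential()]
#'   results.
#' @param V Voltages (mV), same length.
#' @param proportionality Proportionality constant between `1/tau1` and the
#'   rate (default 1).
#' @return List `a`, `b`, `fit` (the `lm`). When the slope is (numerically)
#'   zero, `b` is `Inf` and a warning is raised.
#' @export
rate_from_recovery <- function(tau1, V, proportionality = 1) {
  if (is.list(tau1)) tau1 <- vapply(tau1, function(f) f$tau1, numeric(1))
  stopifnot(length(tau1) == length(V), length(V) >= 2)
  if (length(unique(V)) < 2L) stop("degenerate regression: identical voltages")
  fit <- stats::lm(log(proportionality / tau1) ~ V)
  slope <- unname(stats::coef(fit)[2])
  a <- exp(unname(stats::coef(fit)[1]))
  if (abs(slope) < 1e-12) {
    warning("zero slope: recovery rate has no resolvable voltage dependence")
    b <- Inf
  } else {
    b <- -1 / slope
  }
  list(a = a, b = b, fit = fit)
}

#' Mean open time
#'
#' The mean sojourn time in the open state at a voltage `V` is the
#' reciprocal of the total exit rate from O:
#' `MOT = 1 / (beta13(V) + alpha2(V) + alphax(V))`.
#'
#' @param params A [rate_params()] vector.
#' @param V Membrane potential (mV).
#' @return Mean open time in ms.
#' @export
mean_open_time <- function(params, V) {
  r <- eval_rates(params, V)
  exit <- r[["b13"]] + r[["a2"]] + r[["ax"]]
  if (exit <= 0) stop("infinite mean open time: zero exit rate from O")
  1 / exit
}
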