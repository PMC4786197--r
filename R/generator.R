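#' Build the master-equation generator matrix
#'
#' Assembles the rate matrix Q of the linear master equation
#' `dP/dt = Q %*% P` for a scheme and a resolved rate set. The
#' columns-as-source convention is used throughout the package: entry
#' `Q[j, i]` is the rate from state `i` to state `j`, so every column sums
#' to zero (probability conservation) and all off-diagonal entries are
#' non-negative.
#'
#' @param scheme A [channel_scheme()].
#' @param rates Named numeric vector resolving every rate label of the
#'   scheme (e.g. from [eval_rates()]); zero values are allowed (absent
#'   transition), `NA` is an error.
#' @return A dense square matrix (ms^-1) with state names as dimnames and
#'   the membrane potential (if `rates` carries one) as attribute `V`.
#' @export
build_generator <- function(scheme, rates) {
  de <- directed_edges(scheme)
  miss <- setdiff(unique(de$label), names(rates))
  if (length(miss))
    stop("scheme definition error: unresolved rate label(s): ",
         paste(miss, collapse = ", "))
  vals <- as.numeric(rates[de$label])
  if (any(!is.finite(vals)))
    stop("scheme definition error: non-finite rate for label(s): ",
         paste(unique(de$label[!is.finite(vals)]), collapse = ", "))
  if (any(vals < 0))
    stop("negative transition rate for label(s): ",
         paste(unique(de$label[vals < 0]), collapse = ", "))
  n <- length(scheme$states)
  Q <- matrix(0, n, n, dimnames = list(scheme$states, scheme$states))
  for (k in seq_len(nrow(de))) {
    i <- de$from[k]; j <- de$to[k]
    Q[j, i] <- Q[j, i] + vals[k]
  }
  diag(Q) <- diag(Q) - colSums(Q)
  attr(Q, "V") <- attr(rates, "V")
  Q
}

#' Stationary (equilibrium) occupancy of a generator
#'
#' Solves `Q %*% p = 0`, `sum(p) = 1`, `p >= 0` by least squares on the
#' stacked system. Used for holding-potential initial conditions. For a
#' conservative generator whose recurrent communicating class is unique the
#' solution is unique; schemes with unreachable-but-draining states (e.g. a
#' drug scheme at zero concentration) are handled naturally, with zero mass
#' on transient states.
#'
#' @param Q Generator matrix from [build_generator()].
#' @param tol Residual tolerance for the linear solve.
#' @return Named probability vector over the states of `Q`.
#' @export
equilibrium_distribution <- function(Q, tol = 1e-8) {
  n <- nrow(Q)
  check_generator(Q)
  # columns of Q sum to zero, so the rows are linearly dependent: replace one
  # balance equation by the normalization constraint and solve the square
  # system; fall back to an SVD pseudo-inverse for stiff generators.
  A <- Q; A[n, ] <- 1
  b <- c(rep(0, n - 1L), 1)
  p <- tryCatch(solve(A, b), error = function(e) NULL)
  resid_of <- function(p) {
    if (is.null(p) || any(!is.finite(p))) return(Inf)
    max(abs(Q %*% p)) / max(1, max(abs(Q))) + abs(sum(p) - 1)
  }
  if (resid_of(p) > tol || (!is.null(p) && min(p) < -1e-8)) {
    sv <- svd(rbind(Q, rep(1, n)))
    d <- sv$d
    dinv <- ifelse(d > max(d) * 1e-14, 1 / d, 0)
    p <- as.numeric(sv$v %*% (dinv * crossprod(sv$u, c(rep(0, n), 1))))
  }
  if (resid_of(p) > tol)
    stop("equilibrium not unique: residual too large ",
         "(reducible or defective generator)")
  if (min(p) < -1e-8)
    stop("equilibrium not unique: negative stationary probabilities")
  p <- pmax(p, 0)
  p <- p / sum(p)
  names(p) <- rownames(Q)
  p
}

check_generator <- function(Q, tol = 1e-9) {
  if (!is.matrix(Q) || nrow(Q) != ncol(Q))
    stop("generator must be a square matrix")
  off <- Q; diag(off) <- 0
  if (any(off < -tol))
    stop("generator error: negative off-diagonal entries")
  if (max(abs(colSums(Q))) > tol * max(1, max(abs(Q))))
    stop("generator error: columns do not sum to zero (non-conservative)")
  invisible(TRUE)
}

#' Spectral propagator for a constant-voltage segment
#'
#' Returns a function `function(p0, t)` evaluating the exact solution
#' `P(t) = exp(Q t) %*% p0` of the master equation for a vector of times,
#' as a states-by-times matrix. The default path diagonalizes Q once
#' (spectral solution), so each evaluation is a small dense product and
#' results are identical for any time grid; if Q is numerically defective
#' the propagator falls back to scaling-and-squaring matrix exponentials
#' (`Matrix::expm`) per requested time.
#'
#' @param Q Generator matrix.
#' @return Function `(p0, t) -> matrix` with `length(t)` columns.
#' @export
make_propagator <- function(Q) {
  check_generator(Q)
  n <- nrow(Q)
  if (n == 1L) return(function(p0, t) matrix(p0, 1L, length(t),
                                             dimnames = list(rownames(Q), NULL)))
  eg <- eigen(Q)
  Vc <- eg$vectors
  Vi <- tryCatch(solve(Vc), error = function(e) NULL)
  ok <- FALSE
  if (!is.null(Vi)) {
    recon <- Vc %*% (eg$values * Vi)
    ok <- max(Mod(recon - Q)) <= 1e-8 * max(1, max(abs(Q)))
  }
  if (ok) {
    lam <- eg$values
    function(p0, t) {
      w <- as.vector(Vi %*% p0)
      E <- exp(outer(lam, t))        # n x length(t)
      out <- Re(Vc %*% (E * w))
      rownames(out) <- rownames(Q)
      out
    }
  } else {
    function(p0, t) {
      out <- vapply(t, function(tt) {
        as.numeric(Matrix::expm(Matrix::Matrix(Q * tt)) %*% p0)
      }, numeric(n))
      out <- matrix(out, n, length(t), dimnames = list(rownames(Q), NULL))
      out
    }
  }
}

#' Propagate occupancies through a constant-voltage interval
#'
#' Solves the master equation on `[0, duration]` and samples the occupancy
#' trajectory every `sample_dt` ms (always including both endpoints).
#' Propagation is by the exact spectral/matrix-exponential solution of the
#' linear system, so refining `sample_dt` changes only where the solution
#' is sampled, not its values.
#'
#' @param Q Generator matrix.
#' @param p0 Initial occupancy vector (non-negative, sums to 1 within 1e-8).
#' @param duration Interval length in ms (> 0).
#' @param sample_dt Sampling interval in ms.
#' @return List of class `occupancy_trace` with `time` (ms) and `p`
#'   (states x times matrix).
#' @export
propagate <- function(Q, p0, duration, sample_dt = duration / 200) {
  check_generator(Q)
  if (length(p0) != nrow(Q)) stop("p0 length does not match generator")
  if (any(p0 < -1e-10) || abs(sum(p0) - 1) > 1e-8)
    stop("p0 is not a probability vector")
  if (duration <= 0) stop("duration must be positive")
  tgrid <- unique(c(seq(0, duration, by = sample_dt), duration))
  prop <- make_propagator(Q)
  p <- prop(p0, tgrid)
  structure(list(time = tgrid, p = p), class = "occupancy_trace")
}

#' Extract the conducting (open-state) occupancy from a trace
#'
#' @param trace An `occupancy_trace` from [propagate()].
#' @param state State name to extract (default `"O"`).
#' @return Numeric vector of occupancies along `trace$time`.
#' @export
open_occupancy <- function(trace, state = "O") {
  if (!state %in% rownames(trace$p)) stop("state ", state, " not in trace")
  as.numeric(trace$p[state, ])
}
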