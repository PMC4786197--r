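#' Optimizer options
#'
#' Convergence and bound settings for [minimize_bounded()]. Convergence
#' requires both tolerances simultaneously: the spread of cost values over
#' the simplex must fall below `tol_cost` and the spread of parameter values
#' below `tol_par` (the conjunction of the two 0.01 defaults).
#'
#' @param tol_cost Tolerance on the simplex cost spread (default 0.01).
#' @param tol_par Tolerance on the simplex parameter spread (default 0.01).
#' @param max_iter Maximum simplex iterations.
#' @param lower,upper Bounds (scalar or per-parameter); default positivity.
#' @param seed Optional random seed recorded with results.
#' @return List of class `optimizer_options`.
#' @export
optimizer_options <- function(tol_cost = 0.01, tol_par = 0.01,
                              max_iter = 1000L, lower = 0, upper = Inf,
                              seed = NULL) {
  stopifnot(tol_cost > 0, tol_par > 0, max_iter >= 1)
  structure(list(tol_cost = tol_cost, tol_par = tol_par,
                 max_iter = as.integer(max_iter),
                 lower = lower, upper = upper, seed = seed),
            class = "optimizer_options")
}

# Boundary-reachable variable transforms (per coordinate):
#   (-Inf, Inf): identity
#   [lb, Inf):   x = lb + u^2
#   (-Inf, ub]:  x = ub - u^2
#   [lb, ub]:    x = lb + (ub - lb) * (sin(u) + 1) / 2
make_transform <- function(lower, upper, n) {
  lb <- rep_len(lower, n); ub <- rep_len(upper, n)
  if (any(lb >= ub)) stop("lower bounds must be below upper bounds")
  kind <- ifelse(is.finite(lb) & is.finite(ub), "both",
          ifelse(is.finite(lb), "lower",
          ifelse(is.finite(ub), "upper", "free")))
  to_x <- function(u) {
    x <- u
    i <- kind == "lower"; x[i] <- lb[i] + u[i]^2
    i <- kind == "upper"; x[i] <- ub[i] - u[i]^2
    i <- kind == "both"
    x[i] <- lb[i] + (ub[i] - lb[i]) * (sin(u[i]) + 1) / 2
    x
  }
  to_u <- function(x) {
    if (any(x < lb) || any(x > ub)) stop("initial parameters out of bounds")
    u <- x
    i <- kind == "lower"; u[i] <- sqrt(x[i] - lb[i])
    i <- kind == "upper"; u[i] <- sqrt(ub[i] - x[i])
    i <- kind == "both"
    u[i] <- asin(pmin(1, pmax(-1, 2 * (x[i] - lb[i]) / (ub[i] - lb[i]) - 1)))
    u
  }
  clip <- function(x) pmin(pmax(x, lb), ub)
  list(to_x = to_x, to_u = to_u, clip = clip, lb = lb, ub = ub)
}

#' Bounded Nelder-Mead minimization
#'
#' Direct-search simplex minimization on a smooth bounded transform of the
#' parameter space (quadratic transform for one-sided bounds, sinusoidal for
#' two-sided), so bounds are reachable without stalling the simplex on a
#' face. Standard reflection/expansion/contraction/shrink coefficients
#' (1, 2, 0.5, 0.5). Termination requires the simplex cost spread and the
#' parameter spread (in original coordinates) to fall below their
#' tolerances simultaneously, or `max_iter` iterations.
#'
#' @param fn Cost function of the parameter vector; may return `Inf`.
#' @param x0 Initial parameter vector (within bounds).
#' @param options An [optimizer_options()].
#' @return List: `par` (best parameters), `value`, `history` (data frame
#'   `iteration`, `cost` of the best-so-far value), `iterations`,
#'   `converged`.
#' @export
minimize_bounded <- function(fn, x0, options = optimizer_options()) {
  n <- length(x0)
  tr <- make_transform(options$lower, options$upper, n)
  u0 <- tr$to_u(x0)
  nms <- names(x0)
  f <- function(u) {
    x <- tr$to_x(as.numeric(u))
    names(x) <- nms
    v <- fn(x)
    if (!is.finite(v)) Inf else v
  }
  f0 <- f(u0)
  if (!is.finite(f0)) stop("invalid start: cost is not finite at x0")

  # initial simplex (5% per-coordinate perturbation in transformed space)
  U <- matrix(rep(u0, n + 1L), nrow = n)
  for (i in seq_len(n)) {
    U[i, i + 1L] <- if (U[i, i + 1L] != 0) 1.05 * U[i, i + 1L] else 0.00025
  }
  fv <- c(f0, vapply(2:(n + 1L), function(j) f(U[, j]), numeric(1)))

  rho <- 1; chi <- 2; psi <- 0.5; sigma <- 0.5
  hist_cost <- numeric(options$max_iter)
  it <- 0L
  converged <- FALSE
  while (it < options$max_iter) {
    it <- it + 1L
    ord <- order(fv)
    fv <- fv[ord]; U <- U[, ord, drop = FALSE]
    X <- matrix(vapply(seq_len(n + 1L), function(j) tr$to_x(U[, j]),
                       numeric(n)), nrow = n)
    spread_f <- max(abs(fv[-1L] - fv[1L]))
    spread_x <- max(abs(X[, -1L, drop = FALSE] - X[, 1L]))
    hist_cost[it] <- fv[1L]
    if (spread_f <= options$tol_cost && spread_x <= options$tol_par) {
      converged <- TRUE
      break
    }
    ubar <- rowMeans(U[, -(n + 1L), drop = FALSE])
    ur <- ubar + rho * (ubar - U[, n + 1L])
    fr <- f(ur)
    if (fr < fv[1L]) {
      ue <- ubar + chi * (ur - ubar)
      fe <- f(ue)
      if (fe < fr) { U[, n + 1L] <- ue; fv[n + 1L] <- fe }
      else { U[, n + 1L] <- ur; fv[n + 1L] <- fr }
    } else if (fr < fv[n]) {
      U[, n + 1L] <- ur; fv[n + 1L] <- fr
    } else {
      if (fr < fv[n + 1L]) {
        uc <- ubar + psi * (ur - ubar)
        fc <- f(uc)
        shrink <- !(fc <= fr)
      } else {
        uc <- ubar - psi * (ubar - U[, n + 1L])
        fc <- f(uc)
        shrink <- !(fc < fv[n + 1L])
      }
      if (!shrink) {
        U[, n + 1L] <- uc; fv[n + 1L] <- fc
      } else {
        for (j in 2:(n + 1L)) {
          U[, j] <- U[, 1L] + sigma * (U[, j] - U[, 1L])
          fv[j] <- f(U[, j])
        }
      }
    }
  }
  ord <- order(fv)
  best_u <- U[, ord[1L]]
  list(par = stats::setNames(tr$to_x(best_u), names(x0)),
       value = fv[ord[1L]],
       history = data.frame(iteration = seq_len(it),
                            cost = hist_cost[seq_len(it)]),
       iterations = it,
       converged = converged)
}

# All permutations of 1..n (lexicographic); n! rows.
permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Sequential / factorial protocol scheduling
#'
#' Optimizes protocol groups cumulatively: the first group is optimized for
#' `block_iter` iterations, then the second group's datasets are added and
#' the combined objective optimized for another block, and so on. With
#' `orderings = "factorial"` every permutation of the groups is scheduled
#' (4 groups = 24 orderings) and the ordering with the lowest scheduled cost
#' is continued to convergence.
#'
#' @param groups Named list; each element is a list of
#'   [experiment_dataset()]s forming one protocol group.
#' @param protocols Named list of [protocol()] definitions.
#' @param x0 Initial parameter vector.
#' @param build_model Function `params -> channel_model`.
#' @param options [optimizer_options()] for the final continuation.
#' @param block_iter Iterations per scheduled block (default 100).
#' @param orderings `"factorial"`, or a list of integer permutations of the
#'   groups.
#' @param workers Worker count passed to [total_cost()].
#' @return List: `orderings` (per-ordering group order and scheduled cost),
#'   `best` (continued optimization result for the best ordering),
#'   `best_ordering`.
#' @export
sequential_schedule <- function(groups, protocols, x0,
                                build_model = channel_model,
                                options = optimizer_options(),
                                block_iter = 100L,
                                orderings = "factorial",
                                workers = 1L) {
  ng <- length(groups)
  stopifnot(ng >= 1L)
  if (identical(orderings, "factorial")) {
    perm <- permutations(ng)
    orderings <- lapply(seq_len(nrow(perm)), function(i) perm[i, ])
  }
  if (ng == 1L) {
    ds <- groups[[1L]]
    fn <- function(p) total_cost(p, ds, protocols, build_model,
                                 workers = workers)$total
    res <- minimize_bounded(fn, x0, options)
    return(list(orderings = list(list(order = 1L, cost = res$value,
                                      par = res$par)),
                best = res, best_ordering = 1L))
  }
  runs <- lapply(orderings, function(ord) {
    par <- x0
    cost <- NA_real_
    for (k in seq_along(ord)) {
      ds <- do.call(c, unname(groups[ord[seq_len(k)]]))
      fn <- function(p) total_cost(p, ds, protocols, build_model,
                                   workers = workers)$total
      block_opt <- options
      block_opt$max_iter <- as.integer(block_iter)
      block_opt$tol_cost <- 0  # run the full block
      block_opt$tol_par <- 0
      r <- minimize_bounded(fn, par, block_opt)
      par <- r$par
      cost <- r$value
    }
    list(order = ord, cost = cost, par = par)
  })
  costs <- vapply(runs, function(r) r$cost, numeric(1))
  best_i <- which.min(costs)
  all_ds <- do.call(c, unname(groups))
  fn <- function(p) total_cost(p, all_ds, protocols, build_model,
                               workers = workers)$total
  best <- minimize_bounded(fn, runs[[best_i]]$par, options)
  list(orderings = runs, best = best, best_ordering = runs[[best_i]]$order)
}

#' Perturb parameters by a bounded random factor
#'
#' Multiplies each parameter by an independent uniform factor in
#' `[1 - pct/100, 1 + pct/100]`. Reproducible given `seed`.
#'
#' @param params Numeric parameter vector.
#' @param pct Perturbation percentage (0 <= pct < 100).
#' @param seed Optional integer seed.
#' @return Perturbed parameter vector.
#' @export
perturb_parameters <- function(params, pct, seed = NULL) {
  if (pct < 0) stop("pct must be >= 0")
  if (pct >= 100) stop("pct must be < 100 (rates must stay positive)")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  fac <- stats::runif(length(params), 1 - pct / 100, 1 + pct / 100)
  out <- params * fac
  attributes(out) <- attributes(params)
  out
}

#' Restart an optimization from a perturbed point
#'
#' Kick-starts a search stuck in a local minimum: each parameter of a
#' finished run's optimum is perturbed by an independent uniform factor of
#' up to `pct` percent (clipped to bounds) and the optimization restarted.
#'
#' @param fn Cost function.
#' @param result A [minimize_bounded()] result with finite `value`.
#' @param pct Perturbation percentage (default 10).
#' @param seed Integer seed making the perturbation reproducible.
#' @param options [optimizer_options()].
#' @return A new [minimize_bounded()] result, with the perturbed start
#'   attached as attribute `start`.
#' @export
restart_perturbed <- function(fn, result, pct = 10, seed = NULL,
                              options = optimizer_options()) {
  if (!is.finite(result$value)) stop("cannot restart from an infinite cost")
  tr <- make_transform(options$lower, options$upper, length(result$par))
  start <- tr$clip(perturb_parameters(result$par, pct, seed))
  out <- minimize_bounded(fn, start, options)
  attr(out, "start") <- start
  out
}
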