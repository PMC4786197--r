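#' Reversible channel gating scheme
#'
#' A `channel_scheme` is a labelled, reversible directed graph over channel
#' conformational states. Each undirected edge carries two rate labels, one
#' per direction; labels index into a named rate vector (see [eval_rates()]).
#'
#' @param states Character vector of unique state names.
#' @param edges Data frame with columns `from`, `to`, `fwd`, `rev`: one row
#'   per reversible transition, `fwd` the rate label for `from -> to` and
#'   `rev` for `to -> from`.
#' @param conducting Character vector, subset of `states`, the conducting
#'   (open) states.
#'
#' @return An object of class `channel_scheme`.
#' @seealso [nav_scheme()] for the built-in 8-state sodium channel scheme.
#' @export
channel_scheme <- function(states, edges, conducting = character()) {
  stopifnot(is.character(states), length(states) > 0L)
  if (anyDuplicated(states))
    stop("duplicate state names: ", paste(states[duplicated(states)], collapse = ", "))
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  need <- c("from", "to", "fwd", "rev")
  if (!all(need %in% names(edges)))
    stop("edges must have columns from, to, fwd, rev")
  edges <- edges[, need]
  bad <- setdiff(unique(c(edges$from, edges$to)), states)
  if (length(bad)) stop("edge references unknown state(s): ", paste(bad, collapse = ", "))
  if (any(edges$from == edges$to)) stop("self-loops are not allowed")
  key <- apply(edges[, c("from", "to")], 1L, function(r) paste(sort(r), collapse = "|"))
  if (anyDuplicated(key)) stop("duplicate edge between the same pair of states")
  if (!all(conducting %in% states))
    stop("conducting states must be a subset of states")
  structure(
    list(states = states, edges = edges, conducting = conducting),
    class = "channel_scheme"
  )
}

#' @export
print.channel_scheme <- function(x, ...) {
  cat("channel_scheme:", length(x$states), "states,",
      nrow(x$edges), "reversible transitions\n")
  cat("  states:", paste(x$states, collapse = ", "), "\n")
  cat("  conducting:", paste(x$conducting, collapse = ", "), "\n")
  invisible(x)
}

#' The 8-state cardiac sodium channel gating scheme
#'
#' The wild-type Nav1.5 scheme: three closed states (C3, C2, C1), one open
#' state (O), fast- and slow-inactivated states (IF, IS), and two
#' closed-inactivated states (IC3, IC2). Activation runs C3-C2-C1-O with
#' rates `a11`/`a12`/`a13` (deactivation `b11`/`b12`/`b13`), the inactivated
#' row IC3-IC2-IF shares the activation labels, closed-state inactivation is
#' the vertical `b3` (recovery `a3`), open-state fast inactivation is
#' `a2`/`b2` (with `b2` constrained by microscopic reversibility), and slow
#' inactivation from the open state is `ax`/`bx`.
#'
#' @return A [channel_scheme()] with 8 states and 10 reversible transitions.
#' @export
nav_scheme <- function() {
  edges <- data.frame(
    from = c("IC3", "IC2", "C3", "C2", "C1", "IC3", "IC2", "IF", "O", "O"),
    to   = c("IC2", "IF",  "C2", "C1", "O",  "C3",  "C2",  "C1", "IF", "IS"),
    fwd  = c("a11", "a12", "a11", "a12", "a13", "a3", "a3", "a3", "a2", "ax"),
    rev  = c("b11", "b12", "b11", "b12", "b13", "b3", "b3", "b3", "b2", "bx"),
    stringsAsFactors = FALSE
  )
  channel_scheme(
    states = c("IC3", "IC2", "IF", "IS", "C3", "C2", "C1", "O"),
    edges = edges,
    conducting = "O"
  )
}

# Directed view of a scheme's edges: one row per directed transition.
directed_edges <- function(scheme) {
  e <- scheme$edges
  data.frame(
    from = c(e$from, e$to),
    to = c(e$to, e$from),
    label = c(e$fwd, e$rev),
    stringsAsFactors = FALSE
  )
}

scheme_graph <- function(scheme) {
  igraph::graph_from_data_frame(
    scheme$edges[, c("from", "to")],
    directed = FALSE,
    vertices = scheme$states
  )
}

# Fundamental cycles of the scheme graph relative to a spanning tree built
# from the edges flagged usable. Returns a list of cycles; each cycle is a
# data.frame(from, to) of directed steps around the loop, starting with the
# chord edge.
fundamental_cycles <- function(scheme, tree_edge = rep(TRUE, nrow(scheme$edges))) {
  g <- scheme_graph(scheme)
  n_edge <- nrow(scheme$edges)
  tg <- igraph::subgraph_from_edges(g, which(tree_edge), delete.vertices = FALSE)
  tree <- igraph::mst(tg)
  if (igraph::ecount(tree) != length(scheme$states) - 1L)
    stop("assigned transitions do not connect the scheme; cannot form a spanning tree")
  tree_pairs <- igraph::as_edgelist(tree)
  tree_key <- apply(tree_pairs, 1L, function(r) paste(sort(r), collapse = "|"))
  edge_key <- apply(scheme$edges[, c("from", "to")], 1L,
                    function(r) paste(sort(r), collapse = "|"))
  chords <- which(!(edge_key %in% tree_key))
  lapply(chords, function(i) {
    u <- scheme$edges$from[i]; v <- scheme$edges$to[i]
    path <- igraph::shortest_paths(tree, from = v, to = u, output = "vpath")$vpath[[1]]
    path <- names(path)
    steps <- data.frame(
      from = c(u, path[-length(path)]),
      to = c(v, path[-1L]),
      stringsAsFactors = FALSE
    )
    attr(steps, "chord") <- i
    steps
  })
}

rate_for <- function(scheme, rates, from, to) {
  e <- scheme$edges
  i <- which(e$from == from & e$to == to)
  if (length(i)) return(rates[[e$fwd[i]]])
  i <- which(e$from == to & e$to == from)
  if (length(i)) return(rates[[e$rev[i]]])
  stop("no transition between ", from, " and ", to)
}

label_for <- function(scheme, from, to) {
  e <- scheme$edges
  i <- which(e$from == from & e$to == to)
  if (length(i)) return(e$fwd[i])
  i <- which(e$from == to & e$to == from)
  if (length(i)) return(e$rev[i])
  stop("no transition between ", from, " and ", to)
}

#' Detailed-balance residuals over a cycle basis
#'
#' For each independent cycle of the scheme graph (fundamental cycles of a
#' spanning tree), computes `log(prod forward rates / prod reverse rates)`.
#' All residuals are zero (to floating tolerance) if and only if the rate set
#' satisfies microscopic reversibility.
#'
#' @param scheme A [channel_scheme()].
#' @param rates Named numeric vector resolving every rate label of the scheme.
#' @return Numeric vector of per-cycle log-ratio residuals (length = number of
#'   independent cycles; zero-length if the graph is a tree).
#' @export
cycle_residuals <- function(scheme, rates) {
  cycles <- fundamental_cycles(scheme)
  vapply(cycles, function(cy) {
    lf <- mapply(function(f, t) rate_for(scheme, rates, f, t), cy$from, cy$to)
    lr <- mapply(function(f, t) rate_for(scheme, rates, f, t), cy$to, cy$from)
    if (any(!is.finite(lf)) || any(!is.finite(lr)))
      stop("unresolved rate on a cycle edge")
    if (any(lr == 0) || any(lf == 0))
      stop("detailed balance undefined: zero rate on a cycle edge")
    sum(log(lf)) - sum(log(lr))
  }, numeric(1))
}

#' Close cycles by microscopic reversibility
#'
#' Completes a partially assigned rate vector so that every cycle of the
#' scheme satisfies detailed balance. A spanning tree is formed from the
#' fully assigned transitions; each remaining chord must have exactly one
#' unassigned direction (`NA` in `rates`), which is solved so that the
#' chord's fundamental cycle has product ratio 1. Fully assigned chords are
#' verified instead; a nonzero residual raises a reversibility error. The
#' operation is idempotent.
#'
#' @param scheme A [channel_scheme()].
#' @param rates Named numeric vector covering every rate label, with `NA`
#'   marking rates to be solved.
#' @param tol Verification tolerance on log residuals of fully assigned
#'   chords.
#' @return The completed named rate vector.
#' @export
close_cycles <- function(scheme, rates, tol = 1e-8) {
  e <- scheme$edges
  assigned <- function(lbl) is.finite(rates[lbl])
  full <- vapply(seq_len(nrow(e)), function(i)
    assigned(e$fwd[i]) && assigned(e$rev[i]), logical(1))
  cycles <- fundamental_cycles(scheme, tree_edge = full)
  for (cy in cycles) {
    i <- attr(cy, "chord")
    labs_f <- mapply(function(f, t) label_for(scheme, f, t), cy$from, cy$to)
    labs_r <- mapply(function(f, t) label_for(scheme, f, t), cy$to, cy$from)
    labs <- c(labs_f, labs_r)
    miss <- labs[!is.finite(rates[labs])]
    if (length(miss) == 0L) {
      res <- sum(log(rates[labs_f])) - sum(log(rates[labs_r]))
      if (abs(res) > tol)
        stop("over-constrained cycle through ",
             paste(unique(c(cy$from, cy$to)), collapse = "-"),
             ": residual ", format(res))
      next
    }
    if (length(miss) > 1L)
      stop("under-determined cycle through ",
           paste(unique(c(cy$from, cy$to)), collapse = "-"),
           ": rates ", paste(miss, collapse = ", "), " all unassigned")
    solve_lab <- miss
    if (sum(labs == solve_lab) > 1L)
      stop("rate ", solve_lab, " appears on several edges of one cycle; ",
           "cannot be solved uniquely")
    lf <- rates[labs_f]; lr <- rates[labs_r]
    in_fwd <- solve_lab %in% labs_f
    logf <- sum(log(lf[is.finite(lf)]))
    logr <- sum(log(lr[is.finite(lr)]))
    val <- if (in_fwd) exp(logr - logf) else exp(logf - logr)
    if (!is.finite(val) || val <= 0)
      stop("cycle closure produced a non-positive rate for ", solve_lab)
    rates[solve_lab] <- val
  }
  rates
}
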