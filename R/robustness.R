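#' Perturb-and-refit robustness study
#'
#' Treats a known parameter set as the true optimum (its datasets are
#' generated so that it has zero cost), perturbs it by a bounded random
#' factor at each level, re-optimizes, and reports how close each run
#' returns to the truth: the per-parameter mean ratio (recovered/true) over
#' runs and the standard deviation of the ratio normalized to its mean.
#' Larger perturbations are expected to produce larger spread.
#'
#' @param true_params The generating parameter vector (cost 0 on the
#'   datasets).
#' @param datasets List of [experiment_dataset()]s (typically noise-free
#'   fixtures from [generate_datasets()]).
#' @param protocols Named list of [protocol()] definitions.
#' @param build_model Function `params -> channel_model`.
#' @param levels Perturbation percentages (default 5, 10, 25).
#' @param runs Runs per level (default 3).
#' @param options [optimizer_options()] for each re-optimization (a reduced
#'   `max_iter` keeps the full study desk-scale).
#' @param seed Integer seed; run `r` at level index `l` uses seed
#'   `seed + 1000*l + r`.
#' @param workers Worker count passed to [total_cost()].
#' @return List of class `robustness_report`: `summary` (data frame
#'   `parameter`, `level`, `mean_ratio`, `norm_sd`), `runs` (per-run level,
#'   seed, final cost, ratios), `levels`, `n_runs`.
#' @export
robustness_study <- function(true_params, datasets, protocols,
                             build_model = channel_model,
                             levels = c(5, 10, 25), runs = 3L,
                             options = optimizer_options(max_iter = 500L),
                             seed = 1L, workers = 1L) {
  fn <- function(p) total_cost(p, datasets, protocols, build_model,
                               workers = workers)$total
  run_rows <- list()
  for (l in seq_along(levels)) {
    for (r in seq_len(runs)) {
      s <- seed + 1000L * l + r
      start <- perturb_parameters(true_params, levels[l], seed = s)
      res <- tryCatch(minimize_bounded(fn, start, options),
                      error = function(e) NULL)
      run_rows[[length(run_rows) + 1L]] <- list(
        level = levels[l], run = r, seed = s,
        failed = is.null(res),
        cost = if (is.null(res)) NA_real_ else res$value,
        ratio = if (is.null(res)) NULL else
          unclass(res$par) / unclass(true_params)
      )
    }
  }
  nm <- names(true_params)
  summ <- do.call(rbind, lapply(levels, function(lv) {
    ok <- Filter(function(z) z$level == lv && !z$failed, run_rows)
    if (length(ok) == 0L)
      return(data.frame(parameter = nm, level = lv, mean_ratio = NA_real_,
                        norm_sd = NA_real_, row.names = NULL))
    R <- do.call(rbind, lapply(ok, function(z) z$ratio))
    data.frame(
      parameter = nm,
      level = lv,
      mean_ratio = colMeans(R),
      norm_sd = apply(R, 2L, stats::sd) / colMeans(R),
      row.names = NULL
    )
  }))
  structure(list(summary = summ, runs = run_rows, levels = levels,
                 n_runs = runs, seed = seed),
            class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat("Robustness study:", length(x$levels), "levels x", x$n_runs, "runs\n")
  agg <- stats::aggregate(norm_sd ~ level, data = x$summary, FUN = mean)
  names(agg)[2] <- "mean_norm_sd"
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Export a robustness report as a delimited table
#'
#' @param report A [robustness_study()] result.
#' @param file Path for the CSV summary.
#' @return The summary data frame, invisibly.
#' @export
write_robustness_report <- function(report, file) {
  utils::write.csv(report$summary, file, row.names = FALSE, quote = FALSE)
  invisible(report$summary)
}
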