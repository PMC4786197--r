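#' Experimental summary dataset
#'
#' Observed summary points for one protocol: the sweep-axis values `x`, the
#' measured readouts `y`, and an optional per-point standard deviation.
#'
#' @param protocol Protocol name (must match a protocol definition).
#' @param x,y Numeric vectors of equal, positive length.
#' @param sd Optional per-point SD.
#' @return Data frame of class `experiment_dataset`.
#' @export
experiment_dataset <- function(protocol, x, y, sd = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 1L)
  d <- data.frame(protocol = protocol, x = as.numeric(x), y = as.numeric(y))
  if (!is.null(sd)) {
    stopifnot(length(sd) == length(x))
    d$sd <- as.numeric(sd)
  }
  class(d) <- c("experiment_dataset", "data.frame")
  d
}

#' Normalized per-protocol cost
#'
#' Sum of squared errors between observed and simulated readouts, divided by
#' the number of data points, so that (say) a 9-point availability curve and
#' a single mean-open-time point carry equal weight per unit misfit.
#'
#' @param dataset An [experiment_dataset()].
#' @param simulated Numeric vector of simulated readouts aligned 1:1 with
#'   `dataset$x`.
#' @return Normalized SSE (scalar, >= 0).
#' @export
protocol_cost <- function(dataset, simulated) {
  if (length(simulated) != nrow(dataset))
    stop("alignment error: ", nrow(dataset), " observed vs ",
         length(simulated), " simulated points for protocol ",
         dataset$protocol[1])
  sum((dataset$y - simulated)^2) / nrow(dataset)
}

# Re-target a protocol's sweep axis at a dataset's x values.
protocol_at <- function(pr, x) {
  pr$sweep <- as.numeric(x)
  pr
}

#' Multi-protocol objective
#'
#' Evaluates the total normalized cost of a parameter vector against a list
#' of datasets. Each protocol is simulated at the dataset's sweep values and
#' scored with [protocol_cost()]; the per-protocol costs are summed in
#' dataset registration order, so the report is identical for any worker
#' count (fork-join contract: protocol evaluations are independent and may
#' run on parallel workers via [parallel::mclapply]; the reduction order is
#' fixed). A protocol simulation failure yields an infinite total cost
#' rather than an error, so optimization can continue past pathological
#' parameter regions.
#'
#' @param params Parameter vector accepted by `build_model`.
#' @param datasets List of [experiment_dataset()]s.
#' @param protocols Named list of [protocol()] definitions covering every
#'   dataset's protocol.
#' @param build_model Function `params -> channel_model`; default builds a
#'   drug-free [channel_model()].
#' @param workers Number of parallel workers (1 = serial; forked workers are
#'   only used on platforms that support them).
#' @param sample_dt Trace sampling interval passed to [run_protocol()].
#' @return List of class `cost_report`: `per_protocol` (named numeric),
#'   `total`, `failed` (character vector of failed protocols).
#' @export
total_cost <- function(params, datasets, protocols,
                       build_model = channel_model, workers = 1L,
                       sample_dt = 0.05) {
  names(datasets) <- vapply(datasets, function(d) d$protocol[1], character(1))
  miss <- setdiff(names(datasets), names(protocols))
  if (length(miss))
    stop("no protocol definition for dataset(s): ", paste(miss, collapse = ", "))
  model <- try(build_model(params), silent = TRUE)
  if (inherits(model, "try-error")) {
    per <- rep(Inf, length(datasets)); names(per) <- names(datasets)
    return(structure(list(per_protocol = per, total = Inf,
                          failed = names(datasets)), class = "cost_report"))
  }
  eval_one <- function(nm) {
    d <- datasets[[nm]]
    pr <- protocol_at(protocols[[nm]], d$x)
    tryCatch({
      sim <- run_protocol(model, pr, sample_dt = sample_dt)$readouts$y
      protocol_cost(d, sim)
    }, error = function(e) structure(Inf, msg = conditionMessage(e)))
  }
  nms <- names(datasets)
  res <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(nms, eval_one, mc.cores = workers)
  } else {
    lapply(nms, eval_one)
  }
  per <- vapply(res, as.numeric, numeric(1))
  names(per) <- nms
  structure(list(per_protocol = per, total = sum(per),
                 failed = nms[!is.finite(per)]), class = "cost_report")
}

#' @export
print.cost_report <- function(x, ...) {
  cat("total cost:", format(x$total), "\n")
  for (nm in names(x$per_protocol))
    cat("  ", nm, ": ", format(x$per_protocol[[nm]]), "\n", sep = "")
  if (length(x$failed)) cat("failed:", paste(x$failed, collapse = ", "), "\n")
  invisible(x)
}
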