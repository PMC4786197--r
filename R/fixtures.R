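#' Synthetic dataset specification
#'
#' Describes how to generate synthetic experimental datasets by simulating a
#' known "true" model under a protocol set, optionally adding Gaussian noise
#' to the (mostly dimensionless) readouts. The generating parameters are the
#' ground truth for parameter-recovery studies.
#'
#' @param params Generating [rate_params()].
#' @param protocols Named list of [protocol()]s to simulate.
#' @param noise_sd Absolute SD of additive Gaussian noise on readouts
#'   (>= 0; 0 = noise-free).
#' @param seed Integer seed for the noise.
#' @param spec,scalars Optional [drug_spec()] / [drug_scalars()]; when given
#'   the datasets are generated from the drug model.
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(params, protocols = default_protocols(),
                         noise_sd = 0, seed = 1L,
                         spec = NULL, scalars = NULL) {
  stopifnot(noise_sd >= 0)
  params <- if (inherits(params, "rate_params")) params else rate_params(params)
  structure(list(params = params, protocols = protocols,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 spec = spec, scalars = scalars),
            class = "fixture_spec")
}

#' Generate synthetic experiment datasets
#'
#' Simulates every protocol of a [fixture_spec()] under the generating model
#' and returns one [experiment_dataset()] per protocol, with Gaussian noise
#' of the requested SD added to the readouts. Deterministic given the seed.
#' The generating parameters are attached as attribute
#' `generating_params`, so noise-free fixtures satisfy
#' `total_cost(generating_params, ...)$total == 0` by construction.
#'
#' @param fspec A [fixture_spec()].
#' @return Named list of [experiment_dataset()]s.
#' @export
generate_datasets <- function(fspec) {
  stopifnot(inherits(fspec, "fixture_spec"))
  model <- if (is.null(fspec$spec)) {
    channel_model(fspec$params)
  } else {
    drug_model(fspec$params, fspec$spec,
               if (is.null(fspec$scalars)) flecainide_scalars(fspec$spec)
               else fspec$scalars)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(fspec$seed)
  out <- lapply(fspec$protocols, function(pr) {
    r <- tryCatch(run_protocol(model, pr),
                  error = function(e) stop("fixture generation failed for ",
                                           pr$name, ": ", conditionMessage(e)))
    y <- r$readouts$y
    if (fspec$noise_sd > 0)
      y <- y + stats::rnorm(length(y), 0, fspec$noise_sd)
    experiment_dataset(pr$name, r$readouts$x, y)
  })
  names(out) <- vapply(fspec$protocols, function(p) p$name, character(1))
  attr(out, "generating_params") <- fspec$params
  out
}

# ---------------------------------------------------------------------------
# File I/O. One shared text dialect for tables: comma-separated, header row,
# '.' decimal separator.
# ---------------------------------------------------------------------------

#' Read and write experiment datasets
#'
#' Delimited text with columns `protocol,x,y[,sd]`. Writing then reading
#' reproduces values to full precision.
#'
#' @param datasets List of [experiment_dataset()]s (or one dataset).
#' @param file Path.
#' @return `read_dataset` returns a named list of [experiment_dataset()]s.
#' @export
write_dataset <- function(datasets, file) {
  if (inherits(datasets, "experiment_dataset")) datasets <- list(datasets)
  tab <- do.call(rbind, lapply(datasets, as.data.frame))
  utils::write.csv(format(tab, digits = 17, trim = TRUE, scientific = NA),
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(file) {
  lines <- readLines(file)
  if (length(lines) < 2L) stop("dataset file ", file, " has no data rows")
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  if (!all(c("protocol", "x", "y") %in% header))
    stop("dataset file must have columns protocol,x,y[,sd]")
  ncol_exp <- length(header)
  fields <- strsplit(lines[-1L], ",", fixed = TRUE)
  bad <- which(lengths(fields) != ncol_exp)
  if (length(bad))
    stop("parse error in ", file, " row ", bad[1L] + 1L, ": expected ",
         ncol_exp, " fields, found ", lengths(fields)[bad[1L]])
  tab <- utils::read.csv(text = paste(lines, collapse = "\n"),
                         stringsAsFactors = FALSE)
  num_cols <- intersect(c("x", "y", "sd"), names(tab))
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(tab[[cc]]))
    if (anyNA(v) && !anyNA(tab[[cc]]))
      stop("parse error in ", file, ": non-numeric value in column ", cc,
           " row ", which(is.na(v))[1L] + 1L)
    tab[[cc]] <- v
  }
  split_tab <- split(tab, factor(tab$protocol, levels = unique(tab$protocol)))
  lapply(split_tab, function(d)
    experiment_dataset(d$protocol[1L], d$x, d$y, sd = d$sd))
}

#' Read and write channel parameter files
#'
#' Flat JSON mapping of exactly the 16 free parameter names to values;
#' unknown or missing keys are rejected with the offending key named.
#'
#' @param params A [rate_params()] vector.
#' @param file Path.
#' @return `read_params` returns a [rate_params()] vector.
#' @export
write_params <- function(params, file) {
  params <- if (inherits(params, "rate_params")) params else rate_params(params)
  jsonlite::write_json(as.list(unclass(params)), file, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(file)
}

#' @rdname write_params
#' @export
read_params <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  rate_params(x)
}

#' Read and write protocol definition files
#'
#' YAML list of named protocols; each entry carries `type`, `sweep`,
#' `holding`, and the type-specific segment fields of [protocol()].
#'
#' @param protocols Named list of [protocol()]s.
#' @param file Path.
#' @return `read_protocols` returns a named list of [protocol()]s.
#' @export
write_protocols <- function(protocols, file) {
  x <- lapply(protocols, function(p) unclass(p))
  yaml::write_yaml(x, file)
  invisible(file)
}

#' @rdname write_protocols
#' @export
read_protocols <- function(file) {
  x <- yaml::read_yaml(file)
  out <- lapply(names(x), function(nm) {
    p <- x[[nm]]
    if (is.null(p$name)) p$name <- nm
    do.call(protocol, p)
  })
  names(out) <- vapply(out, function(p) p$name, character(1))
  out
}

#' Read a drug specification file
#'
#' YAML/JSON mapping with the keys of [drug_spec()] plus optional `charged`
#' and `neutral` scalar blocks ([drug_scalars()]). A bundled
#' `flecainide.yaml` ships in `inst/extdata`.
#'
#' @param file Path.
#' @return List with `spec` ([drug_spec()]) and `scalars`
#'   ([drug_scalars()], or `NULL` if the file has no scalar blocks).
#' @export
read_drug <- function(file) {
  x <- if (grepl("\\.json$", file)) jsonlite::read_json(file, simplifyVector = TRUE)
       else yaml::read_yaml(file)
  sc <- NULL
  if (!is.null(x$charged) || !is.null(x$neutral)) {
    if (is.null(x$charged) || is.null(x$neutral))
      stop("drug file must provide both charged and neutral scalar blocks")
    sc <- drug_scalars(unlist(x$charged), unlist(x$neutral))
    x$charged <- NULL; x$neutral <- NULL
  }
  spec <- do.call(drug_spec, x)
  list(spec = spec, scalars = sc)
}
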