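#' Drug-free channel model
#'
#' Bundles a gating scheme and a parameter vector into a model object whose
#' `factory(V)` returns the master-equation generator at any membrane
#' potential.
#'
#' @param params A [rate_params()] vector.
#' @param scheme A [channel_scheme()]; default [nav_scheme()].
#' @return Object of class `channel_model`.
#' @export
channel_model <- function(params, scheme = nav_scheme()) {
  params <- if (inherits(params, "rate_params")) params else rate_params(params)
  structure(list(
    kind = "drug_free",
    params = params,
    scheme = scheme,
    open_state = scheme$conducting[1],
    factory = function(V) build_generator(scheme, eval_rates(params, V))
  ), class = "channel_model")
}

#' Drug-channel interaction model
#'
#' A channel model extended with charged and neutral drug-bound states (see
#' [build_drug_scheme()]). The generator at each voltage is assembled and
#' cycle-closed on demand.
#'
#' @param params A [rate_params()] vector for the drug-free gating.
#' @param spec A [drug_spec()].
#' @param scalars A [drug_scalars()].
#' @param scheme Base [channel_scheme()].
#' @return Object of class `channel_model`.
#' @export
drug_model <- function(params, spec = flecainide_spec(),
                       scalars = flecainide_scalars(spec),
                       scheme = nav_scheme()) {
  params <- if (inherits(params, "rate_params")) params else rate_params(params)
  structure(list(
    kind = "drug",
    params = params,
    spec = spec,
    scalars = scalars,
    scheme = scheme,
    open_state = scheme$conducting[1],
    factory = function(V) {
      build_drug_scheme(scheme, eval_rates(params, V), spec, scalars, V)$Q
    },
    with_concentration = function(conc) {
      spec2 <- spec
      spec2$concentration <- conc
      drug_model(params, spec2, scalars, scheme)
    }
  ), class = "channel_model")
}

# Per-run simulation context: caches generators, spectral propagators and
# equilibria per voltage.
sim_ctx <- function(model) {
  cache <- new.env(parent = emptyenv())
  get_or <- function(key, make) {
    if (!exists(key, envir = cache, inherits = FALSE))
      assign(key, make(), envir = cache)
    get(key, envir = cache, inherits = FALSE)
  }
  Qof <- function(V) get_or(paste0("Q@", V), function() model$factory(V))
  list(
    model = model,
    Q = Qof,
    prop = function(V) get_or(paste0("P@", V),
                              function() make_propagator(Qof(V))),
    equil = function(V) get_or(paste0("E@", V),
                               function() equilibrium_distribution(Qof(V)))
  )
}

ctx_step <- function(ctx, p0, V, dur) {
  as.numeric(ctx$prop(V)(p0, dur))
}

ctx_trace <- function(ctx, p0, V, dur, dt) {
  tt <- unique(c(seq(0, dur, by = dt), dur))
  p <- ctx$prop(V)(p0, tt)
  structure(list(time = tt, p = p, V = V), class = "occupancy_trace")
}

# Peak open occupancy during a constant-voltage segment, refined on the
# analytic segment solution.
ctx_peak <- function(ctx, p0, V, dur, dt) {
  open <- ctx$model$open_state
  prop <- ctx$prop(V)
  Q <- ctx$Q(V)
  trace <- ctx_trace(ctx, p0, V, dur, dt)
  f <- function(t) as.numeric(prop(p0, t)[open, 1])
  df <- function(t) as.numeric((Q %*% prop(p0, t))[open, 1])
  pk <- peak_open(trace, state = open, refine = f, deriv = df)
  list(value = pk$value, time = pk$time, trace = trace)
}

#' Voltage-clamp protocol definition
#'
#' Declarative description of a clamp experiment. Each protocol has a type
#' (which fixes the segment structure and readout), a holding potential,
#' type-specific segment voltages/durations, and exactly one sweep axis.
#' Types and their sweep axes:
#' \describe{
#'   \item{ssa}{steady-state availability; sweep = conditioning voltage (mV);
#'     readout = normalized test-pulse peak.}
#'   \item{act}{steady-state activation; sweep = test voltage (mV); readout =
#'     normalized peak open occupancy.}
#'   \item{rfi}{recovery from inactivation; sweep = recovery interval (ms);
#'     readout = P2/P1 peak ratio.}
#'   \item{rudb}{recovery after a pulse train; sweep = recovery interval
#'     (ms); readout = test peak / first-pulse peak.}
#'   \item{tau50}{time to 50% decay; sweep = test voltage (mV); readout =
#'     Tau50 (ms).}
#'   \item{mot}{mean open time; sweep = voltage (mV); readout = MOT (ms).}
#'   \item{tb}{tonic block; sweep = drug concentration (M); readout = peak
#'     relative to the drug-free peak.}
#'   \item{udb}{use-dependent block; sweep = drug concentration (M); readout
#'     = last/first pulse peak ratio.}
#'   \item{fdudb}{frequency-dependent UDB; sweep = train frequency (Hz);
#'     readout = last/first pulse peak ratio.}
#' }
#'
#' @param name Protocol name (used to match datasets).
#' @param type One of the types above.
#' @param sweep Numeric vector of sweep-axis values.
#' @param holding Holding potential (mV).
#' @param ... Type-specific fields (`cond_dur`, `test_v`, `test_dur`,
#'   `p1_v`, `p1_dur`, `rec_v`, `p2_v`, `p2_dur`, `pulse_v`, `pulse_dur`,
#'   `n_pulses`, `freq`, `conc`).
#' @return Object of class `voltage_protocol`.
#' @export
protocol <- function(name, type, sweep, holding = -100, ...) {
  type <- match.arg(type, c("ssa", "act", "rfi", "rudb", "tau50", "mot",
                            "tb", "udb", "fdudb"))
  extra <- list(...)
  p <- c(list(name = name, type = type, sweep = as.numeric(sweep),
              holding = holding), extra)
  if (length(p$sweep) < 1L) stop("protocol needs at least one sweep value")
  durs <- unlist(p[grepl("_dur$", names(p))])
  if (length(durs) && any(durs <= 0)) stop("segment durations must be > 0")
  if (!is.null(p$freq) && !is.null(p$pulse_dur) &&
      any(p$freq * p$pulse_dur >= 1000))
    stop("pulse duration exceeds the train period at the given frequency")
  structure(p, class = "voltage_protocol")
}

#' Bundled drug-free protocol set
#'
#' The six protocols used to constrain the drug-free channel: steady-state
#' availability (SSA, 9 conditioning voltages), steady-state activation
#' (ACT), recovery from inactivation at -100 mV (RFI), recovery after a
#' 10-Hz pulse train (RUDB), time to 50% current decay (TAU50), and mean
#' open time at -30 mV (MOT). Voltages and durations not printed in the
#' source literature are package defaults; all are editable via
#' [read_protocols()] files.
#'
#' @return Named list of [protocol()] objects.
#' @export
default_protocols <- function() {
  list(
    SSA = protocol("SSA", "ssa", sweep = seq(-130, -50, by = 10),
                   holding = -120, cond_dur = 500, test_v = -20,
                   test_dur = 25),
    ACT = protocol("ACT", "act", sweep = seq(-75, 15, by = 10),
                   holding = -120, test_dur = 25),
    RFI = protocol("RFI", "rfi",
                   sweep = c(1, 3, 10, 30, 100, 300, 1000, 3000),
                   holding = -100, p1_v = -20, p1_dur = 100, rec_v = -100,
                   p2_v = -20, p2_dur = 25),
    RUDB = protocol("RUDB", "rudb",
                    sweep = c(1, 3, 10, 30, 100, 300, 1000, 3000),
                    holding = -100, pulse_v = -20, pulse_dur = 25,
                    n_pulses = 50, freq = 10, test_v = -20, test_dur = 25),
    TAU50 = protocol("TAU50", "tau50", sweep = seq(-40, 10, by = 10),
                     holding = -120, test_dur = 100),
    MOT = protocol("MOT", "mot", sweep = -30)
  )
}

#' Bundled drug-block protocol set
#'
#' The five protocols used to constrain drug binding: steady-state
#' availability in drug (SSA_DRUG), tonic block (TB), use-dependent block at
#' 10 Hz (UDB, 10 and 100 uM), recovery from UDB (RUDB_DRUG, 100 uM), and
#' frequency-dependent UDB (FDUDB).
#'
#' @param conc Concentration (M) for the fixed-concentration protocols.
#' @return Named list of [protocol()] objects.
#' @export
drug_protocols <- function(conc = 100e-6) {
  list(
    SSA_DRUG = protocol("SSA_DRUG", "ssa", sweep = seq(-130, -50, by = 10),
                        holding = -120, cond_dur = 500, test_v = -20,
                        test_dur = 25),
    TB = protocol("TB", "tb", sweep = c(10e-6, 100e-6), holding = -100,
                  test_v = -20, test_dur = 25),
    UDB = protocol("UDB", "udb", sweep = c(10e-6, 100e-6), holding = -100,
                   pulse_v = -20, pulse_dur = 25, n_pulses = 30, freq = 10),
    RUDB_DRUG = protocol("RUDB_DRUG", "rudb",
                         sweep = c(1, 3, 10, 30, 100, 300, 1000, 3000),
                         holding = -100, pulse_v = -20, pulse_dur = 25,
                         n_pulses = 30, freq = 10, test_v = -20,
                         test_dur = 25, conc = conc),
    FDUDB = protocol("FDUDB", "fdudb", sweep = c(2, 5, 10, 20),
                     holding = -100, pulse_v = -20, pulse_dur = 25,
                     n_pulses = 30, conc = conc)
  )
}

# Run a pulse train and return the end-of-train occupancy plus the peaks of
# the first and last pulses.
run_train <- function(ctx, p0, pulse_v, pulse_dur, holding, freq, n_pulses,
                      dt) {
  rest <- 1000 / freq - pulse_dur
  first <- ctx_peak(ctx, p0, pulse_v, pulse_dur, dt)
  p <- ctx_step(ctx, p0, pulse_v, pulse_dur)
  p <- ctx_step(ctx, p, holding, rest)
  if (n_pulses > 2L) {
    for (k in seq_len(n_pulses - 2L)) {
      p <- ctx_step(ctx, p, pulse_v, pulse_dur)
      p <- ctx_step(ctx, p, holding, rest)
    }
  }
  last <- ctx_peak(ctx, p, pulse_v, pulse_dur, dt)
  p_end <- ctx_step(ctx, p, pulse_v, pulse_dur)
  list(first = first$value, last = last$value, p_end = p_end)
}

#' Simulate a voltage-clamp protocol
#'
#' Runs every sweep of a protocol against a model. The initial occupancy of
#' each sweep is the stationary distribution at the holding potential (for
#' drug models this is the drug-equilibrated state). Sweeps are mutually
#' independent; permuting the sweep axis permutes the results.
#'
#' @param model A [channel_model()] or [drug_model()].
#' @param protocol A [protocol()].
#' @param sample_dt Trace sampling interval (ms) for peak bracketing;
#'   readouts are refined on the analytic segment solution and are
#'   insensitive to this value.
#' @param store_traces Keep per-sweep occupancy traces in the result.
#' @return Object of class `sweep_results`: data frame `readouts` with
#'   columns `x`, `y`, plus `sweeps` (list of per-sweep detail) when
#'   `store_traces = TRUE`.
#' @export
run_protocol <- function(model, protocol, sample_dt = 0.05,
                         store_traces = FALSE) {
  stopifnot(inherits(model, "channel_model"),
            inherits(protocol, "voltage_protocol"))
  pr <- protocol
  type <- pr$type
  sweeps <- pr$sweep
  traces <- if (store_traces) vector("list", length(sweeps)) else NULL

  if (type == "mot") {
    y <- vapply(sweeps, function(V) {
      if (model$kind == "drug_free") {
        mean_open_time(model$params, V)
      } else {
        Q <- model$factory(V)
        1 / (-Q[model$open_state, model$open_state])
      }
    }, numeric(1))
    return(structure(list(
      protocol = pr$name,
      readouts = data.frame(x = sweeps, y = y),
      sweeps = traces
    ), class = "sweep_results"))
  }

  if (type %in% c("tb", "udb")) {
    if (model$kind != "drug") stop("protocol ", pr$name, " requires a drug model")
    pk0 <- if (type == "tb") {
      ref <- sim_ctx(model$with_concentration(0))
      ctx_peak(ref, ref$equil(pr$holding), pr$test_v, pr$test_dur,
               sample_dt)$value
    } else NA_real_
    y <- vapply(sweeps, function(conc) {
      m <- model$with_concentration(conc)
      ctx <- sim_ctx(m)
      p0 <- ctx$equil(pr$holding)
      if (type == "tb") {
        pk <- ctx_peak(ctx, p0, pr$test_v, pr$test_dur, sample_dt)$value
        pk / pk0
      } else {
        tr <- run_train(ctx, p0, pr$pulse_v, pr$pulse_dur, pr$holding,
                        pr$freq, pr$n_pulses, sample_dt)
        tr$last / tr$first
      }
    }, numeric(1))
    return(structure(list(
      protocol = pr$name,
      readouts = data.frame(x = sweeps, y = y),
      sweeps = traces
    ), class = "sweep_results"))
  }

  if (type == "fdudb") {
    m <- if (model$kind == "drug" && !is.null(pr$conc))
      model$with_concentration(pr$conc) else model
    ctx <- sim_ctx(m)
    p0 <- ctx$equil(pr$holding)
    y <- vapply(sweeps, function(freq) {
      tr <- run_train(ctx, p0, pr$pulse_v, pr$pulse_dur, pr$holding,
                      freq, pr$n_pulses, sample_dt)
      tr$last / tr$first
    }, numeric(1))
    return(structure(list(
      protocol = pr$name,
      readouts = data.frame(x = sweeps, y = y),
      sweeps = traces
    ), class = "sweep_results"))
  }

  m <- if (model$kind == "drug" && !is.null(pr$conc))
    model$with_concentration(pr$conc) else model
  ctx <- sim_ctx(m)
  p0 <- ctx$equil(pr$holding)

  y <- numeric(length(sweeps))
  for (i in seq_along(sweeps)) {
    s <- sweeps[i]
    if (type == "ssa") {
      p <- ctx_step(ctx, p0, s, pr$cond_dur)
      pk <- ctx_peak(ctx, p, pr$test_v, pr$test_dur, sample_dt)
      y[i] <- pk$value
    } else if (type == "act") {
      pk <- ctx_peak(ctx, p0, s, pr$test_dur, sample_dt)
      y[i] <- pk$value
    } else if (type == "rfi") {
      pk1 <- ctx_peak(ctx, p0, pr$p1_v, pr$p1_dur, sample_dt)
      p <- ctx_step(ctx, p0, pr$p1_v, pr$p1_dur)
      p <- ctx_step(ctx, p, pr$rec_v, s)
      pk2 <- ctx_peak(ctx, p, pr$p2_v, pr$p2_dur, sample_dt)
      y[i] <- pk2$value / pk1$value
      pk <- pk2
    } else if (type == "rudb") {
      tr <- run_train(ctx, p0, pr$pulse_v, pr$pulse_dur, pr$holding,
                      pr$freq, pr$n_pulses, sample_dt)
      p <- ctx_step(ctx, tr$p_end, pr$holding, s)
      pk <- ctx_peak(ctx, p, pr$test_v, pr$test_dur, sample_dt)
      y[i] <- pk$value / tr$first
    } else if (type == "tau50") {
      prop <- ctx$prop(s)
      Q <- ctx$Q(s)
      f <- function(t) as.numeric(prop(p0, t)[m$open_state, 1])
      df <- function(t) as.numeric((Q %*% prop(p0, t))[m$open_state, 1])
      trace <- ctx_trace(ctx, p0, s, pr$test_dur, sample_dt)
      y[i] <- time_to_half_decay(trace, state = m$open_state, refine = f,
                                 deriv = df)
      pk <- list(trace = trace)
    } else {
      stop("protocol definition error: unknown readout for type ", type)
    }
    if (store_traces) traces[[i]] <- list(sweep = s, trace = pk$trace)
  }
  if (type %in% c("ssa", "act")) y <- y / max(y)
  structure(list(
    protocol = pr$name,
    readouts = data.frame(x = sweeps, y = y),
    sweeps = traces
  ), class = "sweep_results")
}

#' @export
print.sweep_results <- function(x, ...) {
  cat("Protocol", x$protocol, "readouts:\n")
  print(x$readouts, row.names = FALSE)
  invisible(x)
}

#' Simulate readouts for a set of protocols
#'
#' @param model A [channel_model()] or [drug_model()].
#' @param protocols Named list of [protocol()] objects.
#' @param sample_dt Trace sampling interval (ms).
#' @return Data frame with columns `protocol`, `x`, `y`.
#' @export
simulate_readouts <- function(model, protocols, sample_dt = 0.05) {
  out <- lapply(protocols, function(pr) {
    r <- run_protocol(model, pr, sample_dt = sample_dt)
    cbind(protocol = pr$name, r$readouts)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
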