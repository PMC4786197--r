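#' Physical constants used in Eyring voltage dependence
#'
#' Faraday's constant `F` (C mol^-1) and the gas constant `R`
#' (mJ mol^-1 K^-1), in the unit system that pairs with membrane potentials
#' in millivolts.
#' @return Named list with `F` and `R`.
#' @export
physical_constants <- function() {
  list(F = 96485.3415, R = 8314.472)
}

#' Charged fraction of a weak base (Henderson-Hasselbalch)
#'
#' Fraction of the protonated (charged) species of a weak base at a given
#' pH: `1 / (1 + 10^(pH - pKa))`. For flecainide (pKa 9.3) at physiological
#' pH 7.4 this is about 0.988.
#'
#' @param pKa Acid dissociation constant of the conjugate acid.
#' @param pH Solution pH.
#' @return Fraction in (0, 1).
#' @export
charged_fraction <- function(pKa, pH = 7.4) {
  stopifnot(is.finite(pKa), is.finite(pH))
  1 / (1 + 10^(pH - pKa))
}

#' Voltage-dependent dissociation constant (Eyring)
#'
#' `Kd(V) = Kd0 * exp(-d * V * F / (R * T))`, placing the fraction `d` of
#' the membrane electric field at the binding site. With `d > 0` the
#' affinity of a cationic blocker for its site weakens (Kd grows) as the
#' membrane hyperpolarizes.
#'
#' @param Kd0 Dissociation constant at 0 mV (M).
#' @param V Membrane potential (mV); may be a vector.
#' @param d Fractional electrical charge/electrical distance, in `[0, 1]`.
#' @param T Absolute temperature (K).
#' @return Kd at each `V`, in M.
#' @export
eyring_kd <- function(Kd0, V, d = 0.7, T = 295) {
  stopifnot(Kd0 > 0, d >= 0, d <= 1, T > 0)
  pc <- physical_constants()
  Kd0 * exp(-d * V * pc$F / (pc$R * T))
}

#' Diffusion-limited binding rates
#'
#' `kon = concentration * D` and `koff = Kd * D`, so `koff/kon = Kd/conc`.
#'
#' @param concentration Free drug concentration (M); zero allowed.
#' @param D Diffusion rate (M^-1 ms^-1).
#' @param Kd Dissociation constant (M).
#' @return Named list `kon`, `koff` (ms^-1).
#' @export
binding_rates <- function(concentration, D, Kd) {
  stopifnot(concentration >= 0, D > 0, Kd > 0)
  list(kon = concentration * D, koff = Kd * D)
}

#' Physicochemical drug specification
#'
#' Fixed, measured drug constants (they are never optimized). Defaults are
#' bundled for flecainide; see [flecainide_spec()].
#'
#' @param pKa Conjugate-acid pKa.
#' @param pH Solution pH.
#' @param diffusion Diffusion rate D (M^-1 ms^-1).
#' @param concentration Total drug concentration (M).
#' @param d Fractional electrical charge sensed by the bound charged drug.
#' @param T Temperature (K).
#' @param kd0_charged_open Kd of charged drug for the open state at 0 mV (M).
#' @param kd_neutral_open,kd_neutral_closed,kd_neutral_inactivated Neutral
#'   drug Kds (M).
#' @param v_ref_closed Reference potential (mV) at which the charged
#'   closed-state Kd is evaluated via [eyring_kd()].
#' @return List of class `drug_spec`.
#' @export
drug_spec <- function(pKa, pH = 7.4, diffusion, concentration,
                      d = 0.7, T = 295,
                      kd0_charged_open,
                      kd_neutral_open, kd_neutral_closed,
                      kd_neutral_inactivated,
                      v_ref_closed = -100) {
  spec <- list(pKa = pKa, pH = pH, diffusion = diffusion,
               concentration = concentration, d = d, T = T,
               kd0_charged_open = kd0_charged_open,
               kd_neutral_open = kd_neutral_open,
               kd_neutral_closed = kd_neutral_closed,
               kd_neutral_inactivated = kd_neutral_inactivated,
               v_ref_closed = v_ref_closed)
  num <- unlist(spec)
  if (any(!is.finite(num))) stop("drug_spec values must be finite")
  pos <- c("pKa", "pH", "diffusion", "T", "kd0_charged_open",
           "kd_neutral_open", "kd_neutral_closed", "kd_neutral_inactivated")
  if (any(unlist(spec[pos]) <= 0)) stop("drug_spec constants must be positive")
  if (spec$concentration < 0) stop("concentration must be >= 0")
  if (spec$d < 0 || spec$d > 1) stop("d must lie in [0, 1]")
  class(spec) <- "drug_spec"
  spec
}

#' Flecainide drug specification
#'
#' Bundled constants for flecainide: pKa 9.3 (about 99% charged at pH 7.4),
#' diffusion 5500 M^-1 ms^-1 (model value), charged open-state Kd0 11.2 uM
#' with Eyring voltage dependence (d = 0.7, T = 295 K; the closed-state
#' charged Kd evaluated at -100 mV is 175.8 uM), and neutral-analog Kds of
#' 400 uM (open), 800 uM (closed), 5.4 uM (inactivated).
#'
#' @param concentration Total flecainide concentration (M).
#' @return A [drug_spec()].
#' @export
flecainide_spec <- function(concentration = 10e-6) {
  drug_spec(
    pKa = 9.3, pH = 7.4, diffusion = 5500, concentration = concentration,
    d = 0.7, T = 295,
    kd0_charged_open = 11.2e-6,
    kd_neutral_open = 400e-6,
    kd_neutral_closed = 800e-6,
    kd_neutral_inactivated = 5.4e-6
  )
}

#' Free drug-bound rate scalars
#'
#' The 8 free charged scalars (`ax1, bx1, a13c, a22, b33, a33, a44, b44`)
#' and 8 free neutral scalars (`ax2, a13n, a_22, b_33, a_44, b_44, ki_on,
#' ki_off`). With the exception of `ki_on` (M^-1 ms^-1, multiplies the
#' neutral concentration to give the inactivated-state on-rate) and `ki_off`
#' (ms^-1, the inactivated-state off-rate), each scalar multiplies the
#' corresponding drug-free rate on its drug-bound edge; the remaining
#' drug-bound rates are constrained by microscopic reversibility (see
#' [build_drug_scheme()]).
#'
#' @param charged Named numeric vector with `ax1, bx1, a13c, a22, b33, a33,
#'   a44, b44` (all > 0).
#' @param neutral Named numeric vector with `ax2, a13n, a_22, b_33, a_44,
#'   b_44, ki_on, ki_off` (all > 0).
#' @return List of class `drug_scalars`.
#' @export
drug_scalars <- function(charged, neutral) {
  cn <- charged_scalar_names(); nn <- neutral_scalar_names()
  charged <- unlist(charged); neutral <- unlist(neutral)
  if (!setequal(names(charged), cn))
    stop("charged scalars must be exactly: ", paste(cn, collapse = ", "))
  if (!setequal(names(neutral), nn))
    stop("neutral scalars must be exactly: ", paste(nn, collapse = ", "))
  charged <- charged[cn]; neutral <- neutral[nn]
  if (any(!is.finite(c(charged, neutral))) || any(c(charged, neutral) <= 0))
    stop("drug scalars must be strictly positive and finite")
  structure(list(charged = charged, neutral = neutral), class = "drug_scalars")
}

#' @rdname drug_scalars
#' @export
charged_scalar_names <- function() {
  c("ax1", "bx1", "a13c", "a22", "b33", "a33", "a44", "b44")
}

#' @rdname drug_scalars
#' @export
neutral_scalar_names <- function() {
  c("ax2", "a13n", "a_22", "b_33", "a_44", "b_44", "ki_on", "ki_off")
}

#' Default flecainide rate scalars
#'
#' Charged defaults are the converged best-fit charged flecainide scalars;
#' neutral defaults are 1 (drug-bound rate equal to the drug-free rate),
#' with `ki_on` defaulting to the diffusion rate and `ki_off` to
#' `Kd_inactivated * D`.
#'
#' @param spec A [drug_spec()] supplying the defaults for `ki_on`/`ki_off`.
#' @return A [drug_scalars()].
#' @export
flecainide_scalars <- function(spec = flecainide_spec()) {
  drug_scalars(
    charged = c(ax1 = 1.0836e-5, bx1 = 4.2106e-8, a13c = 2.4824e-3,
                a22 = 1.2663e2, b33 = 4.8810e-6, a33 = 1.8309e-4,
                a44 = 2.5183, b44 = 4.6378e-2),
    neutral = c(ax2 = 1, a13n = 1, a_22 = 1, b_33 = 1, a_44 = 1, b_44 = 1,
                ki_on = spec$diffusion,
                ki_off = spec$kd_neutral_inactivated * spec$diffusion)
  )
}

# ---------------------------------------------------------------------------
# Extended (drug-bound) scheme construction.
#
# Charged mode: mirror states DC3, DC2, DC1, DO, DIC3, DIC2, DIF, DIS plus
# the trapped inactivated state DIT; binding to open (Eyring Kd at the
# instantaneous V) and closed states (Eyring Kd at the reference potential);
# no direct binding to inactivated states. Neutral mode: mirror states
# NC3 ... NIS; binding to closed, open, and the fast-inactivated row
# (IC3, IC2, IF) via ki_on/ki_off; NIS is reached by gating only.
#
# Scaled edges carry "<label>.<scalar>" labels; edges whose label ends in
# ".mr" are solved by close_cycles. The default edge map is returned as part
# of the extended scheme and can be inspected or overridden.
# ---------------------------------------------------------------------------

drug_edge_map <- function() {
  chg <- data.frame(
    from = c("DIC3", "DIC2", "DC3", "DC2", "DC1", "DC3", "DC2", "DC1",
             "DO", "DO", "DO"),
    to   = c("DIC2", "DIF", "DC2", "DC1", "DO", "DIC3", "DIC2", "DIF",
             "DIF", "DIS", "DIT"),
    fwd_base = c("a11", "a12", "a11", "a12", "a13", "b3", "b3", "b3",
                 "a2", "ax", "a2"),
    fwd_scalar = c("", "", "", "", "a13c", "b33", "b33", "b33",
                   "a22", "ax1", "a44"),
    rev_base = c("b11", "b12", "b11", "b12", "a13", "a3", "a3", "a3",
                 "a2", "bx", "b2"),
    rev_scalar = c("", "", "", "", ".mr", "a33", "a33", "a33",
                   ".mr", "bx1", "b44"),
    stringsAsFactors = FALSE
  )
  neu <- data.frame(
    from = c("NIC3", "NIC2", "NC3", "NC2", "NC1", "NC3", "NC2", "NC1",
             "NO", "NO"),
    to   = c("NIC2", "NIF", "NC2", "NC1", "NO", "NIC3", "NIC2", "NIF",
             "NIF", "NIS"),
    fwd_base = c("a11", "a12", "a11", "a12", "a13", "b3", "b3", "b3",
                 "a2", "ax"),
    fwd_scalar = c("", "", "", "", "a13n", "b_33", "b_33", "b_44",
                   "a_22", "ax2"),
    rev_base = c("b11", "b12", "b11", "b12", "a13", "a3", "a3", "a3",
                 "a2", "bx"),
    rev_scalar = c("", "", "", "", ".mr", ".mr", ".mr", ".mr",
                   ".mr", "a_44"),
    stringsAsFactors = FALSE
  )
  list(charged = chg, neutral = neu,
       charged_binding = c(O = "DO", C3 = "DC3", C2 = "DC2", C1 = "DC1"),
       neutral_binding = c(O = "NO", C3 = "NC3", C2 = "NC2", C1 = "NC1",
                           IC3 = "NIC3", IC2 = "NIC2", IF = "NIF"))
}

#' Extend the channel scheme with drug-bound states
#'
#' Builds the full drug-channel interaction scheme at a membrane potential
#' `V`: the 8 drug-free states plus charged-bound (DC3...DO, DIC3...DIS, and
#' the trapped inactivated state DIT) and neutral-bound (NC3...NIS) mirror
#' states. Binding edges use `kon = conc_frac * D` and `koff = Kd * D`, with
#' the charged open-state Kd following the Eyring voltage dependence at the
#' instantaneous `V`, the charged closed-state Kd evaluated once at
#' `spec$v_ref_closed`, and the neutral inactivated-row binding given by the
#' free `ki_on`/`ki_off` scalars. Drug-bound gating rates are scalar
#' multiples of the drug-free rates per the default edge map
#' ([drug_scalars()]); every remaining rate is solved by [close_cycles()] so
#' that all cycles satisfy detailed balance. Because every base/bound cycle
#' crosses the binding interface an even number of times, the solved gating
#' rates are independent of concentration; they are computed at unit
#' concentration, which keeps the scheme well defined at
#' `concentration = 0`.
#'
#' @param base A [channel_scheme()] (the drug-free scheme).
#' @param base_rates A `rate_set` from [eval_rates()] at the same `V`.
#' @param spec A [drug_spec()].
#' @param scalars A [drug_scalars()].
#' @param V Membrane potential (mV).
#' @param edge_map Optional override of the default drug-bound edge map.
#' @return List of class `extended_model`: `scheme` (the extended
#'   [channel_scheme()]), `rates` (closed rate vector), `Q` (generator),
#'   `map` (edge map used).
#' @export
build_drug_scheme <- function(base, base_rates, spec, scalars, V,
                              edge_map = drug_edge_map()) {
  stopifnot(inherits(spec, "drug_spec"), inherits(scalars, "drug_scalars"))
  fc <- charged_fraction(spec$pKa, spec$pH)
  conc_c <- spec$concentration * fc
  conc_n <- spec$concentration * (1 - fc)
  D <- spec$diffusion
  kd_open_c <- eyring_kd(spec$kd0_charged_open, V, spec$d, spec$T)
  kd_closed_c <- eyring_kd(spec$kd0_charged_open, spec$v_ref_closed,
                           spec$d, spec$T)

  sc <- c(scalars$charged, scalars$neutral)
  mk_mode <- function(tab, tag) {
    lab <- function(base_lab, scalar, dir, i) {
      if (scalar == ".mr") return(paste0(tag, i, dir, ".mr"))
      if (scalar == "") return(base_lab)          # tied to drug-free rate
      paste0(tag, ".", scalar, ".", base_lab)
    }
    data.frame(
      from = tab$from, to = tab$to,
      fwd = mapply(lab, tab$fwd_base, tab$fwd_scalar, "f", seq_len(nrow(tab))),
      rev = mapply(lab, tab$rev_base, tab$rev_scalar, "r", seq_len(nrow(tab))),
      stringsAsFactors = FALSE
    )
  }
  chg_edges <- mk_mode(edge_map$charged, "c")
  neu_edges <- mk_mode(edge_map$neutral, "n")

  bind_edges <- function(map, tag) {
    data.frame(
      from = names(map), to = unname(map),
      fwd = paste0("kon.", tag, ".", names(map)),
      rev = paste0("koff.", tag, ".", names(map)),
      stringsAsFactors = FALSE
    )
  }
  cb <- bind_edges(edge_map$charged_binding, "c")
  nb <- bind_edges(edge_map$neutral_binding, "n")

  states <- c(base$states,
              unique(c(edge_map$charged$from, edge_map$charged$to)),
              unique(c(edge_map$neutral$from, edge_map$neutral$to)))
  ext <- channel_scheme(
    states = states,
    edges = rbind(base$edges, chg_edges, neu_edges, cb, nb),
    conducting = base$conducting
  )

  # rate values: tied labels come from base_rates; scaled labels computed;
  # ".mr" labels left NA for close_cycles.
  rates <- as.numeric(base_rates)
  names(rates) <- names(base_rates)
  scaled_value <- function(tab, tag) {
    out <- numeric(0)
    for (i in seq_len(nrow(tab))) {
      for (dir in c("fwd", "rev")) {
        scl <- tab[[paste0(dir, "_scalar")]][i]
        bl <- tab[[paste0(dir, "_base")]][i]
        if (scl %in% c("", ".mr")) next
        out[paste0(tag, ".", scl, ".", bl)] <- sc[[scl]] * base_rates[[bl]]
      }
    }
    out
  }
  rates <- c(rates, scaled_value(edge_map$charged, "c"),
             scaled_value(edge_map$neutral, "n"))

  # binding rates at unit concentration for cycle closure
  kon_unit_c <- fc * D
  kon_unit_n <- (1 - fc) * D
  koff_c <- c(O = kd_open_c * D,
              C3 = kd_closed_c * D, C2 = kd_closed_c * D, C1 = kd_closed_c * D)
  koff_n <- c(O = spec$kd_neutral_open * D,
              C3 = spec$kd_neutral_closed * D, C2 = spec$kd_neutral_closed * D,
              C1 = spec$kd_neutral_closed * D,
              IC3 = sc[["ki_off"]], IC2 = sc[["ki_off"]], IF = sc[["ki_off"]])
  kon_n_unit <- c(O = kon_unit_n, C3 = kon_unit_n, C2 = kon_unit_n,
                  C1 = kon_unit_n,
                  IC3 = (1 - fc) * sc[["ki_on"]], IC2 = (1 - fc) * sc[["ki_on"]],
                  IF = (1 - fc) * sc[["ki_on"]])
  unit <- rates
  for (s in names(edge_map$charged_binding)) {
    unit[paste0("kon.c.", s)] <- kon_unit_c
    unit[paste0("koff.c.", s)] <- koff_c[[s]]
  }
  for (s in names(edge_map$neutral_binding)) {
    unit[paste0("kon.n.", s)] <- kon_n_unit[[s]]
    unit[paste0("koff.n.", s)] <- koff_n[[s]]
  }
  mr_labels <- grep("\\.mr$", c(ext$edges$fwd, ext$edges$rev), value = TRUE)
  unit[mr_labels] <- NA_real_
  unit <- close_cycles(ext, unit)

  # substitute true concentration into the binding on-rates
  rates <- unit
  for (s in names(edge_map$charged_binding))
    rates[paste0("kon.c.", s)] <- conc_c * D
  for (s in names(edge_map$neutral_binding)) {
    kon1 <- if (s %in% c("IC3", "IC2", "IF")) sc[["ki_on"]] else D
    rates[paste0("kon.n.", s)] <- conc_n * kon1
  }
  attr(rates, "V") <- V
  Q <- build_generator(ext, rates)
  structure(list(scheme = ext, rates = rates, Q = Q, map = edge_map,
                 V = V, spec = spec, scalars = scalars),
            class = "extended_model")
}
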