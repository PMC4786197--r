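---
title: "Markov-state modeling and fitting of sodium channel kinetics and drug block"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markov-state modeling and fitting of sodium channel kinetics and drug block}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(navfit)
```

## The gating model and its assumptions

`navfit` models the cardiac Na⁺ channel as a continuous-time Markov chain
over 8 conformational states: three closed states (C3, C2, C1), one
conducting open state (O), fast- and slow-inactivated states (IF, IS), and
two closed-inactivated states (IC3, IC2). This coupled-state formulation —
as opposed to independent Hodgkin–Huxley gates — represents specific channel
conformations explicitly, which is what makes state-dependent phenomena
(closed-state inactivation, use-dependent drug block) expressible at all.
The scheme has 10 reversible transitions: the activation row C3–C2–C1–O,
the inactivated row IC3–IC2–IF, three closed/closed-inactivated verticals,
open-state fast inactivation O–IF, and slow inactivation O–IS.

Occupancies obey the master equation `dP/dt = Q·P`. We use the
columns-as-source convention — `Q[j, i]` is the rate from state `i` to
state `j` — so each column of `Q` sums to zero; this is asserted in tests
and in `build_generator()` itself.

### Rates and free parameters

Eleven independent voltage-dependent rates are built from 16 strictly
positive free parameters (`rate_params()`); see the README or `eval_rates()`
for the functional forms. Three structural conventions matter:

* The linked multipliers `a12, a13, b12, b13` tie the second and third
  activation (deactivation) steps to the principal rates `α11` (`β11`).
  Their reference value is 1, i.e. all activation steps initially equal.
* Slow inactivation is tied to the open-inactivation and recovery rates:
  `αx = ax·α2` with `ax = 1/20`, and `βx = bx·α3` with `bx = 1/45` in the
  reference set — the literature-anchored proportionalities for these
  poorly-isolated transitions.
* The backward rate `β2` (IF→O) is **never** a parameter. It is computed as
  `β2 = α13·α2·α3/(β13·β3)`, which closes the C1–O–IF loop so that the
  product of forward rates equals the product of reverse rates around every
  cycle (microscopic reversibility). Enforcing the constraint by
  construction, rather than by penalty, makes detailed balance an invariant
  rather than an optimization target; `cycle_residuals()` verifies it over
  a cycle basis of the scheme graph.

The reference parameter set (`default_params()`) was chosen once to give
physiological wild-type kinetics — availability midpoint near −72 mV, fast
activation, mean open time ≈ 0.28 ms at −30 mV, double-exponential recovery
at −100 mV with a ~6 ms fast and a several-hundred-ms slow component — and
serves as the generating truth for all synthetic-data studies. Exponentials
are evaluated in log space and capped at `e^700`, so extreme voltages
visited by the optimizer produce large-but-finite rates instead of
overflow.

One naming note: the inactivated row is IC3, IC2, IF; the state sometimes
called "IC1" in loose usage is IF here, which doubles as the fast
inactivated state reachable from O.

## The drug extension

Drug block mirrors the 8-state scheme into two drug-bound modes:

* **Charged mode** (states DC3…DO, DIC3…DIF, DIS, plus a trapped
  inactivated state DIT reachable from DO): the charged species binds only
  to the open state — with Eyring voltage-dependent affinity
  `Kd(V) = Kd₀·e^(−d·V·F/(R·T))` evaluated at the instantaneous membrane
  potential — and to the closed states, with `Kd` evaluated once at a
  reference potential of −100 mV (the conventional closed-state estimate;
  configurable via `drug_spec(v_ref_closed=)`). It does not bind
  inactivated states directly.
* **Neutral mode** (NC3…NO, NIC3…NIF, NIS): the neutral species binds
  closed, open, and the fast-inactivated row (IC3, IC2, IF). NIS is reached
  by gating only.

The charged/neutral split of the total concentration follows
Henderson–Hasselbalch: `charged fraction = 1/(1+10^(pH−pKa))`. Binding is
diffusion-limited: `kon = concentration·D`, `koff = Kd·D`.

### Free scalars and cycle closure

Each drug-bound gating rate is a scalar multiple of its drug-free
counterpart. Eight charged scalars (`ax1, bx1, a13c, a22, b33, a33, a44,
b44`) and eight neutral scalars (`ax2, a13n, a_22, b_33, a_44, b_44,
ki_on, ki_off`) are free; every remaining drug-bound rate is solved by
`close_cycles()` so that all cycles of the extended graph satisfy detailed
balance. Two of the neutral names have non-multiplier semantics: `ki_on`
(M⁻¹ms⁻¹) multiplies the neutral concentration to give the
inactivated-row on-rate, and `ki_off` (ms⁻¹) is that row's off-rate
directly. They must scale with concentration — otherwise the extended model
would not collapse to the drug-free model at zero concentration, which is a
hard invariant of the package (verified to ~1e−12 in tests).

The default edge map (`drug_scalars()` documentation, configurable through
`build_drug_scheme(edge_map=)`) was chosen by degrees-of-freedom counting.
The closure algebra is a linear system on log-rates over the cycle space of
the extended graph: every independent cycle must end with zero log-residual.
Cycles made only of tied (unscaled) and shared-affinity edges close
structurally; each remaining cycle needs exactly one solvable rate. The
default map allocates the 16 free scalars so that the partition
"free + structurally-closed + solved" exactly exhausts the cycle space:
with binding to inactivated states present, each vertical pair of the
neutral mode can carry at most one free direction, with the reverse rate
solved through the thermodynamic cycle that runs through the binding edges.
Mis-allocations are not silently accepted: `close_cycles()` raises an
over-constrained-cycle error (a test exercises exactly this failure mode).

A useful property falls out of the topology: every cycle crosses the
bound/unbound interface an even number of times, so the drug concentration
cancels from every closure equation. The solved gating rates are therefore
concentration-independent; `build_drug_scheme()` solves them at unit
concentration and substitutes the true `kon` values afterwards, which keeps
`concentration = 0` exactly well-defined.

Charged scalar defaults are a converged flecainide parameterization;
neutral defaults are 1 (drug-bound rate = drug-free rate), with `ki_on`
defaulting to the diffusion rate and `ki_off` to `Kd_inactivated·D`.

## Simulating voltage clamp

Protocols are piecewise-constant voltage waveforms, so the master equation
is linear within each segment and `P(t) = e^{Qt}P(0)` is exact. The
propagator (`make_propagator()`) diagonalizes `Q` once per voltage and
evaluates the spectral solution at any set of times; if the
eigendecomposition fails its reconstruction check (a numerically defective
generator), it falls back to scaling-and-squaring matrix exponentials. A
fine-step ODE integration (`deSolve::ode`, rtol 1e−10) exists **only** as an
independent oracle in the test suite; agreement is required to 1e−6.

Stationary occupancies at the holding potential initialize each sweep. For
drug models this stationary distribution *is* the drug-equilibrated state
(the limit of holding in drug until nothing changes), so no explicit
equilibration loop is needed. The linear solve replaces one redundant
balance row with the normalization constraint; an SVD pseudo-inverse backs
it up for stiff generators, and reducibility is detected by a residual
check rather than by rank heuristics.

### Readouts and their numerics

Peak open occupancy is bracketed on a sampling grid (default 0.05 ms) and
then refined on the *analytic* segment solution: an interior peak is
located by root bisection on the exact derivative `(Q·P(t))[O]` (far more
precise than direct search on the occupancy, whose maximum location is only
determined to √machine-epsilon), with golden-section search as fallback
when the derivative does not bracket a sign change. Time-to-half-decay
(Tau50) bisects the analytic solution for the crossing; it is measured
**from the peak time**, not from pulse onset (decay-phase convention), and
is invariant to uniform trace rescaling. Because all readouts come from the
analytic propagator, halving the sampling grid changes them by < 1e−6 —
a tested invariant.

"Current" readouts use open-state occupancy. All fitted quantities
(availability, activation, recovery fractions, block fractions, pulse
ratios) are normalized to a control peak, so a driving-force factor
`G·(V−E_Na)` would cancel; it is therefore not modeled.

Mean open time is computed analytically as the reciprocal total exit rate
from O, `1/(β13+α2+αx)`; a 10⁵-event stochastic sojourn simulation (holding
times drawn at the generator's total exit rate) is the test-suite oracle.

### Protocol defaults

The bundled protocols (editable YAML in `inst/extdata/`, or
`default_protocols()` / `drug_protocols()`) are: SSA (9 conditioning
voltages −130…−50 mV, 500 ms, test at −20 mV), ACT (test −75…+15 mV), RFI
(double pulse at −100 mV, intervals 1–3000 ms), RUDB (50-pulse 10-Hz train,
then recovery), TAU50 (100-ms depolarizations, −40…+10 mV), MOT (−30 mV),
and for drug work SSA_DRUG, TB, UDB (10-Hz trains at 10 and 100 μM),
RUDB_DRUG, FDUDB (2–20 Hz). Voltages and durations not fixed by the
literature conventions above are package assumptions, declared here rather
than buried in code; the 100-ms TAU50 window is deliberately generous so
the half-decay readout stays defined when optimization or perturbation
studies slow inactivation substantially.

## The objective and the optimizer

Each protocol contributes `SSE/n_points` — normalization by the number of
data points, so a 9-point curve and a 1-point readout weigh equally per
unit misfit ("sampling-rate" normalization by point count; the worked
9-vs-1 example fixes this interpretation). Protocol costs are mutually
independent and can be evaluated on forked workers (`total_cost(workers=)`);
the reduction order is fixed by dataset registration order, so the report is
bitwise identical for any worker count. A simulation failure inside the
search returns an infinite sentinel instead of raising, which keeps the
simplex moving through pathological corners of parameter space.

`minimize_bounded()` is a Nelder–Mead simplex (coefficients 1, 2, 0.5, 0.5)
on a smoothly transformed space: `x = lb + u²` for one-sided bounds (the
positivity case), a sine transform for two-sided bounds. The transform
makes boundaries reachable without the stalling that hard projection causes
on simplex faces. Termination requires *both* the simplex cost spread and
the parameter spread (in original coordinates) to fall below their
tolerances — defaults 0.01 and 0.01 — simultaneously; the conjunction is
the stricter and better-defined reading of a dual-tolerance rule.
Iterations are counted as simplex iterations, not function evaluations;
absolute iteration counts are implementation-dependent and are not treated
as reproducible quantities.

`sequential_schedule()` implements cumulative protocol scheduling: optimize
group 1 for a 100-iteration block, add group 2, re-optimize, and so on;
`orderings = "factorial"` enumerates all `k!` orderings (24 for four
groups) and continues the best to convergence. `restart_perturbed()`
multiplies each parameter by an independent uniform factor within ±10% (by
default) and restarts — the standard kick to escape a shallow local
minimum.

`two_stage_drug_fit()` fits the neutral scalars first against
neutral-analog UDB/recovery data, then freezes them and fits the charged
scalars against the full drug protocol set — mirroring how a neutral
analog compound isolates neutral-state binding experimentally.

## Robustness study

`robustness_study()` perturbs a known optimum by independent uniform
multiplicative factors at ±5, 10, and 25% (three runs per level), refits,
and reports per-parameter mean recovered/true ratios and the SD of the
ratio normalized to its mean. Uniform (not Gaussian) perturbation is the
direct reading of "± X%" as a bounded range; the distribution is a
configurable design choice, not a claim about the world. The package
default budget of 500 simplex iterations per refit (120 in the test suite)
keeps the 9-run study at desk scale; the qualitative finding — spread grows
with perturbation level, while all refits reach acceptably low cost — is
insensitive to the budget, and the full-budget study is one option away.

## Synthetic data: what it does and does not show

`generate_datasets()` simulates a known "true" model under the protocol set
and optionally adds i.i.d. Gaussian noise to the readouts. This emulates
the *structure* of summary electrophysiology datasets — per-protocol sweep
axes, dimensionless normalized ordinates, heterogeneous point counts — and
gives exact ground truth for recovery tests (`total_cost` at the generating
parameters is 0 by construction; with noise SD σ its expectation is σ² per
protocol, verified against the χ² expectation in tests). It does **not**
emulate the pathologies of real data: between-lab systematic offsets,
correlated errors within a sweep, rundown, liquid-junction-potential
shifts, or model misspecification (the generating scheme is the fitted
scheme). Passing recovery tests therefore demonstrates that the pipeline
and optimizer are correct and that the parameters are identifiable *under
the model*, not that the model is true.

Problem sizes used by the shipped studies: the recovery test starts 5% from
truth and runs up to 1200 simplex iterations over the six drug-free
protocols (≈40 sweeps per cost evaluation); the robustness study runs 9
refits at 120 iterations; the two-stage drug fit test uses 15-pulse trains
and 60 iterations per stage. These sizes were chosen so the whole suite
runs comfortably on a laptop while leaving every qualitative conclusion
unchanged at larger budgets.

## Known limitations

* Protocol waveforms are piecewise-constant; ramps and sinusoids are out of
  scope (the exact-propagation design depends on it).
* The drug-bound edge topology is a documented default, configurable but
  not inferable from summary data alone; alternative consistent allocations
  of the 16 scalars exist.
* No formal structural-identifiability analysis is provided; the robustness
  study is an empirical stand-in.
* Single-channel stochastic simulation exists only as a test oracle; the
  engine is deterministic (ensemble) throughout.
* Temperature scaling (Q10) of rates and pH dynamics are not modeled; the
  drug's charged fraction is a constant of the experiment.
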