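#' Fully neutral analog of a drug
#'
#' Returns a copy of a [drug_spec()] whose charged fraction is negligible
#' (pKa far below pH), emulating a neutral analog compound (such as the
#' neutral flecainide derivative used to isolate neutral-state binding).
#'
#' @param spec A [drug_spec()].
#' @return A [drug_spec()] with essentially zero charged fraction.
#' @export
neutral_analog_spec <- function(spec) {
  spec$pKa <- 0.1
  spec
}

#' Two-stage drug-binding optimization
#'
#' Fits the drug-bound rate scalars in two stages, mirroring how
#' state-dependent block models are parameterized in practice: the 8 neutral
#' scalars are first optimized against data measured with a fully neutral
#' analog (use-dependent block and recovery protocols); they are then held
#' constant while the 8 charged scalars are optimized against the full drug
#' protocol set (availability, tonic block, UDB, recovery, frequency
#' dependence).
#'
#' @param params Drug-free [rate_params()] (held fixed throughout).
#' @param spec [drug_spec()] of the (partly charged) drug.
#' @param scalars0 Initial [drug_scalars()].
#' @param neutral_datasets Datasets measured with the neutral analog.
#' @param charged_datasets Datasets measured with the drug itself.
#' @param protocols Named list of [protocol()]s covering both dataset sets.
#' @param options_neutral,options_charged [optimizer_options()] per stage.
#' @param workers Worker count for [total_cost()].
#' @return List: `scalars` (fitted [drug_scalars()]), `neutral_fit`,
#'   `charged_fit` (the two [minimize_bounded()] results).
#' @export
two_stage_drug_fit <- function(params, spec, scalars0,
                               neutral_datasets, charged_datasets,
                               protocols,
                               options_neutral = optimizer_options(),
                               options_charged = optimizer_options(),
                               workers = 1L) {
  stopifnot(inherits(scalars0, "drug_scalars"))
  nspec <- neutral_analog_spec(spec)

  build_neutral <- function(nsc) {
    drug_model(params, nspec,
               drug_scalars(charged = scalars0$charged, neutral = nsc))
  }
  fn_n <- function(nsc) total_cost(nsc, neutral_datasets, protocols,
                                   build_neutral, workers = workers)$total
  neutral_fit <- minimize_bounded(fn_n, scalars0$neutral, options_neutral)
  neutral_hat <- neutral_fit$par

  build_charged <- function(csc) {
    drug_model(params, spec,
               drug_scalars(charged = csc, neutral = neutral_hat))
  }
  fn_c <- function(csc) total_cost(csc, charged_datasets, protocols,
                                   build_charged, workers = workers)$total
  charged_fit <- minimize_bounded(fn_c, scalars0$charged, options_charged)

  list(scalars = drug_scalars(charged = charged_fit$par,
                              neutral = neutral_hat),
       neutral_fit = neutral_fit,
       charged_fit = charged_fit)
}
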