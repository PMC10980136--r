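#' Allometric scaling exponents by parameter class
#'
#' The body-weight power-law exponents used for mouse-to-human
#' extrapolation: -0.25 for rate constants, 0.75 for clearances, 1 for
#' volumes of distribution, and -0.33 for doses; `unscaled` (0) covers
#' dimensionless gains, geometric and affinity parameters that do not vary
#' with body size.
#'
#' @return Named numeric vector of exponents.
#' @export
scaling_exponents <- function() {
  c(rate_constant = -0.25, clearance = 0.75, volume_of_distribution = 1,
    dose = -0.33, unscaled = 0)
}

#' Allometrically scale a single parameter between species
#'
#' `P_h = P_m * (BW_h / BW_m)^A`, with the exponent `A` taken from the
#' parameter-class table (see [scaling_exponents()]) or given directly.
#'
#' @param value_mouse Parameter value in the source species.
#' @param rule A parameter class name (e.g. `"rate_constant"`) or a numeric
#'   exponent.
#' @param species_from,species_to [species_profile()]s supplying the body
#'   weights (defaults: mouse to human).
#' @return The scaled value.
#' @export
scale_parameter <- function(value_mouse, rule,
                            species_from = mouse_profile(),
                            species_to = human_profile()) {
  if (is.character(rule)) {
    exps <- scaling_exponents()
    if (!rule %in% names(exps))
      stop("scale_parameter: unknown parameter class '", rule, "'",
           call. = FALSE)
    a <- exps[[rule]]
  } else if (is.numeric(rule)) {
    a <- rule
  } else stop("scale_parameter: 'rule' must be a class name or exponent",
              call. = FALSE)
  value_mouse * (species_to$body_weight_kg / species_from$body_weight_kg)^a
}

#' Human-equivalent dose from a mouse dose
#'
#' Convenience wrapper scaling a mg/kg dose by body weight. The default
#' exponent -0.25 reproduces the 0.026 mg/kg human-equivalent of the
#' 0.2 mg/kg mouse dose; -0.33, the classical dose-scaling exponent, is
#' available via `exponent`.
#'
#' @param dose_mg_kg Mouse dose in mg/kg.
#' @param exponent Allometric exponent (default -0.25).
#' @inheritParams scale_parameter
#' @return Human dose in mg/kg.
#' @export
human_equivalent_dose <- function(dose_mg_kg, exponent = -0.25,
                                  species_from = mouse_profile(),
                                  species_to = human_profile()) {
  scale_parameter(dose_mg_kg, exponent, species_from, species_to)
}

#' Convert a clinical dose specification to mg/kg
#'
#' Flat doses (mg) are divided by body weight; body-surface-area doses
#' (mg/m^2) are multiplied by the assumed BSA and divided by body weight.
#' Full precision is retained; rounding is for display only.
#'
#' @param dose Dose amount (>= 0).
#' @param unit `"mg"` (flat), `"mg_m2"` (per body surface area), or
#'   `"mg_kg"` (already per kg; returned unchanged).
#' @param species A [species_profile()]; must carry a BSA when `unit` is
#'   `"mg_m2"`.
#' @return Dose in mg/kg.
#' @export
clinical_dose_to_mgkg <- function(dose, unit = c("mg", "mg_m2", "mg_kg"),
                                  species = human_profile()) {
  unit <- match.arg(unit)
  if (any(dose < 0))
    stop("clinical_dose_to_mgkg: dose must be >= 0", call. = FALSE)
  switch(unit,
    mg = dose / species$body_weight_kg,
    mg_m2 = {
      if (!is.finite(species$body_surface_area_m2))
        stop("clinical_dose_to_mgkg: mg/m^2 dose requires a body surface ",
             "area in the species profile", call. = FALSE)
      dose * species$body_surface_area_m2 / species$body_weight_kg
    },
    mg_kg = dose)
}

#' Default parameter-class assignment for scaling
#'
#' Assigns every numeric model parameter either an allometric class (see
#' [scaling_exponents()]) or `"population_average"`, meaning the human value
#' is supplied directly rather than scaled. First-order rate constants scale
#' with exponent -0.25; anatomical volumes with exponent 1; dimensionless
#' gains, saturation constants, binding affinities and microarchitectural
#' quantities (vascular surface density, intercapillary distance, NP and
#' pore diameters) are size-invariant.
#'
#' @return Named character vector: flattened parameter name -> class.
#' @export
default_scaling_rules <- function() {
  c(
    species.body_weight_kg = "population_average",
    species.plasma_volume_ml = "population_average",
    species.tumor_interstitial_fraction = "population_average",
    species.body_surface_area_m2 = "population_average",
    np.diameter_nm = "unscaled",
    np.pore_diameter_nm = "unscaled",
    np.permeability_ref_cm_day = "rate_constant",
    np.degradation_rate_per_day = "rate_constant",
    np.clearance_rate_per_day = "rate_constant",
    np.payload_fraction = "unscaled",
    np.diffusivity_ref_cm2_day = "unscaled",
    transport.vascular_surface_per_cm3 = "unscaled",
    transport.intercapillary_length_um = "unscaled",
    transport.uptake_fraction_cancer = "unscaled",
    transport.uptake_fraction_tam = "unscaled",
    transport.cell_volume_cancer_ml = "volume_of_distribution",
    transport.cell_volume_tam_ml = "volume_of_distribution",
    mirna.production_rate_pm_day = "rate_constant",
    mirna.degradation_rate_per_day = "rate_constant",
    mirna.potency_pm = "unscaled",
    mirna.proliferation_gain = "unscaled",
    mirna.antagonist_gain = "unscaled",
    mirna.antagonist_ec50_mg_ml = "unscaled",
    mirna.antagonist_degradation_per_day = "population_average",
    mirna.exosome_transfer_per_day = "rate_constant",
    checkpoint.pdl1_production_pm_day = "rate_constant",
    checkpoint.pdl1_degradation_per_day = "rate_constant",
    checkpoint.pdl1_repression_pm = "unscaled",
    checkpoint.pd1_equilibrium_pm = "unscaled",
    checkpoint.pd1_turnover_per_day = "rate_constant",
    checkpoint.kd_pd1_pdl1_pm = "unscaled",
    checkpoint.kd_atezolizumab_pm = "unscaled",
    checkpoint.kd_pembrolizumab_pm = "unscaled",
    checkpoint.immune_kill_max_per_day = "population_average",
    checkpoint.inhibition_constant_pm = "unscaled",
    checkpoint.escape_max = "unscaled",
    chemo.clearance_per_day = "rate_constant",
    chemo.permeability_cm_day = "rate_constant",
    chemo.tumor_elimination_per_day = "rate_constant",
    chemo.kill_max_per_day = "population_average",
    chemo.ic50_mg_ml = "unscaled",
    chemo.resistance_gain = "unscaled",
    ici.clearance_per_day = "rate_constant",
    ici.permeability_cm_day = "rate_constant",
    ici.tumor_elimination_per_day = "rate_constant",
    ici.mw_atezolizumab = "unscaled",
    ici.mw_pembrolizumab = "unscaled",
    growth.rate_per_day = "population_average",
    growth.carrying_capacity_cm3 = "population_average",
    growth.initial_volume_cm3 = "population_average"
  )
}

#' Default human population-average overrides
#'
#' Values supplied directly for parameters marked `"population_average"` in
#' [default_scaling_rules()]: human physiology (70 kg, 3 L plasma, BSA
#' 1.9 m^2), a single founding cancer cell (1e-9 cm^3) as the initial
#' condition, a 60 cm^3 carrying capacity, an intrinsic growth rate
#' calibrated so an untreated tumor reaches a 1.5 cm diameter 124 weeks
#' after inception (the stage IA2 presentation of the average patient), an
#' anti-miR-155 intracellular turnover consistent with near-complete
#' inter-dose washout under three-weekly dosing, and immune- and chemo-kill
#' rates re-calibrated against clinical time-to-progression behavior of the
#' standard-of-care drugs (naive allometric scaling of drug-effect rates
#' under-predicts human treatment effects).
#'
#' @return Named numeric vector keyed by flattened parameter name.
#' @export
default_human_overrides <- function() {
  c(
    species.body_weight_kg = 70,
    species.plasma_volume_ml = 3000,
    species.tumor_interstitial_fraction = 0.3,
    species.body_surface_area_m2 = 1.9,
    mirna.antagonist_degradation_per_day = 0.25,
    checkpoint.immune_kill_max_per_day = 0.0737,
    chemo.kill_max_per_day = 0.0114,
    growth.rate_per_day = 0.0533,
    growth.carrying_capacity_cm3 = 60,
    growth.initial_volume_cm3 = 1e-9
  )
}

#' Allometrically scale a complete parameter set
#'
#' Applies [default_scaling_rules()] (or a caller-supplied assignment) to
#' every numeric parameter; parameters marked `"population_average"` must
#' have a value in `overrides`. Any parameter left without a class, and any
#' population-average parameter without an override, is an error listing the
#' offending names.
#'
#' @param params_mouse Source `model_parameters`.
#' @param rules Named character vector: parameter name -> class (see
#'   [default_scaling_rules()]).
#' @param overrides Named numeric vector of direct values for
#'   population-average parameters.
#' @param species_to Target [species_profile()].
#' @return A validated `model_parameters` for the target species.
#' @export
scale_parameter_set <- function(params_mouse,
                                rules = default_scaling_rules(),
                                overrides = default_human_overrides(),
                                species_to = human_profile()) {
  flat <- params_flatten(params_mouse)
  missing_rule <- setdiff(names(flat), names(rules))
  if (length(missing_rule))
    stop("scale_parameter_set: no scaling class assigned for: ",
         paste(missing_rule, collapse = ", "), call. = FALSE)
  pop <- names(rules)[rules == "population_average"]
  pop <- intersect(pop, names(flat))
  missing_ov <- setdiff(pop, names(overrides))
  if (length(missing_ov))
    stop("scale_parameter_set: population-average parameter(s) without a ",
         "supplied value: ", paste(missing_ov, collapse = ", "),
         call. = FALSE)
  out <- flat
  for (nm in names(flat)) {
    cls <- rules[[nm]]
    out[[nm]] <- if (cls == "population_average") overrides[[nm]]
      else scale_parameter(flat[[nm]], cls, params_mouse$species, species_to)
  }
  p <- params_unflatten(out, params_mouse)
  p$species$name <- species_to$name
  p
}

#' Default human parameterization
#'
#' The calibrated mouse defaults of [default_mouse_parameters()] scaled to
#' humans with [scale_parameter_set()] under the default rules and
#' population-average overrides.
#'
#' @return A validated `model_parameters` for an average adult patient.
#' @export
default_human_parameters <- function() {
  scale_parameter_set(default_mouse_parameters())
}
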