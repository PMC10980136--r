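#' Species physiology profile
#'
#' Bundles the species-level physiological quantities used throughout the
#' model: body weight, plasma volume, the interstitial volume fraction of the
#' tumor, and (for humans) an assumed body surface area for clinical dose
#' conversions.
#'
#' @param name `"mouse"` or `"human"`.
#' @param body_weight_kg Body weight in kg. Must be positive.
#' @param plasma_volume_ml Plasma volume in mL. Must be positive.
#' @param tumor_interstitial_fraction Interstitial volume fraction of the
#'   tumor, strictly between 0 and 1.
#' @param body_surface_area_m2 Assumed body surface area in m^2 (used only
#'   for human flat/mg-per-m2 dose conversions); `NA` for mice.
#' @return An object of class `species_profile`.
#' @export
species_profile <- function(name = c("mouse", "human"),
                            body_weight_kg,
                            plasma_volume_ml,
                            tumor_interstitial_fraction,
                            body_surface_area_m2 = NA_real_) {
  name <- match.arg(name)
  if (!is.numeric(body_weight_kg) || body_weight_kg <= 0)
    stop("species_profile: 'body_weight_kg' must be > 0", call. = FALSE)
  if (!is.numeric(plasma_volume_ml) || plasma_volume_ml <= 0)
    stop("species_profile: 'plasma_volume_ml' must be > 0", call. = FALSE)
  if (!is.numeric(tumor_interstitial_fraction) ||
      tumor_interstitial_fraction <= 0 || tumor_interstitial_fraction >= 1)
    stop("species_profile: 'tumor_interstitial_fraction' must lie in (0, 1)",
         call. = FALSE)
  structure(
    list(name = name,
         body_weight_kg = as.numeric(body_weight_kg),
         plasma_volume_ml = as.numeric(plasma_volume_ml),
         tumor_interstitial_fraction = as.numeric(tumor_interstitial_fraction),
         body_surface_area_m2 = as.numeric(body_surface_area_m2)),
    class = "species_profile")
}

#' Default mouse species profile (20 g xenograft host)
#' @return A `species_profile`.
#' @export
mouse_profile <- function() {
  species_profile("mouse", body_weight_kg = 0.02, plasma_volume_ml = 1.5,
                  tumor_interstitial_fraction = 0.3)
}

#' Default human species profile (70 kg, BSA 1.9 m^2)
#' @return A `species_profile`.
#' @export
human_profile <- function() {
  species_profile("human", body_weight_kg = 70, plasma_volume_ml = 3000,
                  tumor_interstitial_fraction = 0.3,
                  body_surface_area_m2 = 1.9)
}

# Positivity/range requirements used by validate_parameters(). Each entry is
# checked against the flattened parameter vector; "pos" means > 0, "nonneg"
# means >= 0.
.param_constraints <- list(
  pos = c("species.body_weight_kg", "species.plasma_volume_ml",
          "np.diameter_nm", "np.pore_diameter_nm",
          "np.permeability_ref_cm_day", "np.diffusivity_ref_cm2_day",
          "transport.vascular_surface_per_cm3",
          "transport.intercapillary_length_um",
          "transport.cell_volume_cancer_ml", "transport.cell_volume_tam_ml",
          "mirna.production_rate_pm_day", "mirna.degradation_rate_per_day",
          "mirna.potency_pm", "mirna.antagonist_ec50_mg_ml",
          "mirna.antagonist_degradation_per_day",
          "checkpoint.pdl1_production_pm_day",
          "checkpoint.pdl1_degradation_per_day",
          "checkpoint.pdl1_repression_pm", "checkpoint.pd1_equilibrium_pm",
          "checkpoint.pd1_turnover_per_day", "checkpoint.kd_pd1_pdl1_pm",
          "checkpoint.kd_atezolizumab_pm", "checkpoint.kd_pembrolizumab_pm",
          "checkpoint.inhibition_constant_pm", "checkpoint.escape_max",
          "chemo.ic50_mg_ml",
          "ici.mw_atezolizumab", "ici.mw_pembrolizumab",
          "growth.rate_per_day", "growth.carrying_capacity_cm3",
          "growth.initial_volume_cm3"),
  nonneg = c("np.degradation_rate_per_day", "np.clearance_rate_per_day",
             "np.payload_fraction",
             "transport.uptake_fraction_cancer",
             "transport.uptake_fraction_tam",
             "mirna.exosome_transfer_per_day",
             "checkpoint.immune_kill_max_per_day",
             "chemo.clearance_per_day", "chemo.permeability_cm_day",
             "chemo.tumor_elimination_per_day", "chemo.kill_max_per_day",
             "chemo.resistance_gain",
             "ici.clearance_per_day", "ici.permeability_cm_day",
             "ici.tumor_elimination_per_day")
)

#' Assemble a full model parameter set
#'
#' Composes the parameter groups consumed by every simulation: species
#' physiology, nanoparticle (NP) disposition, intratumoral transport, the
#' miR-155 axis, the PD-1/PD-L1 checkpoint, cisplatin, immune checkpoint
#' inhibitor (ICI) disposition, and tumor growth. All rates are per day,
#' volumes in cm^3 or mL as named, concentrations in pM (molecular species)
#' or mg/mL (drugs).
#'
#' @param species A [species_profile()].
#' @param np,transport,mirna,checkpoint,chemo,ici,growth Named lists for each
#'   parameter group; see [default_mouse_parameters()] for the complete field
#'   inventory and defaults.
#' @return An object of class `model_parameters` (validated).
#' @seealso [default_mouse_parameters()], [default_human_parameters()],
#'   [validate_parameters()]
#' @export
model_parameters <- function(species, np, transport, mirna, checkpoint,
                             chemo, ici, growth) {
  p <- structure(
    list(species = species, np = np, transport = transport, mirna = mirna,
         checkpoint = checkpoint, chemo = chemo, ici = ici, growth = growth),
    class = "model_parameters")
  validate_parameters(p)
  p
}

#' Validate a model parameter set
#'
#' Checks the structural invariants of the parameter set: required fields
#' present, positivity where required, uptake fractions summing to 1, the
#' proliferation and antagonist gains exceeding 1, and exosomal transfer
#' slower than miR-155 turnover (required for a positive cancer-cell
#' production rate at the shared 1.5 pM equilibrium).
#'
#' @param params A `model_parameters` object.
#' @return `params`, invisibly; errors name the offending field.
#' @export
validate_parameters <- function(params) {
  if (!inherits(params, "model_parameters"))
    stop("validate_parameters: not a 'model_parameters' object", call. = FALSE)
  flat <- params_flatten(params)
  for (nm in .param_constraints$pos) {
    if (!nm %in% names(flat) || !is.finite(flat[[nm]]))
      stop("invalid parameters: '", nm, "' is missing or non-finite",
           call. = FALSE)
    if (flat[[nm]] <= 0)
      stop("invalid parameters: '", nm, "' must be > 0", call. = FALSE)
  }
  for (nm in .param_constraints$nonneg) {
    if (!nm %in% names(flat) || !is.finite(flat[[nm]]))
      stop("invalid parameters: '", nm, "' is missing or non-finite",
           call. = FALSE)
    if (flat[[nm]] < 0)
      stop("invalid parameters: '", nm, "' must be >= 0", call. = FALSE)
  }
  fr <- params$transport$uptake_fraction_cancer +
    params$transport$uptake_fraction_tam
  if (abs(fr - 1) > 1e-9)
    stop("invalid parameters: 'transport.uptake_fraction_*' must sum to 1",
         call. = FALSE)
  if (params$mirna$proliferation_gain <= 1)
    stop("invalid parameters: 'mirna.proliferation_gain' must be > 1",
         call. = FALSE)
  if (params$mirna$antagonist_gain <= 1)
    stop("invalid parameters: 'mirna.antagonist_gain' must be > 1",
         call. = FALSE)
  if (params$mirna$exosome_transfer_per_day >=
      params$mirna$degradation_rate_per_day)
    stop("invalid parameters: 'mirna.exosome_transfer_per_day' must be < ",
         "'mirna.degradation_rate_per_day'", call. = FALSE)
  if (params$np$diameter_nm >= params$np$pore_diameter_nm)
    stop("invalid parameters: 'np.diameter_nm' must be below ",
         "'np.pore_diameter_nm' for nonzero vascular permeation",
         call. = FALSE)
  invisible(params)
}

#' Default mouse parameterization
#'
#' The shipped baseline parameter set for the preclinical (xenograft mouse)
#' model. Printed physiological anchors (body weight 0.02 kg, miR-155
#' equilibrium 1.5 pM, PD-1 equilibrium 1 pM, ten-fold PD-L1 de-repression
#' under complete miR-155 knockdown) are fixed by construction; the remaining
#' free parameters are the calibrated values that reproduce the five
#' preclinical end-of-treatment tumor-growth-inhibition anchors
#' (anti-miR-155 ~62%, cisplatin ~49%, combination ~86%, atezolizumab ~16%,
#' pembrolizumab ~18%) under the reference regimens of
#' [preclinical_regimens()].
#'
#' @return A validated `model_parameters` object.
#' @export
default_mouse_parameters <- function() {
  model_parameters(
    species = mouse_profile(),
    np = list(
      diameter_nm = 100,
      pore_diameter_nm = 400,
      permeability_ref_cm_day = 0.0789,
      degradation_rate_per_day = 0.5,
      clearance_rate_per_day = 1.0,
      payload_fraction = 1.0,
      diffusivity_ref_cm2_day = 8.6e-5
    ),
    transport = list(
      vascular_surface_per_cm3 = 200,
      intercapillary_length_um = 50,
      uptake_fraction_cancer = 0.8,
      uptake_fraction_tam = 0.2,
      cell_volume_cancer_ml = 2e-4,
      cell_volume_tam_ml = 5e-5
    ),
    mirna = list(
      production_rate_pm_day = 1.5,
      degradation_rate_per_day = 1.0,
      potency_pm = 0.6,
      proliferation_gain = 1.727,
      antagonist_gain = 150,
      antagonist_ec50_mg_ml = 0.05,
      antagonist_degradation_per_day = 0.3,
      exosome_transfer_per_day = 0.2
    ),
    checkpoint = list(
      pdl1_production_pm_day = 0.75,
      pdl1_degradation_per_day = 0.5,
      pdl1_repression_pm = 1.5 / 9,
      pd1_equilibrium_pm = 1.0,
      pd1_turnover_per_day = 1.0,
      kd_pd1_pdl1_pm = 1.0,
      kd_atezolizumab_pm = 9.53e4,
      kd_pembrolizumab_pm = 2.74e4,
      immune_kill_max_per_day = 0.0364,
      inhibition_constant_pm = 0.05,
      escape_max = 0.4
    ),
    chemo = list(
      clearance_per_day = 2.0,
      permeability_cm_day = 1e-2,
      tumor_elimination_per_day = 0.5,
      kill_max_per_day = 0.0418,
      ic50_mg_ml = 2e-5,
      resistance_gain = 6.45
    ),
    ici = list(
      clearance_per_day = 0.15,
      permeability_cm_day = 3e-3,
      tumor_elimination_per_day = 0.1,
      mw_atezolizumab = 145000,
      mw_pembrolizumab = 149000
    ),
    growth = list(
      rate_per_day = 0.0716,
      carrying_capacity_cm3 = 10,
      initial_volume_cm3 = 0.1
    )
  )
}

#' Flatten a parameter set to a named numeric vector
#'
#' Names take the form `group.field` (e.g. `"growth.rate_per_day"`); the
#' non-numeric species name is excluded. Round-trips exactly through
#' [params_unflatten()].
#'
#' @param params A `model_parameters` object.
#' @return Named numeric vector.
#' @export
params_flatten <- function(params) {
  out <- c()
  for (grp in names(params)) {
    g <- params[[grp]]
    fields <- names(g)
    fields <- fields[vapply(g, is.numeric, logical(1))]
    v <- vapply(fields, function(f) as.numeric(g[[f]]), numeric(1))
    names(v) <- paste(grp, fields, sep = ".")
    out <- c(out, v)
  }
  out
}

#' Rebuild a parameter set from a flattened vector
#'
#' @param flat Named numeric vector as produced by [params_flatten()].
#' @param template A `model_parameters` object supplying structure and any
#'   non-numeric fields.
#' @return A validated `model_parameters` object.
#' @export
params_unflatten <- function(flat, template) {
  p <- template
  for (nm in names(flat)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2 || is.null(p[[parts[1]]]))
      stop("params_unflatten: unknown parameter '", nm, "'", call. = FALSE)
    p[[parts[1]]][[parts[2]]] <- unname(flat[[nm]])
  }
  validate_parameters(p)
  p
}

#' Apply multiplicative perturbations to named parameters
#'
#' @param params A `model_parameters` object.
#' @param multipliers Named numeric vector of multipliers keyed by flattened
#'   parameter name.
#' @return Perturbed, validated `model_parameters`.
#' @export
perturb_parameters <- function(params, multipliers) {
  flat <- params_flatten(params)
  bad <- setdiff(names(multipliers), names(flat))
  if (length(bad))
    stop("perturb_parameters: unknown parameter(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  flat[names(multipliers)] <- flat[names(multipliers)] * multipliers
  params_unflatten(flat, params)
}

#' Write / read a parameter set as JSON
#'
#' Canonical on-disk form: one key per named parameter (flattened names) plus
#' the species profile. Round-trips to numerical identity.
#'
#' @param params A `model_parameters` object.
#' @param path File path.
#' @return `write_parameters_json()` returns `path` invisibly;
#'   `read_parameters_json()` returns a `model_parameters` object.
#' @export
write_parameters_json <- function(params, path) {
  flat <- as.list(params_flatten(params))
  flat <- flat[vapply(flat, is.finite, logical(1))]  # NA BSA etc. stay template-side
  flat$species.name <- params$species$name
  jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_parameters_json
#' @param template Template `model_parameters` giving the structure (defaults
#'   to the shipped mouse set).
#' @export
read_parameters_json <- function(path, template = default_mouse_parameters()) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  nm <- x[["species.name"]]
  x[["species.name"]] <- NULL
  flat <- unlist(x)
  p <- params_unflatten(flat, template)
  if (!is.null(nm)) p$species$name <- nm
  p
}

#' @export
print.model_parameters <- function(x, ...) {
  flat <- params_flatten(x)
  cat("<model_parameters> species:", x$species$name,
      sprintf("(BW %.3g kg)", x$species$body_weight_kg), "\n")
  cat("  ", length(flat), "numeric parameters in", length(names(x)),
      "groups:", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.species_profile <- function(x, ...) {
  cat(sprintf("<species_profile> %s: BW %.3g kg, plasma %.3g mL, phi_int %.2f\n",
              x$name, x$body_weight_kg, x$plasma_volume_ml,
              x$tumor_interstitial_fraction))
  invisible(x)
}
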