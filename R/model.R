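#' @useDynLib antimiRsim
NULL

# Parameter vector layout consumed by the compiled right-hand side
# (src/model_rhs.c); order must match its #defines.
.rhs_param_order <- c(
  "species.plasma_volume_ml", "species.tumor_interstitial_fraction",
  "np.diameter_nm", "np.pore_diameter_nm", "np.permeability_ref_cm_day",
  "np.degradation_rate_per_day", "np.clearance_rate_per_day",
  "np.payload_fraction", "np.diffusivity_ref_cm2_day",
  "transport.vascular_surface_per_cm3", "transport.intercapillary_length_um",
  "transport.uptake_fraction_cancer", "transport.uptake_fraction_tam",
  "transport.cell_volume_cancer_ml", "transport.cell_volume_tam_ml",
  "mirna.production_rate_pm_day", "mirna.degradation_rate_per_day",
  "mirna.potency_pm", "mirna.proliferation_gain", "mirna.antagonist_gain",
  "mirna.antagonist_ec50_mg_ml", "mirna.antagonist_degradation_per_day",
  "mirna.exosome_transfer_per_day",
  "checkpoint.pdl1_production_pm_day", "checkpoint.pdl1_degradation_per_day",
  "checkpoint.pdl1_repression_pm", "checkpoint.pd1_equilibrium_pm",
  "checkpoint.pd1_turnover_per_day", "checkpoint.kd_pd1_pdl1_pm",
  "checkpoint.kd_atezolizumab_pm", "checkpoint.kd_pembrolizumab_pm",
  "checkpoint.immune_kill_max_per_day", "checkpoint.inhibition_constant_pm",
  "checkpoint.escape_max",
  "chemo.clearance_per_day", "chemo.permeability_cm_day",
  "chemo.tumor_elimination_per_day", "chemo.kill_max_per_day",
  "chemo.ic50_mg_ml", "chemo.resistance_gain",
  "ici.clearance_per_day", "ici.permeability_cm_day",
  "ici.tumor_elimination_per_day", "ici.mw_atezolizumab",
  "ici.mw_pembrolizumab",
  "growth.rate_per_day", "growth.carrying_capacity_cm3")

.rhs_parms <- function(params) {
  flat <- params_flatten(params)
  unname(flat[.rhs_param_order])
}

# State vector layout used by the ODE system. Masses in mg, intracellular
# anti-miR-155 in mg/mL, molecular species in pM, tumor volume in cm^3.
.state_names <- c(
  "np_plasma", "np_tumor",
  "am_cancer", "am_tam",
  "mir_cancer", "mir_tam",
  "pdl1_cancer", "pdl1_tam", "pd1",
  "cis_plasma", "cis_tumor",
  "ate_plasma", "ate_tumor",
  "pem_plasma", "pem_tumor",
  "volume")

.dose_state <- c(anti_mir155_np = "np_plasma", cisplatin = "cis_plasma",
                 atezolizumab = "ate_plasma", pembrolizumab = "pem_plasma")

#' Immune-kill attenuation factor from checkpoint engagement
#'
#' Computes the fraction of the maximal CD8+ T-cell kill rate that survives
#' PD-1:PD-L1 mediated immune escape. Free PD-L1 and PD-1 form a complex at
#' equilibrium (dissociation constant `kd_pd1_pdl1_pm`); atezolizumab
#' competes for PD-L1 and pembrolizumab for PD-1, each raising the effective
#' dissociation constant by a factor `(1 + C/Kd)` (competitive binding with
#' the antibodies in molar excess over the pM-scale receptor pool). The
#' complex concentration `X` solves the resulting quadratic
#' `X^2 - X (L + P + Kd_eff) + L P = 0` (smaller root), and the attenuation
#' is `1 - E_esc * X / (K_I + X)`, with `K_I` the checkpoint inhibition
#' constant and `E_esc` in (0, 1) the maximal checkpoint-suppressible
#' fraction of CD8+ T-cell killing (escape capacity is bounded: part of the
#' immune kill is not PD-1:PD-L1 dependent).
#'
#' The factor lies in (0, 1]: 1 when PD-L1 is absent or the checkpoint is
#' fully blocked by saturating antibody, decreasing toward 0 as the
#' PD-1:PD-L1 complex accumulates.
#'
#' @param free_pdl1_pm Free PD-L1, pM (scalar or vector).
#' @param free_pd1_pm Free PD-1, pM.
#' @param ici_pm Named numeric with elements `atezolizumab` and
#'   `pembrolizumab`: free tumor-interstitial antibody concentrations in pM.
#' @param params A `model_parameters` object (checkpoint group is used).
#' @return Attenuation factor(s) in (0, 1].
#' @export
checkpoint_occupancy <- function(free_pdl1_pm, free_pd1_pm,
                                 ici_pm = c(atezolizumab = 0,
                                            pembrolizumab = 0),
                                 params) {
  ck <- params$checkpoint
  L <- pmax(0, free_pdl1_pm)
  P <- pmax(0, free_pd1_pm)
  a <- max(0, ici_pm[["atezolizumab"]]) / ck$kd_atezolizumab_pm
  b <- max(0, ici_pm[["pembrolizumab"]]) / ck$kd_pembrolizumab_pm
  kd_eff <- ck$kd_pd1_pdl1_pm * (1 + a) * (1 + b)
  s <- L + P + kd_eff
  X <- (s - sqrt(pmax(0, s^2 - 4 * L * P))) / 2
  1 - ck$escape_max * X / (ck$inhibition_constant_pm + X)
}

#' Pre-treatment molecular equilibria
#'
#' Returns the drug-free steady state of the molecular subsystem: miR-155 in
#' both cell types at `g0 / delta_M` (1.5 pM at defaults), PD-L1 at its
#' miR-155-repressed level, and PD-1 at its equilibrium (1 pM by
#' construction).
#'
#' @param params A `model_parameters` object.
#' @return Named numeric: `mir_pm`, `pdl1_pm`, `pd1_pm`.
#' @export
molecular_equilibrium <- function(params) {
  mir <- params$mirna$production_rate_pm_day /
    params$mirna$degradation_rate_per_day
  ck <- params$checkpoint
  pdl1 <- ck$pdl1_production_pm_day * ck$pdl1_repression_pm /
    ((ck$pdl1_repression_pm + mir) * ck$pdl1_degradation_per_day)
  c(mir_pm = mir, pdl1_pm = pdl1, pd1_pm = ck$pd1_equilibrium_pm)
}

#' Initial state vector for a simulation
#'
#' Drug-free initial condition: tumor at `initial_volume_cm3` (or an
#' override), molecular species at their pre-treatment equilibria, all drug
#' compartments empty.
#'
#' @param params A `model_parameters` object.
#' @param volume_cm3 Optional initial tumor volume override (cm^3).
#' @return Named numeric state vector.
#' @export
initial_state <- function(params, volume_cm3 = NULL) {
  eq <- molecular_equilibrium(params)
  y <- stats::setNames(numeric(length(.state_names)), .state_names)
  y["mir_cancer"] <- y["mir_tam"] <- eq[["mir_pm"]]
  y["pdl1_cancer"] <- y["pdl1_tam"] <- eq[["pdl1_pm"]]
  y["pd1"] <- eq[["pd1_pm"]]
  y["volume"] <- if (is.null(volume_cm3)) params$growth$initial_volume_cm3
                 else volume_cm3
  y
}

#' Build the differential-system evaluator
#'
#' Returns the right-hand side of the two-compartment multiscale ODE system:
#' plasma/tumor nanoparticle and drug disposition with permeation-limited
#' vascular exchange (Renkin-type size hindrance for NPs), diffusive cellular
#' uptake and intracellular anti-miR-155 release, miR-155 production,
#' degradation (accelerated by anti-miR-155 through a saturable gain) and
#' TAM-to-cancer-cell exosomal transfer, miR-155-repressed PD-L1 turnover, a
#' constant-turnover PD-1 pool, and logistic tumor growth stimulated by
#' miR-155 and opposed by cisplatin kill (with miR-155-inflated IC50,
#' the chemoresistance abstraction) and checkpoint-gated immune kill.
#'
#' @param params A validated `model_parameters` object.
#' @return A function `(t, y, parms)` returning `list(dy)`, suitable for
#'   [deSolve::lsoda()]; derivatives are finite for any nonnegative state.
#' @export
build_rhs <- function(params) {
  validate_parameters(params)
  sp <- params$species; np <- params$np; tr <- params$transport
  mi <- params$mirna; ck <- params$checkpoint; ch <- params$chemo
  ic <- params$ici; gr <- params$growth

  v_pl <- sp$plasma_volume_ml
  phi <- sp$tumor_interstitial_fraction
  # Renkin-type size hindrance: permeability vanishes at the pore diameter
  p_np <- np$permeability_ref_cm_day * (1 - np$diameter_nm / np$pore_diameter_nm)^2
  # Stokes-Einstein diffusivity ~ 1/diameter, referenced to 100 nm
  len_cm <- tr$intercapillary_length_um * 1e-4
  k_diff <- np$diffusivity_ref_cm2_day * (100 / np$diameter_nm) / len_cm^2
  k_np_el <- np$clearance_rate_per_day + np$degradation_rate_per_day
  mir_eq <- mi$production_rate_pm_day / mi$degradation_rate_per_day
  # cancer-cell intrinsic production offset so both cell types share the
  # pre-treatment equilibrium despite the exosomal source
  g0_cancer <- mi$production_rate_pm_day - mi$exosome_transfer_per_day * mir_eq
  psv <- function(perm, v) perm * tr$vascular_surface_per_cm3 * v

  function(t, y, parms = NULL) {
    y <- pmax(y, 0)
    # volume floored at one cell so transport terms stay finite if a strong
    # treatment drives the tumor toward extinction
    v <- max(y[[16]], 1e-9)
    vi <- phi * v  # interstitial volume, mL

    # --- nanoparticle disposition ---
    j_np <- psv(p_np, v) * (y[[1]] / v_pl - y[[2]] / vi)
    d_np_pl <- -k_np_el * y[[1]] - j_np
    d_np_tu <- j_np - np$degradation_rate_per_day * y[[2]] - k_diff * y[[2]]

    # --- intracellular anti-miR-155 (payload release lumped with uptake) ---
    rel <- k_diff * y[[2]] * np$payload_fraction
    d_am_c <- tr$uptake_fraction_cancer * rel / tr$cell_volume_cancer_ml -
      mi$antagonist_degradation_per_day * y[[3]]
    d_am_t <- tr$uptake_fraction_tam * rel / tr$cell_volume_tam_ml -
      mi$antagonist_degradation_per_day * y[[4]]

    # --- miR-155 axis ---
    hill_am <- function(am) mi$antagonist_gain * am / (mi$antagonist_ec50_mg_ml + am)
    d_mir_c <- g0_cancer + mi$exosome_transfer_per_day * y[[6]] -
      mi$degradation_rate_per_day * (1 + hill_am(y[[3]])) * y[[5]]
    d_mir_t <- mi$production_rate_pm_day -
      mi$degradation_rate_per_day * (1 + hill_am(y[[4]])) * y[[6]]

    # --- PD-L1 (repressed by miR-155) and PD-1 (constant turnover) ---
    d_l_c <- ck$pdl1_production_pm_day * ck$pdl1_repression_pm /
      (ck$pdl1_repression_pm + y[[5]]) - ck$pdl1_degradation_per_day * y[[7]]
    d_l_t <- ck$pdl1_production_pm_day * ck$pdl1_repression_pm /
      (ck$pdl1_repression_pm + y[[6]]) - ck$pdl1_degradation_per_day * y[[8]]
    d_p1 <- ck$pd1_turnover_per_day * (ck$pd1_equilibrium_pm - y[[9]])

    # --- cisplatin ---
    j_cis <- psv(ch$permeability_cm_day, v) * (y[[10]] / v_pl - y[[11]] / vi)
    d_cis_pl <- -ch$clearance_per_day * y[[10]] - j_cis
    d_cis_tu <- j_cis - ch$tumor_elimination_per_day * y[[11]]
    cis_conc <- y[[11]] / vi  # mg/mL

    # --- immune checkpoint inhibitors ---
    j_ate <- psv(ic$permeability_cm_day, v) * (y[[12]] / v_pl - y[[13]] / vi)
    d_ate_pl <- -ic$clearance_per_day * y[[12]] - j_ate
    d_ate_tu <- j_ate - ic$tumor_elimination_per_day * y[[13]]
    j_pem <- psv(ic$permeability_cm_day, v) * (y[[14]] / v_pl - y[[15]] / vi)
    d_pem_pl <- -ic$clearance_per_day * y[[14]] - j_pem
    d_pem_tu <- j_pem - ic$tumor_elimination_per_day * y[[15]]
    # mg/mL -> pM: (g/L) / (g/mol) * 1e12
    ate_pm <- y[[13]] / vi / ic$mw_atezolizumab * 1e12
    pem_pm <- y[[15]] / vi / ic$mw_pembrolizumab * 1e12

    # --- tumor volume ---
    prolif <- 1 + (mi$proliferation_gain - 1) * y[[5]] / (mi$potency_pm + y[[5]])
    ic50_eff <- ch$ic50_mg_ml *
      (1 + ch$resistance_gain * y[[5]] / (mi$potency_pm + y[[5]]))
    d_chemo <- ch$kill_max_per_day * cis_conc / (ic50_eff + cis_conc)
    psi <- checkpoint_occupancy((y[[7]] + y[[8]]) / 2, y[[9]],
                                c(atezolizumab = ate_pm,
                                  pembrolizumab = pem_pm), params)
    d_v <- gr$rate_per_day * prolif * v * (1 - v / gr$carrying_capacity_cm3) -
      d_chemo * v - ck$immune_kill_max_per_day * psi * v

    list(c(d_np_pl, d_np_tu, d_am_c, d_am_t, d_mir_c, d_mir_t,
           d_l_c, d_l_t, d_p1, d_cis_pl, d_cis_tu,
           d_ate_pl, d_ate_tu, d_pem_pl, d_pem_tu, d_v))
  }
}

#' Simulate the model under a dosing regimen
#'
#' Integrates the ODE system from tumor inception (time 0) through the end
#' of follow-up, applying each dose as an instantaneous plasma-mass increment
#' (mg/kg converted to mg by body weight) at its event time; the stiff-capable
#' integrator is restarted at each event. Simultaneous events on the same
#' drug sum. Sub-tolerance negative excursions are clipped to zero; an
#' excursion below -1e-6 raises a numerical-integrity error.
#'
#' @param params A validated `model_parameters` object.
#' @param reg A [regimen()].
#' @param grid Output time grid in absolute days from inception; defaults to
#'   half-day resolution over `[0, treatment_start + follow_up_end]`.
#' @param initial_volume_cm3 Optional baseline tumor volume override.
#' @param rtol,atol Integrator tolerances.
#' @param use_compiled Integrate with the compiled right-hand side (the
#'   default); `FALSE` uses the pure-R evaluator from [build_rhs()], which is
#'   numerically equivalent and retained as a transparency/cross-check path.
#' @return A `trajectory`: a data.frame with `time` (days from inception)
#'   and one column per state, with the parameters and regimen attached as
#'   attributes.
#' @export
simulate_trajectory <- function(params, reg, grid = NULL,
                                initial_volume_cm3 = NULL,
                                rtol = 1e-8, atol = 1e-10,
                                use_compiled = TRUE) {
  if (!inherits(reg, "regimen"))
    stop("simulate_trajectory: 'reg' must be a regimen", call. = FALSE)
  t_end <- reg$treatment_start + reg$follow_up_end
  if (is.null(grid)) grid <- seq(0, t_end, by = 0.5)
  if (min(grid) > 0) grid <- c(0, grid)
  if (use_compiled) {
    validate_parameters(params)
  } else {
    rhs <- build_rhs(params)
  }
  y0 <- initial_state(params, initial_volume_cm3)

  ev <- NULL
  if (length(reg$events)) {
    tab <- regimen_table(reg)
    tab$time_abs <- reg$treatment_start + tab$time_day
    tab$state <- .dose_state[tab$drug]
    tab$mass_mg <- tab$dose_mg_kg * params$species$body_weight_kg
    # simultaneous events on the same drug sum
    agg <- stats::aggregate(mass_mg ~ state + time_abs, tab, sum)
    agg <- agg[agg$mass_mg > 0, , drop = FALSE]
    if (nrow(agg)) {
      ev <- data.frame(var = agg$state, time = agg$time_abs,
                       value = agg$mass_mg, method = "add")
      ev <- ev[order(ev$time), , drop = FALSE]
      grid <- sort(unique(c(grid, ev$time)))
    }
  }
  grid <- grid[grid <= t_end + 1e-9]

  sol <- tryCatch(
    if (use_compiled) {
      ev_c <- ev
      if (!is.null(ev_c)) ev_c$var <- match(ev_c$var, .state_names)
      deSolve::lsoda(y0, grid, func = "antimir_derivs",
                     parms = .rhs_parms(params),
                     dllname = "antimiRsim", initfunc = "antimir_initmod",
                     rtol = rtol, atol = atol,
                     events = if (is.null(ev_c)) NULL else list(data = ev_c),
                     maxsteps = 50000)
    } else {
      deSolve::lsoda(y0, grid, rhs, parms = NULL, rtol = rtol, atol = atol,
                     events = if (is.null(ev)) NULL else list(data = ev),
                     maxsteps = 50000)
    },
    warning = function(w) {
      stop("simulate_trajectory: integrator failure (", conditionMessage(w),
           ")", call. = FALSE)
    })
  sol <- as.data.frame(sol)
  if (nrow(sol) < length(grid))
    stop("simulate_trajectory: integration stopped early at t = ",
         max(sol$time), " d", call. = FALSE)
  states <- as.matrix(sol[, .state_names, drop = FALSE])
  if (min(states) < -1e-6)
    stop("simulate_trajectory: negative state excursion beyond tolerance (",
         signif(min(states), 3), ")", call. = FALSE)
  states[states < 0] <- 0
  out <- data.frame(time = sol$time, states, check.names = FALSE)
  attr(out, "params") <- params
  attr(out, "regimen") <- reg
  class(out) <- c("trajectory", "data.frame")
  out
}

#' Interpolate a trajectory state at arbitrary times
#' @param traj A `trajectory`.
#' @param what State column name.
#' @param times Times (days from inception).
#' @return Numeric vector.
#' @export
trajectory_at <- function(traj, what, times) {
  stats::approx(traj$time, traj[[what]], xout = times, rule = 2)$y
}

#' Percent of injected dose in the tumor interstitium
#'
#' For one nanoparticle dose event, the tumor-interstitial NP mass as a
#' percentage of that event's injected mass, over the window from the event
#' to the next dose of the same drug (or the end of the record).
#'
#' @param traj A `trajectory` from [simulate_trajectory()].
#' @param event A [dose_event()] belonging to the simulated regimen (times in
#'   days from treatment start); its dose must be positive.
#' @return data.frame with `time` (days from inception) and `percent_id`,
#'   values in `[0, 100]`.
#' @export
percent_injected_dose <- function(traj, event) {
  if (event$dose_mg_kg <= 0)
    stop("percent_injected_dose: undefined for a zero dose", call. = FALSE)
  params <- attr(traj, "params"); reg <- attr(traj, "regimen")
  injected <- event$dose_mg_kg * params$species$body_weight_kg
  t0 <- reg$treatment_start + event$time_day
  tab <- regimen_table(reg)
  later <- tab$time_day[tab$drug == event$drug & tab$time_day > event$time_day]
  t1 <- if (length(later)) reg$treatment_start + min(later) else max(traj$time)
  sel <- traj$time >= t0 - 1e-9 & traj$time <= t1 + 1e-9
  data.frame(time = traj$time[sel],
             percent_id = pmin(100, 100 * traj$np_tumor[sel] / injected))
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d time points over %.3g d; final volume %.3g cm^3\n",
              nrow(x), max(x$time), x$volume[nrow(x)]))
  invisible(x)
}

#' Convert a trajectory to tidy long format
#'
#' @param traj A `trajectory`.
#' @param arm,patient_id Optional labels carried into the output.
#' @return data.frame with columns `time`, `variable`, `value`, `arm`,
#'   `patient_id`.
#' @export
trajectory_tidy <- function(traj, arm = NA_character_,
                            patient_id = NA_character_) {
  vars <- setdiff(names(traj), "time")
  out <- do.call(rbind, lapply(vars, function(v)
    data.frame(time = traj$time, variable = v, value = traj[[v]])))
  out$arm <- arm
  out$patient_id <- patient_id
  rownames(out) <- NULL
  out
}
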