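#' Reference regimen for sensitivity analyses
#'
#' The fixed anti-miR-155 regimen against which parameter sensitivities are
#' measured: a presenting average patient (1.5 cm baseline lesion, the
#' week-124 stage IA2 presentation) treated with the allometrically scaled
#' human-equivalent dose (0.026 mg/kg) Q3W for nine cycles; TGI is
#' evaluated at the end of treatment. Anchoring the sweep at presentation
#' (rather than re-growing the tumor from inception under each perturbed
#' parameter set) keeps the response defined across wide growth-rate
#' perturbations.
#'
#' @return A [regimen()] with `treatment_start = 0` (presentation is the
#'   time origin).
#' @export
reference_sensitivity_regimen <- function() {
  regimen(schedule_events("anti_mir155_np", 0.026, "Q3W", 9),
          treatment_start = 0, follow_up_end = 189)
}

# end-of-treatment TGI for a perturbed parameter set (paired control),
# simulated from the presenting 1.5 cm baseline
.tgi_response <- function(params, reg = reference_sensitivity_regimen()) {
  t_end <- reg$treatment_start + reg$follow_up_end
  grid <- unique(c(seq(0, t_end, by = 1), t_end))
  v_base <- volume_from_diameter(1.5)
  ctrl <- simulate_trajectory(params, regimen(list(), reg$treatment_start,
                                              reg$follow_up_end),
                              grid = grid, rtol = 1e-6, atol = 1e-9,
                              initial_volume_cm3 = v_base)
  # TGI is undefined when the perturbed control does not grow over the
  # treatment window (immune kill exceeding proliferation); flag the point
  v0 <- trajectory_at(ctrl, "volume", reg$treatment_start)
  vc <- trajectory_at(ctrl, "volume", reg$treatment_start +
                        end_of_treatment(reg))
  if (vc - v0 <= 1e-3 * v0) return(NA_real_)
  tr <- simulate_trajectory(params, reg, grid = grid,
                            rtol = 1e-6, atol = 1e-9,
                            initial_volume_cm3 = v_base)
  tumor_growth_inhibition(tr, ctrl, end_of_treatment(reg))
}

#' Default parameter set for global sensitivity analysis
#'
#' The 28 biological, transport and drug-effect parameters perturbed in the
#' global analysis (physical constants, molecular weights and the anatomical
#' profile are excluded).
#'
#' @return Character vector of flattened parameter names.
#' @export
default_gsa_parameters <- function() {
  c("growth.rate_per_day", "growth.carrying_capacity_cm3",
    "mirna.proliferation_gain", "mirna.production_rate_pm_day",
    "mirna.degradation_rate_per_day", "mirna.potency_pm",
    "mirna.antagonist_gain", "mirna.antagonist_ec50_mg_ml",
    "mirna.antagonist_degradation_per_day", "mirna.exosome_transfer_per_day",
    "np.diameter_nm", "np.degradation_rate_per_day",
    "np.clearance_rate_per_day", "np.permeability_ref_cm_day",
    "np.diffusivity_ref_cm2_day",
    "transport.vascular_surface_per_cm3",
    "transport.intercapillary_length_um",
    "transport.cell_volume_cancer_ml", "transport.cell_volume_tam_ml",
    "chemo.kill_max_per_day",
    "checkpoint.pdl1_production_pm_day",
    "checkpoint.pdl1_degradation_per_day",
    "checkpoint.pd1_equilibrium_pm", "checkpoint.kd_pd1_pdl1_pm",
    "checkpoint.immune_kill_max_per_day",
    "checkpoint.inhibition_constant_pm", "checkpoint.escape_max",
    "checkpoint.pdl1_repression_pm")
}

#' Local (one-at-a-time) sensitivity sweep
#'
#' Sweeps one parameter over a uniform multiplier grid (default +-50% of
#' baseline) and records end-of-treatment TGI under the reference
#' anti-miR-155 regimen. Simulation failures at individual grid points are
#' flagged, not fatal.
#'
#' @param params Baseline `model_parameters` (human).
#' @param name Flattened parameter name to sweep.
#' @param span Half-width of the multiplier range (0.5 = +-50%).
#' @param n_points Number of grid points (>= 3; an odd count includes the
#'   unperturbed baseline).
#' @param reg Reference regimen (default [reference_sensitivity_regimen()]).
#' @return data.frame: `multiplier`, `value`, `tgi`, `ok`.
#' @export
local_sensitivity <- function(params, name, span = 0.5, n_points = 11,
                              reg = reference_sensitivity_regimen()) {
  if (n_points < 3) stop("local_sensitivity: n_points >= 3", call. = FALSE)
  flat <- params_flatten(params)
  if (!name %in% names(flat))
    stop("local_sensitivity: unknown parameter '", name, "'", call. = FALSE)
  if (flat[[name]] <= 0)
    stop("local_sensitivity: baseline value must be positive", call. = FALSE)
  mults <- seq(1 - span, 1 + span, length.out = n_points)
  out <- lapply(mults, function(m) {
    tgi <- try(.tgi_response(perturb_parameters(
      params, stats::setNames(m, name)), reg), silent = TRUE)
    ok <- !inherits(tgi, "try-error") && is.finite(tgi)
    data.frame(multiplier = m, value = flat[[name]] * m,
               tgi = if (ok) tgi else NA_real_, ok = ok)
  })
  do.call(rbind, out)
}

#' Global sensitivity analysis with regression-based sensitivity indices
#'
#' Latin-hypercube perturbation of many parameters simultaneously
#' (multipliers uniform in `1 +- span`), end-of-treatment TGI as the
#' response, and sensitivity indices (SI) defined as the standardized
#' coefficients of a multivariate linear regression of the response on the
#' multipliers. Replicate LHS designs give an SI distribution per parameter;
#' parameters are then rank-ordered by one-way ANOVA on |SI| with Tukey HSD
#' grouping into homogeneous letter categories.
#'
#' @param params Baseline `model_parameters` (human).
#' @param names Parameters to perturb (default [default_gsa_parameters()]).
#' @param n_samples LHS samples per replicate (>= 10x the number of
#'   parameters).
#' @param n_replicates Number of re-sampled LHS designs.
#' @param span Half-width of the multiplier range.
#' @param seed Integer seed (the whole analysis is deterministic).
#' @param response_fn Response evaluated per sample: a
#'   `function(params_perturbed, multipliers)` returning a scalar. The
#'   default simulates end-of-treatment TGI under the reference regimen.
#' @return A `sensitivity_report`: list with `si` (data.frame: `parameter`,
#'   `replicate`, `si`), `ranking` (data.frame: `parameter`, `mean_abs_si`,
#'   `group`), `anova_p`, and the call settings.
#' @export
global_sensitivity <- function(params, names = default_gsa_parameters(),
                               n_samples = 500, n_replicates = 20,
                               span = 0.5, seed = 155,
                               response_fn = NULL) {
  if (!length(names)) stop("global_sensitivity: empty parameter set",
                           call. = FALSE)
  k <- length(names)
  if (n_samples < 10 * k)
    stop("global_sensitivity: n_samples must be >= 10x the number of ",
         "parameters (", 10 * k, ")", call. = FALSE)
  if (is.null(response_fn))
    response_fn <- function(p, mult) .tgi_response(p)
  flat <- params_flatten(params)
  bad <- setdiff(names, base::names(flat))
  if (length(bad))
    stop("global_sensitivity: unknown parameter(s): ",
         paste(bad, collapse = ", "), call. = FALSE)

  si_rows <- .with_seed(seed, {
    lapply(seq_len(n_replicates), function(rep_i) {
      design <- 1 - span + 2 * span * lhs::randomLHS(n_samples, k)
      colnames(design) <- names
      y <- apply(design, 1, function(mult) {
        p <- try(perturb_parameters(params, stats::setNames(mult, names)),
                 silent = TRUE)
        if (inherits(p, "try-error")) return(NA_real_)
        val <- try(response_fn(p, mult), silent = TRUE)
        if (inherits(val, "try-error")) NA_real_ else val
      })
      keep <- is.finite(y)
      X <- scale(design[keep, , drop = FALSE])
      if (qr(X)$rank < k)
        stop("global_sensitivity: rank-deficient design; increase n_samples",
             call. = FALSE)
      ys <- as.numeric(scale(y[keep]))
      co <- stats::coef(stats::lm(ys ~ X))[-1]
      data.frame(parameter = names, replicate = rep_i,
                 si = as.numeric(co))
    })
  })
  si <- do.call(rbind, si_rows)

  ranking <- NULL; anova_p <- NA_real_
  if (n_replicates >= 2) {
    si$abs_si <- abs(si$si)
    si$parameter_f <- factor(si$parameter)
    fit <- stats::aov(abs_si ~ parameter_f, data = si)
    anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit)$parameter_f
    means <- tapply(si$abs_si, si$parameter_f, mean)
    ranking <- .letter_groups(means, tk)
  }
  structure(list(si = si[, c("parameter", "replicate", "si")],
                 ranking = ranking, anova_p = anova_p,
                 n_samples = n_samples, n_replicates = n_replicates,
                 span = span, seed = seed),
            class = "sensitivity_report")
}

# Greedy compact-letter grouping from Tukey HSD pairwise p-values: order
# parameters by decreasing mean |SI| and place each into the first existing
# group with which it is not significantly different (else a new group).
.letter_groups <- function(means, tukey, alpha = 0.05) {
  pmat <- function(a, b) {
    key1 <- paste(a, b, sep = "-"); key2 <- paste(b, a, sep = "-")
    rn <- rownames(tukey)
    if (key1 %in% rn) tukey[key1, "p adj"]
    else if (key2 %in% rn) tukey[key2, "p adj"] else NA_real_
  }
  ord <- base::names(sort(means, decreasing = TRUE))
  groups <- list()
  assign_grp <- character(length(ord)); base::names(assign_grp) <- ord
  for (p in ord) {
    placed <- FALSE
    for (gi in seq_along(groups)) {
      if (all(vapply(groups[[gi]], function(q) {
        pv <- pmat(p, q); is.na(pv) || pv > alpha
      }, logical(1)))) {
        groups[[gi]] <- c(groups[[gi]], p)
        assign_grp[p] <- letters[gi]
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      groups[[length(groups) + 1]] <- p
      assign_grp[p] <- letters[length(groups)]
    }
  }
  data.frame(parameter = ord, mean_abs_si = as.numeric(means[ord]),
             group = unname(assign_grp[ord]))
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("<sensitivity_report> %d parameters, %d samples x %d replicates\n",
              length(unique(x$si$parameter)), x$n_samples, x$n_replicates))
  if (!is.null(x$ranking)) {
    top <- utils::head(x$ranking, 5)
    for (i in seq_len(nrow(top)))
      cat(sprintf("  %-40s |SI| %.3f  group %s\n", top$parameter[i],
                  top$mean_abs_si[i], top$group[i]))
  }
  invisible(x)
}
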