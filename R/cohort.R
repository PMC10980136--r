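#' The sensitivity-ranked parameter set used for population variability
#'
#' The ten parameters that dominate tumor response to anti-miR-155 therapy
#' (tumor growth rate and miR-155 proliferation gain, NP size and
#' degradation, and the miR-155/anti-miR-155 axis constants); used as the
#' default perturbation set for virtual-patient sampling and prediction
#' intervals.
#'
#' @return Character vector of flattened parameter names.
#' @export
default_sensitive_parameters <- function() {
  c("growth.rate_per_day", "mirna.proliferation_gain",
    "np.diameter_nm", "mirna.production_rate_pm_day",
    "mirna.potency_pm", "mirna.degradation_rate_per_day",
    "mirna.antagonist_gain", "mirna.antagonist_ec50_mg_ml",
    "mirna.antagonist_degradation_per_day", "np.degradation_rate_per_day")
}

# default lognormal sigma: ~95% of multiplicative perturbations within +-30%
.default_cohort_sigma <- log(1.3) / stats::qnorm(0.975)

#' Generate a virtual patient cohort
#'
#' Accept-reject sampling of virtual patients: multiplicative lognormal
#' perturbations of the sensitive parameters are proposed around the base
#' (average-patient) parameterization, untreated growth is simulated from a
#' single founding cell to the screening time (week 124), and the proposal
#' is accepted iff the resulting baseline tumor diameter lies within the
#' stage IA window of 1-2.68 cm (volumes ~0.5-10 cm^3). Fully deterministic
#' given `seed`.
#'
#' @param base_params Human `model_parameters` for the average patient.
#' @param n Number of accepted patients (default 1000).
#' @param sigma Either a single lognormal sigma applied to every sampled
#'   parameter or a named vector; default calibrated so ~95% of proposals
#'   fall within +-30% of baseline.
#' @param sampled_parameters Flattened parameter names to perturb (default
#'   [default_sensitive_parameters()]).
#' @param seed Integer seed.
#' @param screening_day Day of treatment start relative to inception
#'   (default 868 = week 124).
#' @param volume_range Acceptance window for baseline volume, cm^3.
#' @param max_proposals Proposal cap guarding against a degenerate spec.
#' @return A `cohort`: list with `patients` (data.frame: `patient_id`,
#'   `baseline_volume_cm3`, `baseline_diameter_cm`, one `mult.<name>` column
#'   per sampled parameter), `base_params`, `seed`, `proposals`,
#'   `acceptance_rate`, `screening_day`.
#' @export
sample_cohort <- function(base_params, n = 1000,
                          sigma = .default_cohort_sigma,
                          sampled_parameters = default_sensitive_parameters(),
                          seed = 155,
                          screening_day = 868,
                          volume_range = volume_from_diameter(c(1, 2.68)),
                          max_proposals = 1e5) {
  if (n < 1) stop("sample_cohort: n must be >= 1", call. = FALSE)
  flat <- params_flatten(base_params)
  bad <- setdiff(sampled_parameters, names(flat))
  if (length(bad))
    stop("sample_cohort: unknown sampled parameter(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  k <- length(sampled_parameters)
  if (length(sigma) == 1) sigma <- stats::setNames(rep(sigma, k),
                                                   sampled_parameters)
  sigma <- sigma[sampled_parameters]

  grow_reg <- regimen(list(), treatment_start = screening_day,
                      follow_up_end = 1)
  grid <- seq(0, screening_day + 1, by = 4)
  accepted <- vector("list", n)
  n_acc <- 0L; n_prop <- 0L
  .with_seed(seed, {
    while (n_acc < n) {
      if (n_prop >= max_proposals)
        stop("sample_cohort: acceptance rate too low after ", n_prop,
             " proposals; widen the growth-rate prior or the volume window",
             call. = FALSE)
      mult <- stats::setNames(exp(stats::rnorm(k, 0, sigma)),
                              sampled_parameters)
      n_prop <- n_prop + 1L
      p <- try(perturb_parameters(base_params, mult), silent = TRUE)
      if (inherits(p, "try-error")) next
      tr <- try(simulate_trajectory(p, grow_reg, grid = grid,
                                    rtol = 1e-6, atol = 1e-9),
                silent = TRUE)
      if (inherits(tr, "try-error")) next
      v <- trajectory_at(tr, "volume", screening_day)
      if (v >= volume_range[1] && v <= volume_range[2]) {
        n_acc <- n_acc + 1L
        accepted[[n_acc]] <- c(baseline_volume_cm3 = v, mult)
      }
    }
  })
  tab <- as.data.frame(do.call(rbind, accepted))
  names(tab) <- c("baseline_volume_cm3",
                  paste0("mult.", sampled_parameters))
  tab <- cbind(patient_id = sprintf("vp%04d", seq_len(n)), tab)
  tab$baseline_diameter_cm <- diameter_from_volume(tab$baseline_volume_cm3)
  structure(list(patients = tab, base_params = base_params, seed = seed,
                 proposals = n_prop, acceptance_rate = n / n_prop,
                 sampled_parameters = sampled_parameters,
                 screening_day = screening_day),
            class = "cohort")
}

#' Reconstruct one virtual patient's parameter set
#' @param cohort A [sample_cohort()] result.
#' @param i Patient index (or `patient_id` string).
#' @return `model_parameters` for that patient.
#' @export
patient_parameters <- function(cohort, i) {
  if (is.character(i)) i <- match(i, cohort$patients$patient_id)
  row <- cohort$patients[i, ]
  mult <- as.numeric(row[paste0("mult.", cohort$sampled_parameters)])
  names(mult) <- cohort$sampled_parameters
  perturb_parameters(cohort$base_params, mult)
}

#' Simulate a treatment regimen across a cohort
#'
#' Each patient is simulated from treatment start (their accepted baseline
#' volume, molecular species at their own pre-treatment equilibrium) under
#' the given regimen, and the RECIST 1.1 time to progression is extracted.
#'
#' @param cohort A [sample_cohort()] result.
#' @param reg A [regimen()] with `treatment_start = 0` (the cohort's
#'   screening time is the time origin).
#' @param follow_up_end_day Censoring horizon, days from treatment start
#'   (default: the regimen's follow-up end).
#' @param grid_by Output resolution in days.
#' @return data.frame: `patient_id`, `ttp_months`, `event`,
#'   `end_volume_cm3`, `best_response`.
#' @export
cohort_ttp <- function(cohort, reg, follow_up_end_day = NULL, grid_by = 1) {
  if (abs(reg$treatment_start) > 1e-9)
    stop("cohort_ttp: regimen must have treatment_start = 0 (the cohort ",
         "baseline is the time origin)", call. = FALSE)
  if (is.null(follow_up_end_day)) follow_up_end_day <- reg$follow_up_end
  grid <- seq(0, reg$follow_up_end, by = grid_by)
  out <- lapply(seq_len(nrow(cohort$patients)), function(i) {
    p <- patient_parameters(cohort, i)
    tr <- simulate_trajectory(
      p, reg, grid = grid, rtol = 1e-6, atol = 1e-9,
      initial_volume_cm3 = cohort$patients$baseline_volume_cm3[i])
    ttp <- time_to_progression(tr, follow_up_end_day = follow_up_end_day)
    data.frame(patient_id = cohort$patients$patient_id[i],
               ttp_months = ttp$ttp_months, event = ttp$event,
               end_volume_cm3 = tr$volume[nrow(tr)],
               best_response = best_response(ttp$stream))
  })
  do.call(rbind, out)
}

#' Mean end-of-treatment TGI of a regimen across a cohort
#'
#' Paired control/treated simulation per patient; returns the mean TGI at
#' `t_day` over patients (the effect measure used for combination-index
#' screening).
#'
#' @inheritParams cohort_ttp
#' @param t_day Assessment time (days from treatment start).
#' @return Mean TGI (percent).
#' @export
cohort_tgi <- function(cohort, reg, t_day) {
  ctrl_reg <- regimen(list(), 0, reg$follow_up_end)
  grid <- seq(0, reg$follow_up_end, by = 1)
  tgis <- vapply(seq_len(nrow(cohort$patients)), function(i) {
    p <- patient_parameters(cohort, i)
    v0 <- cohort$patients$baseline_volume_cm3[i]
    ctrl <- simulate_trajectory(p, ctrl_reg, grid = grid, rtol = 1e-6,
                                atol = 1e-9, initial_volume_cm3 = v0)
    tr <- simulate_trajectory(p, reg, grid = grid, rtol = 1e-6,
                              atol = 1e-9, initial_volume_cm3 = v0)
    tumor_growth_inhibition(tr, ctrl, t_day)
  }, numeric(1))
  mean(tgis)
}

#' @export
print.cohort <- function(x, ...) {
  d <- x$patients$baseline_diameter_cm
  cat(sprintf("<cohort> %d virtual patients (acceptance %.1f%%, seed %d)\n",
              nrow(x$patients), 100 * x$acceptance_rate, x$seed))
  cat(sprintf("  baseline diameter: %.2f-%.2f cm (median %.2f)\n",
              min(d), max(d), stats::median(d)))
  invisible(x)
}

#' Write / read a cohort as JSON lines (one patient per line)
#' @param cohort A `cohort`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_cohort_jsonl <- function(cohort, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(cohort$patients)))
    writeLines(jsonlite::toJSON(as.list(cohort$patients[i, ]),
                                auto_unbox = TRUE, digits = NA), con)
  invisible(path)
}

#' Synthesize paper-like preclinical growth datasets
#'
#' Generates multi-arm xenograft growth data from the model itself: each
#' arm's mean trajectory is simulated under its regimen and observed at
#' twice-weekly caliper-like time points with multiplicative lognormal
#' replicate noise. The default arm set mirrors a pooled preclinical design:
#' five treatment arms (anti-miR-155, cisplatin, their combination,
#' atezolizumab, pembrolizumab) plus two independent control datasets.
#' These synthetic fixtures stand in for digitized literature data and are
#' the packaged calibration inputs.
#'
#' @param true_params Generating `model_parameters` (mouse).
#' @param arms Named list of regimens (default [preclinical_regimens()]
#'   with a duplicated control arm).
#' @param noise_sigma Lognormal sigma of replicate noise (0 = noise-free).
#' @param replicates Replicates per arm.
#' @param seed Integer seed.
#' @return Named list of [growth_dataset()]s.
#' @export
synth_preclinical_dataset <- function(true_params, arms = NULL,
                                      noise_sigma = 0.05, replicates = 8,
                                      seed = 1) {
  if (noise_sigma < 0) stop("synth_preclinical_dataset: noise_sigma >= 0",
                            call. = FALSE)
  if (replicates < 1) stop("synth_preclinical_dataset: replicates >= 1",
                           call. = FALSE)
  if (is.null(arms)) {
    arms <- preclinical_regimens()
    arms <- c(arms["control"], stats::setNames(arms["control"], "control_ici"),
              arms[setdiff(names(arms), "control")])
  }
  .with_seed(seed, lapply(stats::setNames(nm = names(arms)), function(a) {
    reg <- arms[[a]]
    t_obs <- seq(reg$treatment_start,
                 reg$treatment_start + reg$follow_up_end, by = 3.5)
    tr <- simulate_trajectory(true_params, reg,
                              grid = sort(unique(c(0, t_obs))),
                              rtol = 1e-8, atol = 1e-10)
    mean_mm3 <- trajectory_at(tr, "volume", t_obs) * 1000
    obs <- do.call(rbind, lapply(seq_len(replicates), function(r) {
      noise <- if (noise_sigma > 0)
        exp(stats::rnorm(length(t_obs), 0, noise_sigma)) else 1
      data.frame(time_day = t_obs, volume_mm3 = mean_mm3 * noise,
                 replicate = r)
    }))
    growth_dataset(a, reg, obs)
  }))
}

#' Write growth datasets to a tidy CSV
#' @param datasets List of [growth_dataset()]s.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_growth_csv <- function(datasets, path) {
  tab <- do.call(rbind, lapply(datasets, function(d)
    cbind(arm = d$arm, d$observations)))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
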