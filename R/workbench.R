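#' Run a named, seeded experiment workflow
#'
#' Configuration-driven orchestration of the package's analyses. The config
#' is a named list (or path to a JSON file holding one) with at least
#' `experiment` and `out_dir`; seeds must be explicit where an experiment is
#' stochastic. Outputs (CSV/JSON per experiment) are written atomically to
#' `out_dir` together with a `manifest.json` recording the package version,
#' the config, seeds and runtimes. Experiments:
#'
#' * `calibrate` — synthesize preclinical datasets (seed, noise_sigma,
#'   replicates) and run the pooled fit over `free` parameters.
#' * `scale` — allometrically scale the mouse defaults and write the human
#'   parameter file.
#' * `dose-response` — dose grid + Hill fits for a schedule.
#' * `cohort` — generate a virtual cohort (n, seed).
#' * `monotherapy-trial` — cohort + Q3W dose ladder -> TTP, KM, median PFS.
#' * `gsa` — global sensitivity analysis.
#' * `screen` — combination synergy screen.
#'
#' @param config Named list or path to a JSON config.
#' @return The result bundle (list), invisibly; side effect: files in
#'   `out_dir`.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  if (is.null(config$experiment))
    stop("run_experiment: config needs an 'experiment' name", call. = FALSE)
  if (is.null(config$out_dir))
    stop("run_experiment: config needs an 'out_dir'", call. = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  runner <- switch(config$experiment,
    "calibrate" = .exp_calibrate,
    "scale" = .exp_scale,
    "dose-response" = .exp_dose_response,
    "cohort" = .exp_cohort,
    "monotherapy-trial" = .exp_trial,
    "gsa" = .exp_gsa,
    "screen" = .exp_screen,
    stop("run_experiment: unknown experiment '", config$experiment, "'",
         call. = FALSE))
  result <- runner(config)
  manifest <- list(
    experiment = config$experiment,
    package_version = as.character(utils::packageVersion("antimiRsim")),
    config = config,
    runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    outputs = result$files)
  .write_json_atomic(manifest, file.path(config$out_dir, "manifest.json"))
  invisible(result)
}

.write_json_atomic <- function(x, path) {
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  file.rename(tmp, path)
  invisible(path)
}

.write_csv_atomic <- function(x, path) {
  tmp <- paste0(path, ".tmp")
  utils::write.csv(x, tmp, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

.cfg <- function(config, name, default) {
  if (is.null(config[[name]])) default else config[[name]]
}

.exp_calibrate <- function(config) {
  p <- default_mouse_parameters()
  seed <- .cfg(config, "seed", 1)
  ds <- synth_preclinical_dataset(
    p, noise_sigma = .cfg(config, "noise_sigma", 0.05),
    replicates = .cfg(config, "replicates", 8), seed = seed)
  free_names <- .cfg(config, "free",
                     c("growth.rate_per_day", "mirna.proliferation_gain",
                       "chemo.kill_max_per_day"))
  fl <- params_flatten(p)
  free <- lapply(stats::setNames(nm = free_names), function(nm)
    c(fl[[nm]] / 5, fl[[nm]] * 5))
  start <- params_unflatten(
    replace(fl, free_names, fl[free_names] * 1.3), p)
  fit <- fit_parameters(start, free, ds,
                        n_starts = .cfg(config, "n_starts", 1), seed = seed)
  f1 <- .write_csv_atomic(fit$fitted, file.path(config$out_dir,
                                                "calibration_fit.csv"))
  f2 <- .write_json_atomic(
    list(estimate = as.list(fit$estimate), objective = fit$objective,
         pearson_r = fit$pearson_r, pearson_p = fit$pearson_p,
         converged = fit$converged),
    file.path(config$out_dir, "calibration_report.json"))
  list(fit = fit, files = c(f1, f2))
}

.exp_scale <- function(config) {
  pm <- if (!is.null(config$mouse_params)) read_parameters_json(
    config$mouse_params) else default_mouse_parameters()
  ph <- scale_parameter_set(pm)
  f <- file.path(config$out_dir, "human_parameters.json")
  write_parameters_json(ph, f)
  list(params = ph, files = f)
}

.exp_dose_response <- function(config) {
  ph <- default_human_parameters()
  doses <- .cfg(config, "doses", default_dose_grid(
    .cfg(config, "n_doses", 20)))
  schedule <- .cfg(config, "schedule", "Q3W")
  grid <- run_dose_grid(ph, doses, schedule)
  hill <- fit_hill(grid$dose[grid$ok], grid$tgi[grid$ok], "eq1")
  f1 <- .write_csv_atomic(grid, file.path(config$out_dir,
                                          "dose_response.csv"))
  f2 <- .write_json_atomic(
    list(schedule = schedule, coefficients = as.list(hill$coefficients),
         ec99 = ec_p(hill, 99)),
    file.path(config$out_dir, "hill_fit.json"))
  list(grid = grid, hill = hill, files = c(f1, f2))
}

.exp_cohort <- function(config) {
  ph <- default_human_parameters()
  co <- sample_cohort(ph, n = .cfg(config, "n_patients", 1000),
                      seed = .cfg(config, "seed", 155))
  f <- file.path(config$out_dir, "cohort.jsonl")
  write_cohort_jsonl(co, f)
  list(cohort = co, files = f)
}

.exp_trial <- function(config) {
  ph <- default_human_parameters()
  co <- sample_cohort(ph, n = .cfg(config, "n_patients", 200),
                      seed = .cfg(config, "seed", 155))
  doses <- .cfg(config, "doses", c(0.026, 0.3, 2.5))
  fu <- .cfg(config, "follow_up_end", 430)
  arms <- c(list(control = regimen(list(), 0, fu)),
            stats::setNames(lapply(doses, function(d)
              clinical_regimen(dose_mg_kg = d, schedule = "Q3W",
                               treatment_start = 0, follow_up_end = fu)),
              paste0("dose_", doses)))
  rows <- lapply(names(arms), function(a) {
    tt <- cohort_ttp(co, arms[[a]])
    cbind(arm = a, tt)
  })
  endpoints <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(names(arms), function(a) {
    tt <- endpoints[endpoints$arm == a, ]
    km <- kaplan_meier(tt$ttp_months, tt$event)
    data.frame(arm = a, median_pfs_months = median_pfs(km),
               events = sum(tt$event), n = nrow(tt))
  }))
  f1 <- .write_csv_atomic(endpoints, file.path(config$out_dir,
                                               "trial_endpoints.csv"))
  f2 <- .write_csv_atomic(summary, file.path(config$out_dir,
                                             "trial_summary.csv"))
  list(endpoints = endpoints, summary = summary, cohort = co,
       files = c(f1, f2))
}

.exp_gsa <- function(config) {
  ph <- default_human_parameters()
  rep <- global_sensitivity(
    ph, names = .cfg(config, "parameters", default_gsa_parameters()),
    n_samples = .cfg(config, "n_samples", 500),
    n_replicates = .cfg(config, "n_replicates", 20),
    seed = .cfg(config, "seed", 155))
  f1 <- .write_csv_atomic(rep$si, file.path(config$out_dir,
                                            "gsa_si_samples.csv"))
  f2 <- .write_json_atomic(
    list(ranking = rep$ranking, anova_p = rep$anova_p),
    file.path(config$out_dir, "gsa_report.json"))
  list(report = rep, files = c(f1, f2))
}

.exp_screen <- function(config) {
  ph <- default_human_parameters()
  drugs <- .cfg(config, "drugs", c("anti_mir155_np", "cisplatin"))
  co <- NULL
  if (.cfg(config, "n_patients", 0) > 0)
    co <- sample_cohort(ph, n = config$n_patients,
                        seed = .cfg(config, "seed", 155))
  sc <- screen_combinations(drugs, cohort = co, params = ph,
                            n_samples = .cfg(config, "n_samples", 50),
                            seed = .cfg(config, "seed", 155))
  f1 <- .write_csv_atomic(sc, file.path(config$out_dir, "screen.csv"))
  conds <- list(
    strong_synergy = synergy_conditions(sc, "strong-synergy"),
    antagonism = synergy_conditions(sc, "antagonism"))
  f2 <- .write_json_atomic(conds, file.path(config$out_dir,
                                            "synergy_conditions.json"))
  list(screen = sc, conditions = conds, files = c(f1, f2))
}
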