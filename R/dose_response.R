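#' Build a clinical anti-tumor regimen on the human timeline
#'
#' Treatment starts at week 124 post-inception (the stage IA2 screening
#' time); the default cycle counts per schedule (QW 25, Q2W 13, Q3W 9) give
#' a ~six-month treatment course.
#'
#' @param drug Drug id (see [dose_event()]).
#' @param dose_mg_kg Per-dose amount, mg/kg.
#' @param schedule `"QW"`, `"Q2W"` or `"Q3W"`.
#' @param n_cycles Dose count (default per schedule, six-month course).
#' @param treatment_start Days from inception (default 868; use 0 for
#'   cohort simulations that start at the screening baseline).
#' @param follow_up_end Days from treatment start (default 189).
#' @return A [regimen()].
#' @export
clinical_regimen <- function(drug = "anti_mir155_np", dose_mg_kg,
                             schedule = c("Q3W", "Q2W", "QW"),
                             n_cycles = NULL, treatment_start = 868,
                             follow_up_end = 189) {
  schedule <- match.arg(schedule)
  if (is.null(n_cycles))
    n_cycles <- switch(schedule, QW = 25, Q2W = 13, Q3W = 9)
  regimen(schedule_events(drug, dose_mg_kg, schedule, n_cycles),
          treatment_start = treatment_start, follow_up_end = follow_up_end)
}

#' Default log-uniform dose grid
#' @param n Number of doses.
#' @param range Dose range in mg/kg.
#' @return Numeric vector, log-uniformly spaced.
#' @export
default_dose_grid <- function(n = 20, range = c(1e-3, 10)) {
  exp(seq(log(range[1]), log(range[2]), length.out = n))
}

#' Run a dose grid under a fixed schedule
#'
#' Simulates anti-miR-155 monotherapy at each dose (treatment from week 124,
#' ~six months), sharing a single control arm, and records end-of-treatment
#' TGI and the RECIST diameter-change endpoint. Per-dose simulation failures
#' are recorded (`ok = FALSE`), not fatal.
#'
#' @param params_human Human `model_parameters`.
#' @param doses Dose vector, mg/kg (> 0); default
#'   [default_dose_grid()].
#' @param schedule `"QW"`, `"Q2W"` or `"Q3W"`.
#' @param treatment_start,follow_up_end Timeline (days); defaults as in
#'   [clinical_regimen()].
#' @return data.frame: `dose`, `tgi`, `diameter_change`, `ok`; the schedule
#'   is attached as an attribute.
#' @export
run_dose_grid <- function(params_human, doses = default_dose_grid(),
                          schedule = c("Q3W", "Q2W", "QW"),
                          treatment_start = 868, follow_up_end = 189) {
  schedule <- match.arg(schedule)
  if (any(doses <= 0)) stop("run_dose_grid: doses must be > 0",
                            call. = FALSE)
  grid <- seq(0, treatment_start + follow_up_end, by = 1)
  ctrl <- simulate_trajectory(
    params_human, regimen(list(), treatment_start, follow_up_end),
    grid = grid, rtol = 1e-6, atol = 1e-9)
  eot <- end_of_treatment(clinical_regimen(dose_mg_kg = 1,
                                           schedule = schedule,
                                           treatment_start = treatment_start,
                                           follow_up_end = follow_up_end))
  out <- lapply(doses, function(d) {
    reg <- clinical_regimen(dose_mg_kg = d, schedule = schedule,
                            treatment_start = treatment_start,
                            follow_up_end = follow_up_end)
    res <- try({
      tr <- simulate_trajectory(params_human, reg, grid = grid,
                                rtol = 1e-6, atol = 1e-9)
      c(tumor_growth_inhibition(tr, ctrl, eot),
        diameter_change_percent(tr, eot))
    }, silent = TRUE)
    if (inherits(res, "try-error"))
      data.frame(dose = d, tgi = NA_real_, diameter_change = NA_real_,
                 ok = FALSE)
    else data.frame(dose = d, tgi = res[1], diameter_change = res[2],
                    ok = TRUE)
  })
  out <- do.call(rbind, out)
  attr(out, "schedule") <- schedule
  out
}

#' Fit a Hill dose-response model
#'
#' Two forms: `eq1`, `E = Emax / (1 + (EC50/D)^n)` (effect zero at zero
#' dose), and `eq2`, `E = Emin + (Emax - Emin) / (1 + (EC50/D)^n)` (`Emin`
#' is the effect at zero dose; used for the RECIST diameter-change endpoint,
#' where the response decreases from a large zero-dose change). Plain
#' (unweighted) least squares via [minpack.lm::nlsLM()], start values from a
#' log-log (logit) linearization, with `n` bounded to (0.05, 10] and `EC50`
#' to within 10x the dose span.
#'
#' @param doses Dose vector (>= 4 points spanning >= 2 decades).
#' @param effects Observed effects (same length).
#' @param form `"eq1"` or `"eq2"`.
#' @return A `hill_fit`: list with `coefficients` (named: `emax`, `ec50`,
#'   `n`, and `emin` for eq2), `vcov`, `form`, `fitted`, `ill_conditioned`.
#' @export
fit_hill <- function(doses, effects, form = c("eq1", "eq2")) {
  form <- match.arg(form)
  keep <- is.finite(doses) & is.finite(effects)
  doses <- doses[keep]; effects <- effects[keep]
  if (length(doses) < 4)
    stop("fit_hill: need >= 4 dose points", call. = FALSE)
  span_ok <- log10(max(doses) / min(doses)) >= 2
  if (!span_ok)
    warning("fit_hill: doses span fewer than 2 decades; ",
            "the fit may be ill-conditioned")

  ord <- order(doses); doses <- doses[ord]; effects <- effects[ord]
  if (form == "eq1") {
    emax0 <- max(effects) * 1.05 + 1e-9
    frac <- pmin(pmax(effects / emax0, 1e-3), 1 - 1e-3)
    lin <- stats::lm(stats::qlogis(frac) ~ log(doses))
    n0 <- unname(min(max(abs(stats::coef(lin)[2]), 0.1), 5))
    ec0 <- unname(exp(-stats::coef(lin)[1] / stats::coef(lin)[2]))
    if (!is.finite(ec0) || ec0 <= 0) ec0 <- stats::median(doses)
    fit <- minpack.lm::nlsLM(
      effects ~ emax / (1 + (ec50 / doses)^n),
      start = list(emax = emax0, ec50 = ec0, n = n0),
      lower = c(emax = -Inf, ec50 = min(doses) / 10, n = 0.05),
      upper = c(emax = Inf, ec50 = max(doses) * 10, n = 10),
      control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    emin0 <- effects[1]; emax0 <- effects[length(effects)]
    ec0 <- stats::median(doses)
    fit <- minpack.lm::nlsLM(
      effects ~ emin + (emax - emin) / (1 + (ec50 / doses)^n),
      start = list(emin = emin0, emax = emax0, ec50 = ec0, n = 1),
      lower = c(emin = -Inf, emax = -Inf, ec50 = min(doses) / 10, n = 0.05),
      upper = c(emin = Inf, emax = Inf, ec50 = max(doses) * 10, n = 10),
      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  co <- stats::coef(fit)
  vc <- try(stats::vcov(fit), silent = TRUE)
  if (inherits(vc, "try-error")) vc <- matrix(NA_real_, length(co),
                                              length(co))
  structure(list(coefficients = co, vcov = vc, form = form,
                 fitted = stats::fitted(fit),
                 residuals = stats::resid(fit),
                 ill_conditioned = !span_ok),
            class = "hill_fit")
}

#' Evaluate a fitted Hill model
#' @param fit A `hill_fit`.
#' @param dose Dose(s), mg/kg.
#' @return Predicted effect(s).
#' @export
predict_hill <- function(fit, dose) {
  co <- fit$coefficients
  base <- 1 / (1 + (co[["ec50"]] / dose)^co[["n"]])
  if (fit$form == "eq1") co[["emax"]] * base
  else co[["emin"]] + (co[["emax"]] - co[["emin"]]) * base
}

#' Invert a Hill fit for the EC_p dose
#'
#' Closed form: `D = EC50 * (p / (100 - p))^(1/n)` — the dose producing p%
#' of the maximal effect (of the Emin-to-Emax span for eq2).
#'
#' @param fit A `hill_fit`.
#' @param p Percent of maximal effect, in (0, 100).
#' @return Dose in mg/kg.
#' @export
ec_p <- function(fit, p) {
  if (any(p <= 0 | p >= 100))
    stop("ec_p: p must lie strictly between 0 and 100", call. = FALSE)
  co <- fit$coefficients
  co[["ec50"]] * (p / (100 - p))^(1 / co[["n"]])
}

#' @export
print.hill_fit <- function(x, ...) {
  co <- x$coefficients
  cat("<hill_fit> form", x$form, ":",
      paste(sprintf("%s = %.4g", names(co), co), collapse = ", "), "\n")
  invisible(x)
}

#' Latin-hypercube prediction intervals for a dose-response curve
#'
#' Draws `n_sets` joint parameter perturbations (LHS, multipliers uniform in
#' `1 +- span`) of the sensitive parameters, recomputes the TGI dose-response
#' for each set, and returns per-dose empirical percentile bands.
#'
#' @param params_human Baseline human `model_parameters`.
#' @param doses Dose grid (mg/kg).
#' @param schedule Injection schedule.
#' @param sensitive Parameters to perturb (default
#'   [default_sensitive_parameters()]).
#' @param n_sets Number of parameter sets (>= 100).
#' @param span Half-width of the multiplier range (default 0.1 = +-10%).
#' @param level Interval coverage (default 0.9: 5th-95th percentiles).
#' @param seed Integer seed.
#' @return data.frame: `dose`, `lower`, `median`, `upper`.
#' @export
prediction_interval <- function(params_human, doses = default_dose_grid(),
                                schedule = "Q3W",
                                sensitive = default_sensitive_parameters(),
                                n_sets = 1000, span = 0.1, level = 0.9,
                                seed = 155) {
  if (n_sets < 100)
    stop("prediction_interval: n_sets must be >= 100 (interval unstable)",
         call. = FALSE)
  flat <- params_flatten(params_human)
  bad <- setdiff(sensitive, names(flat))
  if (length(bad))
    stop("prediction_interval: unknown sensitive parameter(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  k <- length(sensitive)
  design <- .with_seed(seed, 1 - span + 2 * span * lhs::randomLHS(n_sets, k))
  tgis <- apply(design, 1, function(mult) {
    p <- perturb_parameters(params_human, stats::setNames(mult, sensitive))
    run_dose_grid(p, doses, schedule)$tgi
  })
  tgis <- matrix(tgis, nrow = length(doses))
  alpha <- (1 - level) / 2
  data.frame(
    dose = doses,
    lower = apply(tgis, 1, stats::quantile, probs = alpha, na.rm = TRUE),
    median = apply(tgis, 1, stats::median, na.rm = TRUE),
    upper = apply(tgis, 1, stats::quantile, probs = 1 - alpha, na.rm = TRUE))
}
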