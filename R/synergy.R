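#' Median-effect fit (Chou analysis)
#'
#' Linear regression of `log(fa / fu)` on `log(dose)` per the median-effect
#' equation `fa/fu = (D/Dm)^m`: the slope is `m` and the median-effect dose
#' `Dm` (dose for 50% effect) follows from the intercept. Effects are
#' clipped to (0.001, 0.999) before the logit; clipping events are counted.
#'
#' @param doses Monotherapy doses (> 0; >= 3 usable points).
#' @param fa Fraction affected at each dose, in (0, 1) after clipping
#'   (for this pipeline: TGI / 100).
#' @return A `median_effect_fit`: list with `dm`, `m`, `r` (correlation of
#'   the median-effect plot), `n_clipped`, `n_points`.
#' @export
median_effect_fit <- function(doses, fa) {
  keep <- is.finite(doses) & is.finite(fa) & doses > 0
  doses <- doses[keep]; fa <- fa[keep]
  clipped <- fa <= 0.001 | fa >= 0.999
  fa <- pmin(pmax(fa, 0.001), 0.999)
  if (length(doses) < 3)
    stop("median_effect_fit: need >= 3 usable dose points", call. = FALSE)
  y <- log(fa / (1 - fa))
  x <- log(doses)
  fit <- stats::lm(y ~ x)
  m <- unname(stats::coef(fit)[2])
  if (!is.finite(m) || m <= 0)
    stop("median_effect_fit: non-positive median-effect slope; effects do ",
         "not increase with dose", call. = FALSE)
  dm <- exp(-unname(stats::coef(fit)[1]) / m)
  structure(list(dm = dm, m = m, r = stats::cor(x, y),
                 n_clipped = sum(clipped), n_points = length(doses)),
            class = "median_effect_fit")
}

#' Dose required for a given effect level
#'
#' `D_x = Dm * (fa / (1 - fa))^(1/m)` — the monotherapy dose producing
#' fraction affected `fa` under a median-effect fit.
#'
#' @param fit A [median_effect_fit()].
#' @param fa Effect level(s), strictly in (0, 1).
#' @return Dose(s) in the fit's dose units.
#' @export
required_dose <- function(fit, fa) {
  if (any(fa <= 0 | fa >= 1))
    stop("required_dose: fa must lie strictly in (0, 1)", call. = FALSE)
  fit$dm * (fa / (1 - fa))^(1 / fit$m)
}

#' Chou-Talalay combination index
#'
#' Non-constant-ratio form for two or three drugs:
#' `CI = sum_j D_j / D_x,j(fa)`, where `D_j` is the dose of drug j in the
#' combination and `D_x,j` the monotherapy dose of drug j alone producing
#' the combination's observed effect `fa`. CI < 1 indicates synergism,
#' CI ~ 1 additivity, CI > 1 antagonism.
#'
#' @param doses Named numeric vector of combination doses (2 or 3 drugs).
#' @param fa Observed fraction affected of the combination, in (0, 1).
#' @param fits Named list of [median_effect_fit()]s, one per drug in
#'   `doses`.
#' @return The combination index (positive scalar).
#' @export
combination_index <- function(doses, fa, fits) {
  if (length(fa) != 1 || fa <= 0 || fa >= 1)
    stop("combination_index: fa must be a scalar strictly in (0, 1)",
         call. = FALSE)
  if (!length(doses) %in% 2:3)
    stop("combination_index: 2 or 3 drugs expected", call. = FALSE)
  missing_fit <- setdiff(names(doses), names(fits))
  if (length(missing_fit))
    stop("combination_index: no median-effect fit for: ",
         paste(missing_fit, collapse = ", "), call. = FALSE)
  sum(vapply(names(doses), function(d)
    doses[[d]] / required_dose(fits[[d]], fa), numeric(1)))
}

#' Classify a combination index
#'
#' Thresholds: CI < 0.3 strong synergy; 0.3 <= CI < 0.9 synergy;
#' 0.9 <= CI <= 1.1 additive; CI > 1.1 antagonism. The classes partition
#' the positive axis with no gaps or overlaps.
#'
#' @param ci Combination index (> 0), vectorized.
#' @return Factor with levels `strong-synergy`, `synergy`, `additive`,
#'   `antagonism`.
#' @export
classify_ci <- function(ci) {
  if (any(ci <= 0)) stop("classify_ci: CI must be > 0", call. = FALSE)
  lv <- c("strong-synergy", "synergy", "additive", "antagonism")
  factor(ifelse(ci < 0.3, lv[1],
         ifelse(ci < 0.9, lv[2],
         ifelse(ci <= 1.1, lv[3], lv[4]))), levels = lv)
}

# Per-drug clinical dose caps (mg/kg): standard-of-care drugs at their
# clinically prescribed doses (70 kg / 1.9 m^2 assumptions), anti-miR-155
# at the 2.5 mg/kg tolerability-based ceiling.
.screen_dose_caps <- function() {
  c(anti_mir155_np = 2.5,
    cisplatin = clinical_dose_to_mgkg(75, "mg_m2"),
    atezolizumab = clinical_dose_to_mgkg(1200, "mg"),
    pembrolizumab = clinical_dose_to_mgkg(200, "mg"))
}

# Q3W regimen for one drug on the cohort timeline (treatment_start = 0);
# cisplatin is truncated at six cycles per clinical practice
.screen_regimen_events <- function(drug, dose) {
  n <- if (drug == "cisplatin") 6 else 9
  schedule_events(drug, dose, "Q3W", n)
}

#' Monotherapy median-effect fits for combination-index screening
#'
#' Regenerates, for each drug, a log-spaced monotherapy dose grid on the
#' same cohort (or the average patient when `cohort` is `NULL`), computes
#' end-of-treatment TGI-based fractions affected under the Q3W screening
#' regimen, and fits the median-effect line.
#'
#' @param drugs Drug ids.
#' @param cohort A [sample_cohort()] result, or `NULL` for the average
#'   patient (`params` then required).
#' @param params Human `model_parameters` (average patient), used when
#'   `cohort` is `NULL`.
#' @param n_doses Grid size per drug.
#' @param follow_up_end Days from treatment start.
#' @return Named list of [median_effect_fit()]s.
#' @export
monotherapy_fits <- function(drugs, cohort = NULL, params = NULL,
                             n_doses = 8, follow_up_end = 200) {
  caps <- .screen_dose_caps()
  stats::setNames(lapply(drugs, function(drug) {
    doses <- exp(seq(log(0.01), log(caps[[drug]]), length.out = n_doses))
    fa <- vapply(doses, function(d) {
      reg <- regimen(.screen_regimen_events(drug, d), 0, follow_up_end)
      tgi <- if (is.null(cohort)) {
        .screen_tgi_average(params, reg)
      } else cohort_tgi(cohort, reg, end_of_treatment(reg))
      pmin(pmax(tgi / 100, 0.001), 0.999)
    }, numeric(1))
    median_effect_fit(doses, fa)
  }), drugs)
}

# average-patient end-of-treatment TGI on the cohort timeline
.screen_tgi_average <- function(params, reg) {
  grid <- seq(0, reg$follow_up_end, by = 1)
  v0 <- volume_from_diameter(1.5)
  ctrl <- simulate_trajectory(params, regimen(list(), 0, reg$follow_up_end),
                              grid = grid, rtol = 1e-6, atol = 1e-9,
                              initial_volume_cm3 = v0)
  tr <- simulate_trajectory(params, reg, grid = grid, rtol = 1e-6,
                            atol = 1e-9, initial_volume_cm3 = v0)
  tumor_growth_inhibition(tr, ctrl, end_of_treatment(reg))
}

#' LHS screening of drug combinations for synergy
#'
#' Latin-hypercube sampling of non-constant-ratio dose combinations
#' (default 50 samples per combination, each drug between 0.01 mg/kg and
#' its clinical cap), simulation of each sampled combination under the Q3W
#' regimen (cisplatin truncated at six cycles), TGI-based fraction affected
#' at end of treatment, combination index against per-drug monotherapy
#' median-effect fits, synergy classification, and (when a cohort is
#' supplied) median PFS from Kaplan-Meier analysis of per-patient times to
#' progression.
#'
#' @param drugs Character vector of 2 or 3 drug ids.
#' @param cohort A [sample_cohort()] result, or `NULL` to screen on the
#'   average patient (no median PFS column in that case).
#' @param params Human `model_parameters` when `cohort` is `NULL`.
#' @param n_samples LHS samples (default 50).
#' @param dose_ranges Optional named list `drug -> c(min, max)` overriding
#'   the default 0.01-to-cap ranges.
#' @param fits Optional pre-computed [monotherapy_fits()].
#' @param follow_up_end Days from treatment start (default 200 for effect
#'   evaluation; extend for survival endpoints).
#' @param seed Integer seed for the LHS design.
#' @return data.frame with one row per sample: per-drug doses
#'   (`dose.<drug>`), `fa`, `ci`, `class`, per-drug dose fractions
#'   (`frac.<drug>`), `total_dose`, `median_pfs_months` (cohort mode), and
#'   `ok` (failures isolated per sample).
#' @export
screen_combinations <- function(drugs, cohort = NULL, params = NULL,
                                n_samples = 50, dose_ranges = NULL,
                                fits = NULL, follow_up_end = 200,
                                seed = 155) {
  if (!length(drugs) %in% 2:3)
    stop("screen_combinations: 2 or 3 drugs expected", call. = FALSE)
  if (is.null(cohort) && is.null(params))
    stop("screen_combinations: supply a cohort or average-patient params",
         call. = FALSE)
  caps <- .screen_dose_caps()
  ranges <- lapply(stats::setNames(nm = drugs), function(d)
    if (!is.null(dose_ranges[[d]])) dose_ranges[[d]] else
      c(0.01, caps[[d]]))
  for (d in drugs)
    if (ranges[[d]][1] < 0.01 - 1e-12 || ranges[[d]][2] > caps[[d]] + 1e-9)
      stop("screen_combinations: dose range for ", d,
           " outside [0.01, clinical cap]", call. = FALSE)
  if (is.null(fits))
    fits <- monotherapy_fits(drugs, cohort = cohort, params = params,
                             follow_up_end = follow_up_end)

  k <- length(drugs)
  design <- .with_seed(seed, lhs::randomLHS(n_samples, k))
  doses_mat <- sapply(seq_len(k), function(j) {
    r <- ranges[[drugs[j]]]
    exp(log(r[1]) + design[, j] * (log(r[2]) - log(r[1])))
  })
  doses_mat <- matrix(doses_mat, ncol = k)
  colnames(doses_mat) <- drugs

  rows <- lapply(seq_len(n_samples), function(i) {
    doses <- doses_mat[i, ]
    row <- as.list(stats::setNames(doses, paste0("dose.", drugs)))
    res <- try({
      ev <- do.call(c, lapply(drugs, function(d)
        .screen_regimen_events(d, doses[[d]])))
      reg <- regimen(ev, 0, follow_up_end)
      tgi <- if (is.null(cohort)) .screen_tgi_average(params, reg)
             else cohort_tgi(cohort, reg, end_of_treatment(reg))
      fa <- pmin(pmax(tgi / 100, 0.001), 0.999)
      ci <- combination_index(doses, fa, fits)
      med <- NA_real_
      if (!is.null(cohort)) {
        tt <- cohort_ttp(cohort, reg)
        med <- median_pfs(kaplan_meier(tt$ttp_months, tt$event))
      }
      list(fa = fa, ci = ci, med = med)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      row <- c(row, fa = NA_real_, ci = NA_real_,
               class = NA_character_, median_pfs_months = NA_real_,
               ok = FALSE)
    } else {
      row <- c(row, fa = res$fa, ci = res$ci,
               class = as.character(classify_ci(res$ci)),
               median_pfs_months = res$med, ok = TRUE)
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  tot <- rowSums(out[, paste0("dose.", drugs), drop = FALSE])
  for (d in drugs) out[[paste0("frac.", d)]] <- out[[paste0("dose.", d)]] / tot
  out$total_dose <- tot
  attr(out, "fits") <- fits
  out
}

#' Mine threshold conditions for a synergy class
#'
#' Descriptive decision-stump search over the screening table: finds the
#' conjunction of up to `max_terms` simple threshold predicates (on doses,
#' dose fractions and total dose) that maximizes precision for the target
#' class while keeping at least `min_recall` of its members. Greedy and
#' descriptive, not inferential.
#'
#' @param screen A [screen_combinations()] result.
#' @param target `"strong-synergy"` or `"antagonism"`.
#' @param max_terms Maximum number of conjunctive terms.
#' @param min_recall Minimum fraction of target rows the rule must retain.
#' @return List with `terms` (data.frame: `variable`, `direction`,
#'   `threshold`), `precision`, `recall`, `n_target`; `NULL` if the class
#'   is absent.
#' @export
synergy_conditions <- function(screen, target = "strong-synergy",
                               max_terms = 3, min_recall = 0.7) {
  ok <- screen[screen$ok & !is.na(screen$class), , drop = FALSE]
  y <- ok$class == target
  if (!any(y)) return(NULL)
  vars <- grep("^(dose|frac)\\.|^total_dose$", names(ok), value = TRUE)
  sel <- rep(TRUE, nrow(ok))
  terms <- data.frame(variable = character(), direction = character(),
                      threshold = numeric())
  for (step in seq_len(max_terms)) {
    best <- NULL
    for (v in vars) {
      for (thr in unique(stats::quantile(ok[[v]], probs = seq(0.05, 0.95,
                                                              by = 0.05)))) {
        for (dir in c(">", "<")) {
          cand <- sel & (if (dir == ">") ok[[v]] > thr else ok[[v]] < thr)
          rec <- sum(cand & y) / sum(y)
          if (rec < min_recall || !any(cand)) next
          prec <- sum(cand & y) / sum(cand)
          if (is.null(best) || prec > best$prec) {
            best <- list(v = v, dir = dir, thr = thr, prec = prec,
                         sel = cand)
          }
        }
      }
    }
    if (is.null(best)) break
    prev_prec <- sum(sel & y) / sum(sel)
    if (best$prec <= prev_prec + 1e-9) break
    sel <- best$sel
    terms <- rbind(terms, data.frame(variable = best$v,
                                     direction = best$dir,
                                     threshold = best$thr))
  }
  list(terms = terms,
       precision = sum(sel & y) / sum(sel),
       recall = sum(sel & y) / sum(y),
       n_target = sum(y))
}

#' @export
print.median_effect_fit <- function(x, ...) {
  cat(sprintf("<median_effect_fit> Dm = %.4g, m = %.3f, r = %.3f (%d points, %d clipped)\n",
              x$dm, x$m, x$r, x$n_points, x$n_clipped))
  invisible(x)
}
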