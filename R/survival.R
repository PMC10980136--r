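#' Kaplan-Meier progression-free survival curve
#'
#' Product-limit estimator of the PFS function from per-patient times to
#' progression with censoring flags (censored = no progression before the
#' end of follow-up). Ties are handled by the simultaneous-event convention
#' of the product-limit estimator.
#'
#' @param ttp_months Nonnegative event/censoring times in months.
#' @param event Logical (or 0/1): `TRUE` if progression was observed,
#'   `FALSE` if censored.
#' @return A `survival_curve`: data.frame with `time`, `surv`, `n_risk`,
#'   `n_event`, `n_censor`, carrying the [survival::survfit()] object as an
#'   attribute. `S(0) = 1` by construction.
#' @export
kaplan_meier <- function(ttp_months, event) {
  if (!length(ttp_months))
    stop("kaplan_meier: empty input", call. = FALSE)
  if (any(ttp_months < 0))
    stop("kaplan_meier: times must be nonnegative", call. = FALSE)
  if (length(event) != length(ttp_months))
    stop("kaplan_meier: 'event' and 'ttp_months' lengths differ",
         call. = FALSE)
  sf <- survival::survfit(survival::Surv(ttp_months, as.integer(event)) ~ 1)
  out <- data.frame(time = sf$time, surv = sf$surv, n_risk = sf$n.risk,
                    n_event = sf$n.event, n_censor = sf$n.censor)
  attr(out, "survfit") <- sf
  class(out) <- c("survival_curve", "data.frame")
  out
}

#' Median progression-free survival from a KM curve
#'
#' The smallest time at which the survival probability drops to 0.5 or
#' below; `NA` (not reached) if the curve stays above 0.5 throughout.
#'
#' @param curve A [kaplan_meier()] result.
#' @return Median PFS in months, or `NA_real_` if not reached.
#' @export
median_pfs <- function(curve) {
  hit <- which(curve$surv <= 0.5 + 1e-12)
  if (!length(hit)) return(NA_real_)
  curve$time[hit[1]]
}

#' Hazard ratio for disease progression (Cox model)
#'
#' Fits a Cox proportional-hazards model with a single binary covariate
#' (treatment vs control) and reports the hazard ratio with a Wald
#' confidence interval. Complete or near-complete separation of the two
#' groups (all treatment progressions after all control progressions)
#' produces a numerically degenerate, vanishing estimate; this is detected
#' and flagged rather than reported as a bare point estimate.
#'
#' @param ttp_treatment,event_treatment Times (months) and progression flags
#'   for the treatment group.
#' @param ttp_control,event_control Same for the control group.
#' @param conf_level Confidence level of the Wald interval.
#' @return List: `hr`, `ci_lower`, `ci_upper`, `p_value`, `degenerate`
#'   (logical; `TRUE` when the fit is separation-dominated and the point
#'   estimate should not be trusted).
#' @export
hazard_ratio <- function(ttp_treatment, event_treatment,
                         ttp_control, event_control,
                         conf_level = 0.95) {
  if (!length(ttp_treatment) || !length(ttp_control))
    stop("hazard_ratio: both groups must be non-empty", call. = FALSE)
  if (!any(event_treatment) && !any(event_control))
    stop("hazard_ratio: no progression events in either group",
         call. = FALSE)
  tt <- c(ttp_treatment, ttp_control)
  ev <- as.integer(c(event_treatment, event_control))
  gr <- c(rep(1L, length(ttp_treatment)), rep(0L, length(ttp_control)))
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(tt, ev) ~ gr,
                    control = survival::coxph.control(iter.max = 50)))
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  # separation: the partial likelihood is monotone in beta, the estimate
  # runs away and the Wald SE explodes
  degenerate <- !is.finite(beta) || abs(beta) > 15 || !is.finite(se) ||
    se > 10
  list(hr = exp(beta),
       ci_lower = exp(beta - z * se),
       ci_upper = exp(beta + z * se),
       p_value = summary(fit)$coefficients[1, "Pr(>|z|)"],
       degenerate = degenerate)
}

#' Hill characterization of median PFS versus dose
#'
#' Fits the zero-baseline Hill form to median PFS across a dose ladder
#' (not-reached medians are excluded with a warning) and reports the
#' maximal median PFS `emax` with a Wald confidence interval.
#'
#' @param doses Dose vector, mg/kg.
#' @param median_pfs_months Median PFS per dose (months; `NA` = not
#'   reached).
#' @param conf_level Confidence level for the `emax` interval.
#' @return List: `fit` (a [fit_hill()] `hill_fit`), `emax`, `emax_ci`
#'   (length-2 vector).
#' @export
pfs_dose_hill <- function(doses, median_pfs_months, conf_level = 0.95) {
  keep <- is.finite(median_pfs_months)
  if (any(!keep))
    warning("pfs_dose_hill: excluding ", sum(!keep),
            " not-reached median(s)")
  if (sum(keep) < 4)
    stop("pfs_dose_hill: need >= 4 dose points with reached medians",
         call. = FALSE)
  fit <- fit_hill(doses[keep], median_pfs_months[keep], form = "eq1")
  emax <- fit$coefficients[["emax"]]
  se <- sqrt(fit$vcov[1, 1])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(fit = fit, emax = emax,
       emax_ci = c(emax - z * se, emax + z * se))
}

#' @export
print.survival_curve <- function(x, ...) {
  med <- median_pfs(x)
  cat(sprintf("<survival_curve> %d subjects, %d events; median PFS %s\n",
              x$n_risk[1], sum(x$n_event),
              if (is.na(med)) "not reached" else sprintf("%.2f months", med)))
  invisible(x)
}
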