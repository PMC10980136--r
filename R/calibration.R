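#' A tumor-growth dataset for calibration
#'
#' One treatment arm's volumetric growth observations together with the
#' regimen that generated them.
#'
#' @param arm Arm label.
#' @param reg The [regimen()] under which the observations were collected.
#' @param observations data.frame with columns `time_day` (days from
#'   inception), `volume_mm3` (> 0), and `replicate`.
#' @return A `growth_dataset`.
#' @export
growth_dataset <- function(arm, reg, observations) {
  req <- c("time_day", "volume_mm3", "replicate")
  if (!all(req %in% names(observations)))
    stop("growth_dataset: observations need columns ",
         paste(req, collapse = ", "), call. = FALSE)
  if (any(observations$volume_mm3 <= 0))
    stop("growth_dataset: volumes must be > 0", call. = FALSE)
  t_end <- reg$treatment_start + reg$follow_up_end
  if (any(observations$time_day < 0 | observations$time_day > t_end + 1e-9))
    stop("growth_dataset: observation times outside the experiment span",
         call. = FALSE)
  structure(list(arm = arm, regimen = reg, observations = observations),
            class = "growth_dataset")
}

#' Goodness of fit: Pearson correlation of predicted vs observed
#'
#' @param predicted,observed Equal-length paired numeric vectors (n >= 3).
#' @return List with `pearson_r` and `pearson_p` (two-sided).
#' @export
goodness_of_fit <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(predicted) < 3)
    stop("goodness_of_fit: need equal-length vectors with n >= 3",
         call. = FALSE)
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0)
    stop("goodness_of_fit: correlation undefined for a constant vector",
         call. = FALSE)
  ct <- stats::cor.test(predicted, observed)
  list(pearson_r = unname(ct$estimate), pearson_p = ct$p.value)
}

# residual vector across all arms for a candidate free-parameter vector
.calib_residuals <- function(theta, free_names, params0, datasets,
                             log_scale, rtol, atol) {
  fl <- params_flatten(params0)
  fl[free_names] <- theta
  p <- try(params_unflatten(fl, params0), silent = TRUE)
  if (inherits(p, "try-error")) return(rep(1e6, sum(vapply(
    datasets, function(d) nrow(d$observations), integer(1)))))
  unlist(lapply(datasets, function(d) {
    tr <- try(simulate_trajectory(p, d$regimen, grid = sort(unique(
      c(0, d$observations$time_day))), rtol = rtol, atol = atol),
      silent = TRUE)
    if (inherits(tr, "try-error"))
      return(rep(1e6, nrow(d$observations)))
    pred <- trajectory_at(tr, "volume", d$observations$time_day) * 1000
    if (log_scale) log(pmax(pred, 1e-6)) - log(d$observations$volume_mm3)
    else (pred - d$observations$volume_mm3) / mean(d$observations$volume_mm3)
  }))
}

#' Pooled nonlinear least-squares calibration
#'
#' Estimates a set of free model parameters by minimizing the summed squared
#' residuals across all supplied arms simultaneously (a pooled objective:
#' one parameter vector must explain every arm). Residuals are computed on
#' volume in natural scale, normalized per arm by the arm's mean observed
#' volume so that large-tumor arms do not dominate; log-scale residuals are
#' available via `log_scale = TRUE`. Optimization uses bounded
#' Levenberg-Marquardt least squares ([minpack.lm::nls.lm()]), optionally
#' with multiple log-uniform restarts (fixed seed, best fit kept).
#'
#' @param params0 Starting `model_parameters`.
#' @param free Named list: flattened parameter name -> `c(lower, upper)`
#'   bounds (finite, positive).
#' @param datasets List of [growth_dataset()]s.
#' @param log_scale Use log-volume residuals.
#' @param n_starts Number of optimizer starts (1 = start at `params0`
#'   values; additional starts are drawn log-uniformly within bounds).
#' @param seed Seed for the multi-start draws.
#' @param rtol,atol Integrator tolerances used during fitting.
#' @return A `calibration_result`: list with `estimate` (named vector),
#'   `at_bounds` (logical), `residuals`, `pearson_r`, `pearson_p`,
#'   `objective`, `converged`, `fitted` (data.frame of predicted vs observed)
#'   and `params` (the fitted `model_parameters`).
#' @export
fit_parameters <- function(params0, free, datasets, log_scale = FALSE,
                           n_starts = 1, seed = 20240314,
                           rtol = 1e-6, atol = 1e-9) {
  if (!length(free))
    stop("fit_parameters: 'free' must name at least one parameter",
         call. = FALSE)
  if (!length(datasets))
    stop("fit_parameters: no datasets supplied", call. = FALSE)
  if (!all(vapply(datasets, inherits, logical(1), "growth_dataset")))
    stop("fit_parameters: 'datasets' must be growth_dataset objects",
         call. = FALSE)
  free_names <- names(free)
  fl0 <- params_flatten(params0)
  bad <- setdiff(free_names, names(fl0))
  if (length(bad))
    stop("fit_parameters: unknown free parameter(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  lower <- vapply(free, `[[`, numeric(1), 1)
  upper <- vapply(free, `[[`, numeric(1), 2)
  if (any(!is.finite(lower)) || any(!is.finite(upper)) ||
      any(lower <= 0) || any(lower >= upper))
    stop("fit_parameters: bounds must be finite, positive, lower < upper",
         call. = FALSE)

  starts <- list(pmin(pmax(fl0[free_names], lower), upper))
  if (n_starts > 1) {
    rng <- .with_seed(seed, matrix(stats::runif((n_starts - 1) *
      length(free_names)), ncol = length(free_names)))
    for (i in seq_len(n_starts - 1))
      starts[[i + 1]] <- exp(log(lower) + rng[i, ] * (log(upper) - log(lower)))
  }

  best <- NULL
  for (st in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = st, lower = lower, upper = upper,
      fn = .calib_residuals, free_names = free_names, params0 = params0,
      datasets = datasets, log_scale = log_scale, rtol = rtol, atol = atol,
      control = minpack.lm::nls.lm.control(maxiter = 100)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("fit_parameters: optimization failed from every start point",
         call. = FALSE)

  est <- stats::setNames(as.numeric(best$par), free_names)
  flf <- fl0; flf[free_names] <- est
  pfit <- params_unflatten(flf, params0)
  fitted <- do.call(rbind, lapply(datasets, function(d) {
    tr <- simulate_trajectory(pfit, d$regimen, grid = sort(unique(
      c(0, d$observations$time_day))), rtol = rtol, atol = atol)
    data.frame(arm = d$arm, time_day = d$observations$time_day,
               observed_mm3 = d$observations$volume_mm3,
               predicted_mm3 = trajectory_at(
                 tr, "volume", d$observations$time_day) * 1000)
  }))
  gof <- goodness_of_fit(fitted$predicted_mm3, fitted$observed_mm3)
  structure(list(
    estimate = est,
    at_bounds = est <= lower * (1 + 1e-8) | est >= upper * (1 - 1e-8),
    residuals = best$fvec,
    objective = best$deviance,
    trace = best$rsstrace,
    converged = best$info %in% 1:4,
    pearson_r = gof$pearson_r,
    pearson_p = gof$pearson_p,
    fitted = fitted,
    params = pfit), class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result> objective", signif(x$objective, 4),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  for (nm in names(x$estimate))
    cat(sprintf("  %s = %.5g%s\n", nm, x$estimate[[nm]],
                if (x$at_bounds[[nm]]) " [at bound]" else ""))
  cat(sprintf("  Pearson r = %.4f (p = %.3g)\n", x$pearson_r, x$pearson_p))
  invisible(x)
}

# evaluate `expr` under a temporary RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
    globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
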