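# Shared fixtures, computed lazily and cached for the whole test run.
.fx <- new.env(parent = emptyenv())

fx_mouse <- function() default_mouse_parameters()
fx_human <- function() {
  if (is.null(.fx$human)) .fx$human <- default_human_parameters()
  .fx$human
}

# the six preclinical arms simulated at reporting tolerance
fx_preclinical_sims <- function() {
  if (is.null(.fx$sims)) {
    regs <- preclinical_regimens()
    p <- fx_mouse()
    .fx$sims <- lapply(regs, function(r) simulate_trajectory(p, r))
  }
  .fx$sims
}

fx_preclinical_tgi <- function() {
  if (is.null(.fx$tgi)) {
    sims <- fx_preclinical_sims()
    .fx$tgi <- vapply(
      setdiff(names(sims), "control"),
      function(a) tumor_growth_inhibition(sims[[a]], sims$control, 28),
      numeric(1))
  }
  .fx$tgi
}

# a small shared virtual cohort for module-level tests
fx_small_cohort <- function() {
  if (is.null(.fx$cohort))
    .fx$cohort <- sample_cohort(fx_human(), n = 25, seed = 155)
  .fx$cohort
}

# hand-built single-lesion trajectory from a diameter series (for RECIST
# tests): daily grid, treatment starts at day 0
make_diam_trajectory <- function(time_day, diameter_cm,
                                 follow_up_end = max(time_day)) {
  reg <- regimen(list(), treatment_start = 0,
                 follow_up_end = follow_up_end)
  out <- data.frame(time = time_day,
                    volume = volume_from_diameter(diameter_cm))
  attr(out, "regimen") <- reg
  class(out) <- c("trajectory", "data.frame")
  out
}
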