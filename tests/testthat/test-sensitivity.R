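test_that("regression SI recover a known linear response", {
  p <- fx_human()
  pars <- c("growth.rate_per_day", "mirna.potency_pm",
            "np.pore_diameter_nm")
  # synthetic response: strong, weak and null effects plus noise
  fn <- function(params, mult) {
    3 * mult[[1]] + 1 * mult[[2]] + 0 * mult[[3]] + rnorm(1, 0, 0.05)
  }
  rep <- global_sensitivity(p, names = pars, n_samples = 60,
                            n_replicates = 4, seed = 7, response_fn = fn)
  si <- tapply(abs(rep$si$si), rep$si$parameter, mean)
  expect_gt(si[["growth.rate_per_day"]], si[["mirna.potency_pm"]])
  expect_gt(si[["mirna.potency_pm"]], si[["np.pore_diameter_nm"]])
  # the null parameter is statistically indistinguishable from zero
  null_si <- rep$si$si[rep$si$parameter == "np.pore_diameter_nm"]
  expect_lt(abs(mean(null_si)), 2 * sd(null_si) / sqrt(length(null_si)) + 0.1)
  # ranking partitions the parameter set
  expect_setequal(rep$ranking$parameter, pars)
  expect_true(all(nchar(rep$ranking$group) > 0))
})

test_that("a fixed seed reproduces the report bit for bit", {
  p <- fx_human()
  pars <- c("growth.rate_per_day", "mirna.potency_pm")
  fn <- function(params, mult) 2 * mult[[1]] - mult[[2]] + rnorm(1, 0, 0.1)
  r1 <- global_sensitivity(p, names = pars, n_samples = 25,
                           n_replicates = 2, seed = 11, response_fn = fn)
  r2 <- global_sensitivity(p, names = pars, n_samples = 25,
                           n_replicates = 2, seed = 11, response_fn = fn)
  expect_identical(r1$si, r2$si)
})

test_that("preconditions on the design size are enforced", {
  p <- fx_human()
  expect_error(global_sensitivity(p, names = c("growth.rate_per_day",
                                               "mirna.potency_pm"),
                                  n_samples = 10),
               "10x")
  expect_error(local_sensitivity(p, "no.such"), "unknown")
})

test_that("a parameter outside the model is a flat LSA curve", {
  p <- fx_human()
  # body surface area only enters dose-unit conversions, never the dynamics
  sweep <- local_sensitivity(p, "species.body_surface_area_m2",
                             n_points = 3)
  expect_true(all(sweep$ok))
  expect_lt(diff(range(sweep$tgi)), 1e-9)
})

test_that("the unperturbed LSA point reproduces the baseline response", {
  p <- fx_human()
  sweep <- local_sensitivity(p, "mirna.antagonist_ec50_mg_ml",
                             n_points = 3, span = 0.5)
  expect_equal(sweep$multiplier[2], 1)
  base <- sweep$tgi[2]
  sweep2 <- local_sensitivity(p, "growth.rate_per_day", n_points = 3,
                              span = 0.25)
  expect_equal(sweep2$tgi[2], base, tolerance = 1e-9)
})

test_that("LSA directions match the biology for key parameters", {
  p <- fx_human()
  # anti-miR-155 potency: larger EC50 (weaker antagonist) worsens response
  ec <- local_sensitivity(p, "mirna.antagonist_ec50_mg_ml", n_points = 5)
  expect_true(all(diff(ec$tgi) < 0))
  # faster anti-miR-155 degradation worsens response
  dam <- local_sensitivity(p, "mirna.antagonist_degradation_per_day",
                           n_points = 3)
  expect_lt(dam$tgi[3], dam$tgi[1])
  # fast-growing tumors respond worse over most of the range (the sweep is
  # kept inside the span where the perturbed control still grows; beyond
  # that TGI is undefined and the point is flagged)
  g <- local_sensitivity(p, "growth.rate_per_day", n_points = 5,
                         span = 0.25)
  expect_lt(g$tgi[5], g$tgi[3])
  expect_lt(g$tgi[4], g$tgi[2])
})

test_that("the full-model GSA puts proliferation parameters on top", {
  p <- fx_human()
  pars <- c("growth.rate_per_day", "mirna.proliferation_gain",
            "mirna.antagonist_ec50_mg_ml", "chemo.kill_max_per_day",
            "checkpoint.pd1_equilibrium_pm")
  rep <- global_sensitivity(p, names = pars, n_samples = 60,
                            n_replicates = 3, seed = 155)
  top2 <- rep$ranking$parameter[1:2]
  expect_true(all(c("growth.rate_per_day", "mirna.proliferation_gain")
                  %in% top2))
  # cisplatin kill has no causal path under anti-miR monotherapy
  null_si <- rep$si$si[rep$si$parameter == "chemo.kill_max_per_day"]
  expect_lt(abs(mean(null_si)),
            2 * sd(null_si) / sqrt(length(null_si)) + 0.02)
})
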