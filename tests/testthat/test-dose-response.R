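test_that("noiseless Hill data are recovered exactly", {
  truth <- c(emax = 66.7, ec50 = 0.033, n = 0.74)
  doses <- default_dose_grid(12)
  eff <- truth[["emax"]] / (1 + (truth[["ec50"]] / doses)^truth[["n"]])
  fit <- fit_hill(doses, eff, "eq1")
  expect_equal(fit$coefficients[["emax"]], truth[["emax"]], tolerance = 1e-5)
  expect_equal(fit$coefficients[["ec50"]], truth[["ec50"]], tolerance = 1e-5)
  expect_equal(fit$coefficients[["n"]], truth[["n"]], tolerance = 1e-5)
  # defining property: the effect at EC50 is half the maximum
  expect_equal(predict_hill(fit, fit$coefficients[["ec50"]]),
               fit$coefficients[["emax"]] / 2, tolerance = 1e-9)
})

test_that("5%-noise Hill fits stay within 10% of the truth", {
  truth <- c(emax = 66.7, ec50 = 0.033, n = 0.74)
  doses <- default_dose_grid(20)
  clean <- truth[["emax"]] / (1 + (truth[["ec50"]] / doses)^truth[["n"]])
  set.seed(31)
  rel <- as.numeric(replicate(5, {
    eff <- clean * exp(rnorm(length(doses), 0, 0.05))
    fit <- fit_hill(doses, eff, "eq1")
    abs(unlist(fit$coefficients)[names(truth)] - truth) / truth
  }))
  expect_lt(median(rel), 0.10)
})

test_that("the falling diameter-change endpoint fits the offset Hill form", {
  # decreasing response: Emin (zero-dose effect) above Emax (high-dose)
  truth <- c(emin = 268.9, emax = 21.5, ec50 = 0.05, n = 0.9)
  doses <- default_dose_grid(15)
  eff <- truth[["emin"]] + (truth[["emax"]] - truth[["emin"]]) /
    (1 + (truth[["ec50"]] / doses)^truth[["n"]])
  fit <- fit_hill(doses, eff, "eq2")
  expect_equal(fit$coefficients[["emin"]], truth[["emin"]], tolerance = 1e-4)
  expect_equal(fit$coefficients[["emax"]], truth[["emax"]], tolerance = 1e-4)
  expect_gt(fit$coefficients[["emin"]], fit$coefficients[["emax"]])
})

test_that("EC_p inversion has the closed form and round-trips", {
  truth <- c(emax = 50, ec50 = 0.4, n = 1)
  doses <- default_dose_grid(10, c(1e-3, 100))
  eff <- truth[["emax"]] / (1 + (truth[["ec50"]] / doses)^truth[["n"]])
  fit <- fit_hill(doses, eff, "eq1")
  expect_equal(ec_p(fit, 50), fit$coefficients[["ec50"]], tolerance = 1e-6)
  expect_equal(ec_p(fit, 99), 99 * fit$coefficients[["ec50"]],
               tolerance = 1e-4)
  expect_error(ec_p(fit, 100), "strictly between")
  for (p in c(10, 50, 85, 99))
    expect_equal(predict_hill(fit, ec_p(fit, p)),
                 p / 100 * fit$coefficients[["emax"]], tolerance = 1e-9)
})

test_that("dose grids vanish at zero dose and reward frequent dosing", {
  ph <- fx_human()
  tiny <- run_dose_grid(ph, 1e-6, "Q3W")
  expect_lt(abs(tiny$tgi), 1)
  d <- 0.026
  q3w <- run_dose_grid(ph, d, "Q3W")
  qw <- run_dose_grid(ph, d, "QW")
  expect_gte(qw$tgi, q3w$tgi)
})

test_that("prediction intervals collapse at zero spread and reproduce", {
  ph <- fx_human()
  doses <- c(0.01, 0.3)
  pi0 <- prediction_interval(ph, doses, n_sets = 100, span = 0,
                             seed = 5)
  expect_equal(pi0$lower, pi0$upper, tolerance = 1e-9)
  expect_error(prediction_interval(ph, doses, n_sets = 50), ">= 100")
  pi1 <- prediction_interval(ph, doses, n_sets = 100, span = 0.1, seed = 9)
  pi2 <- prediction_interval(ph, doses, n_sets = 100, span = 0.1, seed = 9)
  expect_identical(pi1, pi2)
  expect_true(all(pi1$upper >= pi1$lower))
})

test_that("interval coverage matches its nominal level on a fresh ensemble", {
  ph <- fx_human()
  doses <- c(0.05)
  band <- prediction_interval(ph, doses, n_sets = 150, span = 0.1,
                              seed = 21)
  # fresh draws from the same generating distribution
  sens <- default_sensitive_parameters()
  set.seed(77)
  fresh <- 0.9 + 0.2 * lhs::randomLHS(150, length(sens))
  tgis <- apply(fresh, 1, function(m) {
    run_dose_grid(perturb_parameters(ph, setNames(m, sens)), doses,
                  "Q3W")$tgi
  })
  cover <- mean(tgis >= band$lower & tgis <= band$upper)
  expect_gt(cover, 0.82)
  expect_lt(cover, 0.98)
})
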