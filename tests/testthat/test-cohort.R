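test_that("zero-variance sampling reproduces the average patient", {
  ph <- fx_human()
  co <- sample_cohort(ph, n = 3, sigma = 1e-12, seed = 1)
  expect_equal(co$patients$baseline_volume_cm3,
               rep(co$patients$baseline_volume_cm3[1], 3), tolerance = 1e-9)
  mults <- as.matrix(co$patients[, grep("^mult\\.",
                                        names(co$patients))])
  expect_equal(as.numeric(mults), rep(1, length(mults)), tolerance = 1e-6)
  # the average patient presents at ~1.5 cm, inside the acceptance window
  expect_gt(co$patients$baseline_diameter_cm[1], 1)
  expect_lt(co$patients$baseline_diameter_cm[1], 2.68)
})

test_that("cohort generation is seed-deterministic", {
  ph <- fx_human()
  c1 <- sample_cohort(ph, n = 10, seed = 42)
  c2 <- sample_cohort(ph, n = 10, seed = 42)
  expect_identical(c1$patients, c2$patients)
  expect_identical(c1$proposals, c2$proposals)
  c3 <- sample_cohort(ph, n = 10, seed = 43)
  expect_false(identical(c1$patients, c3$patients))
})

test_that("accepted baselines respect the stage IA window", {
  co <- fx_small_cohort()
  d <- co$patients$baseline_diameter_cm
  expect_true(all(d >= 1 & d <= 2.68))
  expect_true(all(!duplicated(co$patients$patient_id)))
})

test_that("an impossible window fails with actionable advice", {
  ph <- fx_human()
  expect_error(
    sample_cohort(ph, n = 5, seed = 1, volume_range = c(1e9, 2e9),
                  max_proposals = 200),
    "acceptance rate")
})

test_that("patient parameter reconstruction applies the stored multipliers", {
  co <- fx_small_cohort()
  p1 <- patient_parameters(co, 1)
  mult <- co$patients[["mult.growth.rate_per_day"]][1]
  expect_equal(p1$growth$rate_per_day,
               co$base_params$growth$rate_per_day * mult, tolerance = 1e-12)
  p_by_id <- patient_parameters(co, co$patients$patient_id[1])
  expect_equal(params_flatten(p_by_id), params_flatten(p1))
})

test_that("noise-free synthetic data equal the model mean exactly", {
  p <- fx_mouse()
  ds <- synth_preclinical_dataset(
    p, arms = preclinical_regimens(c("control", "cisplatin")),
    noise_sigma = 0, replicates = 1)
  tr <- simulate_trajectory(p, preclinical_regimens("cisplatin")$cisplatin)
  obs <- ds$cisplatin$observations
  pred <- trajectory_at(tr, "volume", obs$time_day) * 1000
  expect_equal(obs$volume_mm3, pred, tolerance = 1e-6)
})

test_that("the default synthetic design has five treatments and two controls", {
  p <- fx_mouse()
  ds <- synth_preclinical_dataset(p, noise_sigma = 0, replicates = 1)
  expect_length(ds, 7)
  ctrl_arms <- names(ds)[vapply(ds, function(d)
    length(d$regimen$events) == 0, logical(1))]
  expect_length(ctrl_arms, 2)
})

test_that("synthetic noise is seeded and lognormal-multiplicative", {
  p <- fx_mouse()
  arms <- preclinical_regimens("control")
  d1 <- synth_preclinical_dataset(p, arms = arms, noise_sigma = 0.05,
                                  replicates = 3, seed = 9)
  d2 <- synth_preclinical_dataset(p, arms = arms, noise_sigma = 0.05,
                                  replicates = 3, seed = 9)
  expect_identical(d1$control$observations, d2$control$observations)
  d0 <- synth_preclinical_dataset(p, arms = arms, noise_sigma = 0,
                                  replicates = 3, seed = 9)
  ratio <- d1$control$observations$volume_mm3 /
    d0$control$observations$volume_mm3
  expect_true(all(ratio > 0.75 & ratio < 1.3))  # ~5% lognormal
})

test_that("seeded noisy data still let calibration recover the growth rate", {
  truth <- fx_mouse()
  ds <- synth_preclinical_dataset(
    truth, arms = preclinical_regimens(c("control", "anti_mir155")),
    noise_sigma = 0.05, replicates = 4, seed = 5)
  fl <- params_flatten(truth)
  free <- list(growth.rate_per_day = fl[["growth.rate_per_day"]] * c(0.3, 3))
  start <- perturb_parameters(truth, c(growth.rate_per_day = 1.4))
  fit <- fit_parameters(start, free, ds)
  expect_lt(abs(fit$estimate[[1]] - fl[["growth.rate_per_day"]]) /
              fl[["growth.rate_per_day"]], 0.10)
})
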