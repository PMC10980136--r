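test_that("the RHS respects its structural limits", {
  p <- fx_mouse()
  rhs <- build_rhs(p)
  y0 <- initial_state(p)

  # logistic brake: zero-drug tumor at carrying capacity cannot grow
  y <- y0; y[["volume"]] <- p$growth$carrying_capacity_cm3
  dv <- rhs(0, y)[[1]][16]
  expect_lte(dv, 0)

  # miR-155 equilibrium is a fixed point of the molecular subsystem
  d <- rhs(0, y0)[[1]]
  expect_equal(d[5], 0, tolerance = 1e-12)  # cancer-cell miR-155
  expect_equal(d[6], 0, tolerance = 1e-12)  # TAM miR-155

  # saturating anti-miR-155: degradation multiplier approaches 1 + A_AM
  am <- p$mirna$antagonist_ec50_mg_ml * 1e6
  y <- y0; y[["am_tam"]] <- am
  mir_eq <- p$mirna$production_rate_pm_day / p$mirna$degradation_rate_per_day
  d <- rhs(0, y)[[1]]
  mult <- (p$mirna$production_rate_pm_day - d[6]) /
    (p$mirna$degradation_rate_per_day * mir_eq)
  expect_equal(mult, 1 + p$mirna$antagonist_gain, tolerance = 1e-4)
})

test_that("invalid parameters are rejected before building the system", {
  p <- fx_mouse()
  p$growth$rate_per_day <- 0
  expect_error(build_rhs(p), "growth.rate_per_day")
})

test_that("drug mass is conserved when elimination and uptake are off", {
  p <- fx_mouse()
  p$np$degradation_rate_per_day <- 0
  p$np$clearance_rate_per_day <- 0
  p$np$diffusivity_ref_cm2_day <- 1e-30  # no cellular uptake
  p$chemo$clearance_per_day <- 0
  p$chemo$tumor_elimination_per_day <- 0
  reg <- combine_regimen(
    schedule_events("anti_mir155_np", 0.2, "BIW", 4),
    schedule_events("cisplatin", 8, "QW", 2),
    treatment_start = 7, follow_up_end = 21)
  tr <- simulate_trajectory(p, reg)
  bw <- p$species$body_weight_kg
  after <- tr$time > 7 + 10.5 + 1e-6  # after the last anti-miR dose
  expect_equal(tr$np_plasma[after] + tr$np_tumor[after],
               rep(4 * 0.2 * bw, sum(after)), tolerance = 1e-6)
  after_cis <- tr$time > 14 + 1e-6
  expect_equal(tr$cis_plasma[after_cis] + tr$cis_tumor[after_cis],
               rep(2 * 8 * bw, sum(after_cis)), tolerance = 1e-6)
})

test_that("control simulation grows monotonically from inoculation", {
  ctrl <- fx_preclinical_sims()$control
  expect_true(all(diff(ctrl$volume) > 0))
})

test_that("all state series stay nonnegative under every preclinical arm", {
  for (tr in fx_preclinical_sims())
    expect_gte(min(as.matrix(tr[, -1])), -1e-9)
})

test_that("pre-treatment molecular equilibria match their anchors", {
  ctrl <- fx_preclinical_sims()$control
  expect_equal(ctrl$mir_cancer, rep(1.5, nrow(ctrl)), tolerance = 1e-6)
  expect_equal(ctrl$mir_tam, rep(1.5, nrow(ctrl)), tolerance = 1e-6)
  expect_equal(ctrl$pd1, rep(1, nrow(ctrl)), tolerance = 1e-6)
})

test_that("sustained anti-miR-155 suppresses miR-155 and de-represses PD-L1", {
  am <- fx_preclinical_sims()$anti_mir155
  ctrl <- fx_preclinical_sims()$control
  on_trt <- am$time > 20 & am$time < 32
  expect_lt(max(am$mir_cancer[on_trt]), 0.05)
  expect_lt(max(am$mir_tam[on_trt]), 0.05)
  ratio <- max(am$pdl1_cancer) / ctrl$pdl1_cancer[1]
  expect_gt(ratio, 8)
  expect_lt(ratio, 10.5)
})

test_that("percent injected dose behaves at its limits", {
  p <- fx_mouse()
  regs <- preclinical_regimens()
  # essentially impermeable vasculature: nothing extravasates
  p0 <- p; p0$np$permeability_ref_cm_day <- 1e-30
  tr <- simulate_trajectory(p0, regs$anti_mir155)
  w <- percent_injected_dose(tr, regs$anti_mir155$events[[1]])
  expect_lt(max(w$percent_id), 1e-8)
  expect_error(percent_injected_dose(tr, dose_event("anti_mir155_np", 0, 0)),
               "zero dose")

  # probe: enormous permeability, no elimination, interstitium >> plasma
  pp <- p
  pp$np$permeability_ref_cm_day <- 1e4
  pp$np$degradation_rate_per_day <- 0
  pp$np$clearance_rate_per_day <- 0
  pp$np$diffusivity_ref_cm2_day <- 1e-30
  pp$growth$carrying_capacity_cm3 <- 1e6
  pp$growth$initial_volume_cm3 <- 1e5
  reg <- regimen(list(dose_event("anti_mir155_np", 0.2, 0)), 1, 5)
  tr <- simulate_trajectory(pp, reg)
  w <- percent_injected_dose(tr, reg$events[[1]])
  expect_gt(max(w$percent_id), 99.5)
  expect_lte(max(w$percent_id), 100)
})

test_that("per-injection %ID peaks sit in the expected band", {
  regs <- preclinical_regimens()
  tr <- fx_preclinical_sims()$anti_mir155
  peaks <- vapply(regs$anti_mir155$events, function(e)
    max(percent_injected_dose(tr, e)$percent_id), numeric(1))
  expect_gt(median(peaks), 1.5)   # soft anchor: ~3 +- 1.5 %ID
  expect_lt(median(peaks), 4.5)
})

test_that("checkpoint occupancy matches a brute-force equilibrium solver", {
  p <- fx_mouse()
  ck <- p$checkpoint
  L <- 0.4; P <- 1; ici <- c(atezolizumab = ck$kd_atezolizumab_pm,
                             pembrolizumab = 0)
  got <- checkpoint_occupancy(L, P, ici, p)
  # independent oracle: root-find the complex from the binding equations
  kd_eff <- ck$kd_pd1_pdl1_pm * (1 + ici[["atezolizumab"]] /
                                   ck$kd_atezolizumab_pm)
  f <- function(X) (L - X) * (P - X) - X * kd_eff
  X <- uniroot(f, c(0, min(L, P)), tol = 1e-14)$root
  expect_equal(got, 1 - ck$escape_max * X / (ck$inhibition_constant_pm + X),
               tolerance = 1e-9)

  # structural limits
  expect_equal(checkpoint_occupancy(0, 1, c(atezolizumab = 0,
                                            pembrolizumab = 0), p), 1)
  expect_gt(checkpoint_occupancy(10, 1, c(atezolizumab = 1e12,
                                          pembrolizumab = 0), p), 0.999)
  expect_lt(checkpoint_occupancy(10, 1, c(atezolizumab = 0,
                                          pembrolizumab = 0), p),
            checkpoint_occupancy(0.1, 1, c(atezolizumab = 0,
                                           pembrolizumab = 0), p))
})

test_that("compiled and pure-R system evaluations agree", {
  p <- fx_mouse()
  reg <- preclinical_regimens()$combination
  a <- simulate_trajectory(p, reg, rtol = 1e-8, atol = 1e-10)
  b <- simulate_trajectory(p, reg, rtol = 1e-8, atol = 1e-10,
                           use_compiled = FALSE)
  expect_equal(as.matrix(a[, -1]), as.matrix(b[, -1]), tolerance = 1e-6)
})

test_that("tightening integrator tolerances leaves the endpoint unchanged", {
  p <- fx_mouse()
  reg <- preclinical_regimens()$anti_mir155
  v1 <- trajectory_at(simulate_trajectory(p, reg, rtol = 1e-8,
                                          atol = 1e-10), "volume", 35)
  v2 <- trajectory_at(simulate_trajectory(p, reg, rtol = 5e-9,
                                          atol = 5e-11), "volume", 35)
  expect_lt(abs(v1 - v2) / v1, 1e-3)
})
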