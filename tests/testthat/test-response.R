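test_that("TGI limits: identical arms give 0%, a pinned tumor gives 100%", {
  sims <- fx_preclinical_sims()
  ctrl <- sims$control
  expect_equal(tumor_growth_inhibition(ctrl, ctrl, 28), 0)

  pinned <- ctrl
  v0 <- trajectory_at(ctrl, "volume", 7)
  pinned$volume <- rep(v0, nrow(pinned))
  attr(pinned, "regimen") <- attr(ctrl, "regimen")
  expect_equal(tumor_growth_inhibition(pinned, ctrl, 28), 100)

  # undefined before the control has grown
  expect_error(tumor_growth_inhibition(ctrl, pinned, 28), "undefined|grown")
})

test_that("spherical diameter-volume conversions invert each other", {
  expect_equal(diameter_from_volume(pi / 6), 1)
  expect_equal(diameter_from_volume(10), 2.68, tolerance = 0.005)
  expect_equal(diameter_from_volume(0), 0)
  expect_error(diameter_from_volume(-1), ">= 0")
  d <- c(0.3, 1, 1.5, 2.68, 5)
  expect_equal(diameter_from_volume(volume_from_diameter(d)), d,
               tolerance = 1e-12)
})

test_that("RECIST progression needs both the 20% and the 5 mm rule", {
  # baseline 1.5 cm: 20% is 0.3 cm < 0.5 cm floor, so PD only at 2.0 cm
  tr <- make_diam_trajectory(0:100, seq(1.5, 2.1, length.out = 101))
  s <- recist_stream(tr)
  first_pd <- s$time_day[which(s$category == "PD")[1]]
  expect_equal(s$diameter_cm[s$time_day == first_pd] >= 2.0, TRUE)
  expect_true(all(s$category[s$diameter_cm < 2.0 - 1e-9] != "PD"))

  # baseline 3.0 cm: 20% is 0.6 cm > floor, so PD at 3.6 cm
  tr <- make_diam_trajectory(0:100, seq(3, 3.8, length.out = 101))
  s <- recist_stream(tr)
  d_pd <- s$diameter_cm[which(s$category == "PD")[1]]
  expect_gte(d_pd, 3.6)
  expect_lt(d_pd, 3.62)
})

test_that("a 40% shrink is a partial response, measured from baseline", {
  tr <- make_diam_trajectory(0:60, seq(1.5, 0.9, length.out = 61))
  s <- recist_stream(tr)
  expect_identical(as.character(s$category[nrow(s)]), "PR")
  expect_identical(best_response(s), "PR")
})

test_that("progression is referenced to the nadir, not the baseline", {
  # shrink to 1.0 cm, then regrow: PD once 1.5 cm (nadir*1.2 & +0.5) is hit,
  # even though that is the baseline itself
  d <- c(seq(1.5, 1.0, length.out = 31), seq(1.0, 1.6, length.out = 40)[-1])
  tr <- make_diam_trajectory(seq_along(d) - 1, d)
  s <- recist_stream(tr)
  pd <- which(s$category == "PD")
  expect_true(length(pd) > 0)
  expect_gte(s$diameter_cm[pd[1]], 1.5)
})

test_that("time to progression converts days to months and censors", {
  # crosses its threshold (2.0 cm from 1.5 baseline) exactly at day 61
  d <- c(seq(1.5, 2.0, length.out = 62), seq(2.0, 2.2, length.out = 30)[-1])
  tr <- make_diam_trajectory(seq_along(d) - 1, d)
  ttp <- time_to_progression(tr)
  expect_true(ttp$event)
  expect_equal(ttp$ttp_months, 61 / 30.44, tolerance = 1e-9)

  shrink <- make_diam_trajectory(0:90, seq(1.5, 0.8, length.out = 91))
  ttp <- time_to_progression(shrink)
  expect_false(ttp$event)
  expect_equal(ttp$ttp_months, 90 / 30.44)
})

test_that("assessment categories are invariant to super-sampling", {
  d <- c(seq(1.5, 1.2, length.out = 31), seq(1.2, 2.3, length.out = 61)[-1])
  coarse <- make_diam_trajectory(seq_along(d) - 1, d)
  t_fine <- seq(0, length(d) - 1, by = 0.25)
  fine <- make_diam_trajectory(
    t_fine, approx(seq_along(d) - 1, d, xout = t_fine)$y)
  days <- seq(0, 90, by = 3)
  expect_identical(recist_stream(coarse, days)$category,
                   recist_stream(fine, days)$category)
})

test_that("pointwise-smaller tumors never progress earlier", {
  base <- seq(1.5, 2.4, length.out = 120)
  tr_big <- make_diam_trajectory(seq_along(base) - 1, base)
  tr_small <- make_diam_trajectory(seq_along(base) - 1, base * 0.93)
  t_big <- time_to_progression(tr_big)$ttp_months
  t_small <- time_to_progression(tr_small)$ttp_months
  expect_gte(t_small, t_big)
})
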