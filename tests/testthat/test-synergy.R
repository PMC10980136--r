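test_that("the median-effect line recovers its generating parameters", {
  # Dm = 1, m = 1: fa = D/(1+D), fa(Dm) = 0.5
  doses <- c(0.2, 0.5, 1, 2, 5)
  fa <- doses / (1 + doses)
  fit <- median_effect_fit(doses, fa)
  expect_equal(fit$m, 1, tolerance = 1e-9)
  expect_equal(fit$dm, 1, tolerance = 1e-9)
  expect_equal(fit$r, 1, tolerance = 1e-9)

  # Dm = 0.5, m = 2: closed-form generation
  dm <- 0.5; m <- 2
  fa <- 1 / (1 + (dm / doses)^m)
  fit <- median_effect_fit(doses, fa)
  expect_equal(fit$dm, dm, tolerance = 1e-9)
  expect_equal(fit$m, m, tolerance = 1e-9)
})

test_that("non-monotone effects still fit, with a poor plot correlation", {
  doses <- c(0.1, 0.3, 1, 3, 10)
  fa <- c(0.2, 0.6, 0.4, 0.7, 0.75)
  fit <- median_effect_fit(doses, fa)
  expect_lt(fit$r, 0.99)
  expect_error(median_effect_fit(c(1, 2), c(0.2, 0.4)), ">= 3")
})

test_that("required doses follow the Chou inversion and a numeric oracle", {
  fit <- structure(list(dm = 0.8, m = 1.6, r = 1, n_clipped = 0,
                        n_points = 5), class = "median_effect_fit")
  expect_equal(required_dose(fit, 0.5), 0.8)
  fit1 <- structure(list(dm = 2, m = 1, r = 1, n_clipped = 0, n_points = 5),
                    class = "median_effect_fit")
  expect_equal(required_dose(fit1, 0.9), 9 * 2)
  # numeric inversion of the median-effect curve as the oracle
  fa_of <- function(d) 1 / (1 + (fit$dm / d)^fit$m)
  for (fa in c(0.2, 0.5, 0.8)) {
    d_oracle <- uniroot(function(d) fa_of(d) - fa, c(1e-6, 1e6),
                        tol = 1e-12)$root
    expect_equal(required_dose(fit, fa), d_oracle, tolerance = 1e-7)
  }
  expect_error(required_dose(fit, 1), "strictly")
})

test_that("a sham self-combination is exactly additive", {
  # one drug split into two pseudo-drugs with the same median-effect line
  fit <- median_effect_fit(c(0.2, 0.5, 1, 2, 5),
                           1 / (1 + (0.7 / c(0.2, 0.5, 1, 2, 5))^1.3))
  fa <- 0.65
  dx <- required_dose(fit, fa)
  ci <- combination_index(c(a = 0.3 * dx, b = 0.7 * dx), fa,
                          list(a = fit, b = fit))
  expect_equal(ci, 1, tolerance = 1e-6)
  # linearity: halving all doses at fixed effect halves CI
  ci_half <- combination_index(c(a = 0.15 * dx, b = 0.35 * dx), fa,
                               list(a = fit, b = fit))
  expect_equal(ci_half, ci / 2, tolerance = 1e-9)
})

test_that("a worked two-drug case matches hand arithmetic", {
  fit_a <- structure(list(dm = 1, m = 1, r = 1, n_clipped = 0,
                          n_points = 5), class = "median_effect_fit")
  fit_b <- structure(list(dm = 4, m = 2, r = 1, n_clipped = 0,
                          n_points = 5), class = "median_effect_fit")
  fa <- 0.8
  # D_x,a = 1 * 4 = 4; D_x,b = 4 * 2 = 8; CI = 1/4 + 2/8 = 0.5
  ci <- combination_index(c(a = 1, b = 2), fa, list(a = fit_a, b = fit_b))
  expect_equal(ci, 0.5, tolerance = 1e-12)
  # three-drug form sums a third ratio
  ci3 <- combination_index(c(a = 1, b = 2, c = 2), fa,
                           list(a = fit_a, b = fit_b, c = fit_a))
  expect_equal(ci3, 0.5 + 2 / 4, tolerance = 1e-12)
})

test_that("CI is invariant to a consistent change of dose units", {
  doses <- c(0.2, 0.5, 1, 2, 5)
  fa_line <- 1 / (1 + (0.7 / doses)^1.3)
  fit_mgkg <- median_effect_fit(doses, fa_line)
  fit_ugkg <- median_effect_fit(doses * 1000, fa_line)
  ci1 <- combination_index(c(a = 0.3, b = 0.4), 0.6,
                           list(a = fit_mgkg, b = fit_mgkg))
  ci2 <- combination_index(c(a = 300, b = 400), 0.6,
                           list(a = fit_ugkg, b = fit_ugkg))
  expect_equal(ci1, ci2, tolerance = 1e-9)
})

test_that("CI classification partitions the positive axis", {
  expect_identical(as.character(classify_ci(0.25)), "strong-synergy")
  expect_identical(as.character(classify_ci(1.0)), "additive")
  expect_identical(as.character(classify_ci(1.2)), "antagonism")
  grid <- c(1e-6, 0.2999, 0.3, 0.5, 0.8999, 0.9, 1.1, 1.1001, 50)
  cls <- classify_ci(grid)
  expect_false(any(is.na(cls)))
  expect_identical(as.character(cls),
                   c("strong-synergy", "strong-synergy", "synergy",
                     "synergy", "synergy", "additive", "additive",
                     "antagonism", "antagonism"))
  expect_error(classify_ci(0), "> 0")
})

test_that("the combination screen is seed-stable and well-formed", {
  ph <- fx_human()
  fits <- monotherapy_fits(c("anti_mir155_np", "cisplatin"), params = ph,
                           n_doses = 5)
  s1 <- screen_combinations(c("anti_mir155_np", "cisplatin"), params = ph,
                            n_samples = 6, fits = fits, seed = 31)
  s2 <- screen_combinations(c("anti_mir155_np", "cisplatin"), params = ph,
                            n_samples = 6, fits = fits, seed = 31)
  expect_identical(s1$dose.anti_mir155_np, s2$dose.anti_mir155_np)
  expect_identical(s1$ci, s2$ci)
  expect_true(all(c("dose.anti_mir155_np", "dose.cisplatin", "fa", "ci",
                    "class", "frac.anti_mir155_np", "total_dose", "ok")
                  %in% names(s1)))
  expect_true(all(s1$ok))
  expect_true(all(s1$ci > 0))
  expect_equal(s1$frac.anti_mir155_np + s1$frac.cisplatin,
               rep(1, nrow(s1)), tolerance = 1e-12)
  # dose caps respected
  expect_true(all(s1$dose.anti_mir155_np <= 2.5 + 1e-9))
  expect_error(
    screen_combinations(c("anti_mir155_np", "cisplatin"), params = ph,
                        n_samples = 4,
                        dose_ranges = list(anti_mir155_np = c(0.001, 1))),
    "outside")
})

test_that("condition mining returns high-precision threshold conjunctions", {
  # constructed screen table with a known separating rule
  set.seed(8)
  n <- 120
  tab <- data.frame(
    dose.a = runif(n, 0.01, 2), dose.b = runif(n, 0.01, 2))
  tab$total_dose <- tab$dose.a + tab$dose.b
  tab$frac.a <- tab$dose.a / tab$total_dose
  tab$frac.b <- 1 - tab$frac.a
  tab$fa <- 0.5; tab$ok <- TRUE
  tab$ci <- ifelse(tab$dose.b > 0.9 & tab$frac.a < 0.5,
                   0.2, 1.0) + rnorm(n, 0, 0.01)
  tab$class <- as.character(classify_ci(pmax(tab$ci, 0.01)))
  rule <- synergy_conditions(tab, "strong-synergy")
  expect_gt(rule$precision, 0.9)
  expect_gte(rule$recall, 0.7)
  expect_true(all(rule$terms$variable %in% names(tab)))
  expect_null(synergy_conditions(tab, "antagonism"))
})
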