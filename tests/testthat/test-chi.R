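test_that("calibration line recovers exact and noisy linear standards", {
  # two points define the line
  two <- fit_calibration(data.frame(rt_min = c(1, 2),
                                    literature_index = c(10, 30)))
  expect_equal(two$slope, 20)
  expect_equal(two$intercept, -10)
  expect_equal(two$r_squared, 1)

  # exact fit on y = 5x + 3
  exact <- fit_calibration(data.frame(rt_min = 1:6,
                                      literature_index = 5 * (1:6) + 3))
  expect_equal(exact$slope, 5)
  expect_equal(exact$intercept, 3)

  # noisy standards: estimates agree with the closed-form OLS oracle and
  # land within 3 standard errors of the truth
  std <- gen_calibration_run(12, 4, n_standards = 20, noise_sd = 0.5,
                             seed = 42)
  fit <- fit_calibration(std)
  oracle <- ols_line_oracle(std$rt_min, std$literature_index)
  expect_equal(fit$slope, oracle$slope, tolerance = 1e-10)
  expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-10)
  expect_lt(abs(fit$slope - 12), 3 * oracle$se_slope)
  expect_lt(abs(fit$intercept - 4), 3 * oracle$se_intercept)
})

test_that("degenerate calibration inputs are rejected", {
  expect_error(fit_calibration(data.frame(rt_min = 1,
                                          literature_index = 10)),
               "at least 2")
  expect_error(fit_calibration(data.frame(rt_min = c(2, 2, 2),
                                          literature_index = c(1, 2, 3))),
               "identical")
})

test_that("applying a calibration maps and flags extrapolation", {
  line <- list(slope = 20, intercept = -10)
  expect_equal(as.numeric(apply_calibration(line, 2)), 30)
  beyond <- apply_calibration(line, 6)
  expect_equal(as.numeric(beyond), 110)
  expect_true(attr(beyond, "extrapolated"))
  ident <- apply_calibration(list(slope = 1, intercept = 0), 3.7)
  expect_equal(as.numeric(ident), 3.7)
  expect_false(attr(ident, "extrapolated"))
  expect_error(apply_calibration(line, -1), "negative")
})

test_that("calibration and application compose to the identity on exact standards", {
  std <- data.frame(rt_min = seq(0.5, 5, by = 0.5))
  std$literature_index <- 18 * std$rt_min - 7
  fit <- fit_calibration(std)
  expect_equal(fit$r_squared, 1)
  expect_equal(as.numeric(apply_calibration(fit, std$rt_min)),
               std$literature_index, tolerance = 1e-10)
})

test_that("CHI to CHI LogP conversion matches the printed column", {
  expect_equal(chi_to_chilogp(91.64, round = TRUE), 3.48)
  expect_equal(chi_to_chilogp(118.39, round = TRUE), 4.93)
  expect_equal(chi_to_chilogp(1.467 / 0.054), 0)
  # full 26-row reproduction from the pH 10.6 column
  t1 <- ipsapirone_logp(); t3 <- ipsapirone_chromatography()
  expect_equal(chi_to_chilogp(t3$`CHI_pH10.6`, round = TRUE), t1$CHI_LogP)
})

test_that("percent-HSA and logK transforms are exact mutual inverses", {
  expect_equal(pct_hsa_to_logk(47.66, round = TRUE), -0.05)
  expect_equal(pct_hsa_to_logk(99.13, round = TRUE), 1.72)
  expect_equal(pct_hsa_to_logk(50.5), 0)
  expect_equal(as.numeric(logk_to_pct_hsa(0)), 50.5)

  grid <- seq(-1, 2, by = 0.1)
  expect_equal(pct_hsa_to_logk(as.numeric(logk_to_pct_hsa(grid))), grid,
               tolerance = 1e-12)

  # strong binders exceed 100 percent and come back censored
  strong <- logk_to_pct_hsa(2.27)
  expect_equal(as.numeric(strong), 100.46, tolerance = 5e-3)
  expect_true(attr(strong, "censored"))

  expect_error(pct_hsa_to_logk(0), "between 0 and 101")
  expect_error(pct_hsa_to_logk(101), "between 0 and 101")
})

test_that("tabulated logK values are reproduced from percent HSA within 0.01", {
  t3 <- ipsapirone_chromatography()
  ok <- !t3$pct_HSA_censored
  recomputed <- pct_hsa_to_logk(t3$pct_HSA[ok], round = TRUE)
  expect_true(all(abs(recomputed - t3$logK_HSA[ok]) <= 0.01 + 1e-9))
})

test_that("acid/base calls follow the CHI-vs-pH profile", {
  basic <- classify_acid_base(48.96, 88.07, 91.64, threshold = 10)
  expect_equal(basic$call, "basic")
  expect_false(basic$ambiguous)

  neutral <- classify_acid_base(50, 50, 50, threshold = 10)
  expect_equal(neutral$call, "neutral")

  acidic <- classify_acid_base(91.64, 88.07, 48.96, threshold = 10)
  expect_equal(acidic$call, "acidic")

  # rise then fall beyond threshold in both directions: dominant wins,
  # flagged ambiguous
  amb <- classify_acid_base(40, 80, 55, threshold = 10)
  expect_equal(amb$call, "basic")
  expect_true(amb$ambiguous)
})

test_that("fixture profiles classify basic except the pH 2.6 outlier of compound 8", {
  t3 <- ipsapirone_chromatography()
  calls <- classify_acid_base(t3$`CHI_pH2.6`, t3$`CHI_pH7.4`,
                              t3$`CHI_pH10.6`)
  expect_equal(sum(calls$call == "basic"), 25)
  # compound 8's printed CHI at pH 2.6 (97.99) sits within 3.4 CHI units
  # of its pH 7.4 value, so its profile is flat at the default threshold
  expect_equal(calls$call[8], "neutral")
})

test_that("half-away-from-zero rounding differs from banker's rounding where it should", {
  expect_equal(round_half_away(2.675, 2), 2.68)
  expect_equal(round_half_away(-2.675, 2), -2.68)
  expect_equal(round_half_away(0.125, 2), 0.13)
})
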