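test_that("the allometric mass estimator reproduces the worked example", {
  expect_equal(round(campione_evans_mass(14, 13), 2), 0.68)
  expect_equal(round(100 * campione_evans_mass(14, 13) / 1.2602), 54)
  # closed-form scaling: doubling both circumferences
  expect_equal(campione_evans_mass(28, 26) / campione_evans_mass(14, 13),
               2^2.749, tolerance = 1e-12)
  expect_error(campione_evans_mass(-1, 13), "positive")
})

test_that("the mass estimator is strictly increasing in each circumference", {
  base <- campione_evans_mass(14, 13)
  expect_gt(campione_evans_mass(14.1, 13), base)
  expect_gt(campione_evans_mass(14, 13.1), base)
})

test_that("the default battery has 22 tests and recovers separated classes", {
  specs <- default_lda_test_specs()
  expect_length(specs, 22)
  d <- make_toy_morphometrics(seed = 1, biped_mean = rep(0, 4),
                              quadruped_mean = rep(3, 4), n = 40)
  v <- lda_stance_tests(d, nrow(d), seed = 1)
  expect_equal(v$tally, 22)
  expect_equal(v$majority, "quadruped")
  expect_true(all(v$posteriors > 0.9, na.rm = TRUE))
  # reproducible given the seed
  v2 <- lda_stance_tests(d, nrow(d), seed = 1)
  expect_identical(v$posteriors, v2$posteriors)
})

test_that("a focal taxon equidistant between centroids has posterior ~0.5", {
  d <- make_toy_morphometrics(seed = 2, biped_mean = rep(0, 4),
                              quadruped_mean = rep(3, 4), n = 4000,
                              focal_offset = rep(-1.5, 4))
  v <- lda_stance_tests(d, nrow(d), seed = 2, prior = "equal")
  full <- v$posteriors[15]  # the all-predictors, full-training test
  expect_lt(abs(full - 0.5), 0.05)
})

test_that("identical class distributions give ~0.5 expected posterior", {
  ps <- vapply(1:20, function(s) {
    d <- make_toy_morphometrics(seed = s, biped_mean = rep(0, 4),
                                quadruped_mean = rep(0, 4), n = 60,
                                focal_offset = rep(0, 4))
    specs <- list(list(predictors = c("body_mass", "dimensionless_com",
                                      "forelimb_length", "hindlimb_length"),
                       frac = 1))
    lda_stance_tests(d, nrow(d), specs, seed = s,
                     prior = "equal")$posteriors[1]
  }, numeric(1))
  expect_lt(abs(mean(ps) - 0.5), 0.1)  # within Monte-Carlo error
})

test_that("LDA posteriors are invariant to affine predictor rescaling", {
  d <- make_toy_morphometrics(seed = 3, n = 50)
  specs <- list(list(predictors = c("body_mass", "dimensionless_com",
                                    "forelimb_length", "hindlimb_length"),
                     frac = 1))
  v1 <- lda_stance_tests(d, nrow(d), specs, seed = 1)
  d2 <- d
  d2$body_mass <- 100 * d2$body_mass - 7
  d2$forelimb_length <- 0.01 * d2$forelimb_length + 3
  v2 <- lda_stance_tests(d2, nrow(d2), specs, seed = 1)
  expect_equal(v1$posteriors, v2$posteriors, tolerance = 1e-8)
})

test_that("singular training data marks the test failed, not dropped", {
  d <- make_toy_morphometrics(seed = 4, n = 20)
  d$body_mass <- 1  # constant predictor: within-class variance zero
  specs <- list(list(predictors = "body_mass", frac = 1),
                list(predictors = "hindlimb_length", frac = 1))
  v <- lda_stance_tests(d, nrow(d), specs, seed = 1)
  expect_length(v$posteriors, 2)
  expect_true(is.na(v$posteriors[1]))
  expect_false(is.na(v$posteriors[2]))
})

test_that("circumference regression fits, hulls and degeneracies behave", {
  # exact line
  cf <- seq(1, 2, length.out = 10)
  d <- data.frame(log_femoral = cf, log_humeral = 0.9 * cf + 0.05,
                  stance = rep(c("quadruped", "biped"), 5))
  r <- circumference_regression(d)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  expect_equal(r$slope, 0.9, tolerance = 1e-12)
  # seeded noisy line: slope within 2 SE
  set.seed(10)
  dn <- data.frame(log_femoral = cf,
                   log_humeral = 0.9 * cf + 0.05 + rnorm(10, sd = 0.02),
                   stance = rep(c("quadruped", "biped"), 5))
  rn <- circumference_regression(dn)
  se <- summary(rn$fit)$coefficients["log_femoral", "Std. Error"]
  expect_lt(abs(rn$slope - 0.9), 2 * se)
  # point-in-hull: focal inside the quadruped triangle
  dh <- data.frame(
    log_femoral = c(0, 1, 0.5, 0.5, 5, 6, 5.5),
    log_humeral = c(0, 0, 1, 0.3, 5, 5, 6),
    stance = c("quadruped", "quadruped", "quadruped", "unknown",
               "biped", "biped", "biped"))
  rh <- circumference_regression(dh, focal_row = 4)
  expect_true(rh$focal_in_hull[["quadruped"]])
  expect_false(rh$focal_in_hull[["biped"]])
  dbad <- data.frame(log_femoral = rep(1, 5), log_humeral = 1:5,
                     stance = "quadruped")
  expect_error(circumference_regression(dbad), "degenerate")
})

test_that("the static bipedalism criterion bands are correct", {
  b <- static_bipedalism_check(0.053, 0.080)
  expect_equal(round(b$ratio_pct), 66)
  expect_equal(b$verdict, "marginal")
  expect_equal(static_bipedalism_check(0.09, 0.080)$verdict, "fails")
  expect_equal(static_bipedalism_check(0, 0.080)$verdict, "passes")
  expect_equal(static_bipedalism_check(0.047, 0.080)$verdict, "passes")
  expect_equal(static_bipedalism_check(0.048, 0.080)$verdict, "marginal")
  expect_equal(static_bipedalism_check(0.080, 0.080)$verdict, "fails")
  expect_error(static_bipedalism_check(0.05, 0), "positive")
})
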