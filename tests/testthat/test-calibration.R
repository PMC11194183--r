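test_that("power fit recovers exact parameters on noiseless data", {
  om <- c(0.6, 0.8, 1.0, 1.3, 1.7)
  tr <- 0.7 * om^0.255
  fit <- fit_power_per_season(om, tr)
  expect_equal(fit$alpha, 0.7, tolerance = 1e-9)
  expect_equal(fit$exponent, 0.255, tolerance = 1e-9)
  nls_fit <- fit_power_per_season(om, tr, method = "nls")
  expect_equal(nls_fit$exponent, 0.255, tolerance = 1e-6)
  expect_error(fit_power_per_season(rep(1, 5), tr), "distinct")
  expect_error(fit_power_per_season(om, -tr), "positive")
})

test_that("power fit is scale-consistent and unbiased under noise", {
  om <- c(0.6, 0.8, 1.0, 1.3, 1.7)
  tr <- 0.7 * om^0.255
  f1 <- fit_power_per_season(om, tr)
  f2 <- fit_power_per_season(om, 1.2 * tr)
  expect_equal(f2$alpha, 1.2 * f1$alpha, tolerance = 1e-9)
  expect_equal(f2$exponent, f1$exponent, tolerance = 1e-9)
  # 200 noisy single-season refits: mean exponent within 2 SE of truth
  set.seed(31)
  bs <- replicate(200, {
    omr <- runif(21, 0.6, 1.7)
    trr <- 0.7 * omr^0.255 + rnorm(21, 0, 0.03)
    fit_power_per_season(omr, trr)$exponent
  })
  expect_lt(abs(mean(bs) - 0.255), 2 * sd(bs) / sqrt(200))
})

test_that("exponent averaging returns mean and SE = SD/sqrt(n)", {
  avg <- average_exponent(c(0.2, 0.3))
  expect_equal(avg$mean, 0.25)
  expect_equal(avg$se, 0.05)
  expect_equal(average_exponent(rep(0.255, 5))$se, 0)
  expect_error(average_exponent(0.2), ">= 2")
  # five-season draws at the observed spread give SE ~ sigma/sqrt(5)
  set.seed(32)
  ses <- replicate(2000, average_exponent(rnorm(5, 0.255, 0.072))$se)
  expect_equal(mean(ses), 0.072 / sqrt(5), tolerance = 0.05)
})

test_that("alpha tracks Day-0 transparency along the calibration line", {
  expect_equal(round(alpha_from_day0(0.90), 2), 0.82)
  expect_equal(alpha_from_day0(0.90), 1.0293 * 0.90 - 0.1087)
  expect_equal(alpha_from_day0(0.1087 / 1.0293), 0, tolerance = 1e-12)
  expect_equal(alpha_from_day0(0.63), 0.5398, tolerance = 1e-4)
  expect_error(alpha_from_day0(0.05), "within")
  expect_error(alpha_from_day0(1.2), "within")
})

test_that("D4T is the power-law baseline", {
  expect_equal(predict_d4t(1, alpha = 0.77), 0.77)
  expect_equal(predict_d4t(1.5, alpha = 0.82), 0.82 * 1.5^0.255)
  expect_equal(predict_d4t(1.5, alpha = 0.82), 0.90932, tolerance = 1e-5)
  expect_equal(predict_d4t(0.63, alpha = 0.82), 0.72886, tolerance = 1e-5)
  expect_error(predict_d4t(-1, alpha = 0.8), "positive")
})

test_that("duration regression recovers slope and beta exactly when noiseless", {
  grid <- expand.grid(duration_days = c(1.5, 4, 8, 15),
                      treatment = c("medium", "high"), rep = 1:3,
                      stringsAsFactors = FALSE)
  grid$season <- "Nov14"
  grid$omega_ar <- runif(nrow(grid), 0.6, 1.1)
  alpha <- c(Nov14 = 0.75)
  grid$transparency <- predict_d4t(grid$omega_ar, 0.75) -
    0.0238 * grid$duration_days + 0.1026
  fit <- fit_duration_effect(grid, alpha)
  expect_equal(fit$duration_slope, -0.0238, tolerance = 1e-9)
  expect_equal(fit$beta, 0.1026, tolerance = 1e-9)

  amb <- grid; amb$treatment <- "ambient"
  expect_error(fit_duration_effect(amb, alpha), "ambient-only")
  one <- grid[grid$duration_days == 4, ]
  expect_error(fit_duration_effect(one, alpha), "distinct")
})

test_that("duration slope recovery is unbiased over noisy replicates", {
  slopes <- vapply(1:200, function(i) {
    d <- generate_duration_dataset(generator_config(), seed = i)
    fit_duration_effect(d, attr(d, "alpha_by_season"), 0.255)$duration_slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) + 0.0238), 2 * sd(slopes) / sqrt(200))
})

test_that("the full calibration chain refits generated data", {
  d <- generate_transparency_dataset(generator_config(), seed = 7)
  fit <- fit_transparency_model(d)
  expect_s3_class(fit, "shellcal")
  truth <- attr(d, "alpha_by_season")
  expect_equal(unname(fit$alpha_by_season[names(truth)]), unname(truth),
               tolerance = 0.05)
  expect_lt(abs(fit$exponent_b - 0.255), 3 * fit$exponent_se)
  # the generator derives Day-0 from the published alpha line, so the
  # refit alpha line is tight
  expect_gt(fit$alpha_line["r2"], 0.95)
  expect_equal(unname(fit$alpha_line["slope"]), 1.0293, tolerance = 0.15)
  expect_lt(abs(fit$alpha_pristine - alpha_from_day0(0.90)), 0.05)
})

test_that("shellcal methods behave as a classed model fit", {
  d <- generate_transparency_dataset(generator_config(), seed = 8)
  fit <- fit_transparency_model(d)
  expect_output(print(fit), "exponent b")
  expect_output(print(summary(fit)), "Per-season power fits")
  cf <- coef(fit)
  expect_true(all(c("exponent_b", "duration_slope", "beta") %in% names(cf)))
  expect_equal(length(residuals(fit)), nrow(d))
  expect_equal(residuals(fit), d$transparency - predict(fit))
  # predictions at the reference day are the D4T baseline
  nd <- data.frame(season = names(fit$alpha_by_season)[1],
                   omega_ar = 1, duration_days = 4)
  expect_equal(predict(fit, nd), unname(fit$alpha_by_season[1]))
  expect_error(predict(fit, transform(nd, season = "nope")), "absent")
  # simulate: deterministic under seed, same design size
  s1 <- simulate(fit, nsim = 1, seed = 99)
  s2 <- simulate(fit, nsim = 1, seed = 99)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), nrow(d))
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
})
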