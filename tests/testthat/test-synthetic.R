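test_that("all generators are deterministic under a fixed seed", {
  cfg <- generator_config(n_genes = 200, n_strong = 20, n_very_strong = 5)
  expect_identical(generate_transparency_dataset(cfg, seed = 1),
                   generate_transparency_dataset(cfg, seed = 1))
  expect_identical(generate_duration_dataset(cfg, seed = 1),
                   generate_duration_dataset(cfg, seed = 1))
  expect_identical(generate_expression_matrix(cfg, seed = 1),
                   generate_expression_matrix(cfg, seed = 1))
  expect_identical(generate_respiration_dataset(cfg, seed = 1),
                   generate_respiration_dataset(cfg, seed = 1))
  expect_identical(lapply(generate_shell_images(c(0.5, 0.8), seed = 1),
                          unclass),
                   lapply(generate_shell_images(c(0.5, 0.8), seed = 1),
                          unclass))
  expect_false(identical(generate_transparency_dataset(cfg, seed = 1),
                         generate_transparency_dataset(cfg, seed = 2)))
})

test_that("noise-free ambient Day-4 records follow the power law exactly", {
  cfg <- generator_config(noise_sd_transparency = 0, durations_days = 4)
  d <- generate_transparency_dataset(cfg, seed = 2)
  alpha <- attr(d, "alpha_by_season")
  amb <- d[d$treatment == "ambient", ]
  expect_equal(amb$transparency,
               unname(alpha[amb$season]) * amb$omega_ar^0.255,
               tolerance = 1e-12)
})

test_that("generated saturation states match the seasonal design", {
  cfg <- generator_config(n_per_cell = 1000, durations_days = 4)
  d <- generate_transparency_dataset(cfg, seed = 3)
  agg_m <- aggregate(omega_ar ~ season + treatment, d, mean)
  agg_s <- aggregate(omega_ar ~ season + treatment, d, sd)
  key <- paste(chem$season, chem$treatment)
  mu <- chem$omega_ar[match(paste(agg_m$season, agg_m$treatment), key)]
  sd_ <- chem$omega_sd[match(paste(agg_m$season, agg_m$treatment), key)]
  expect_true(all(abs(agg_m$omega_ar - mu) < 4 * sd_ / sqrt(1000) + 1e-3))
  expect_true(all(abs(agg_s$omega_ar - sd_) < 0.01))
})

test_that("transparency respects the biological floor and the unit cap", {
  d <- generate_transparency_dataset(
    generator_config(noise_sd_transparency = 0.15), seed = 4)
  expect_true(all(d$transparency >= 0.40))
  expect_true(all(d$transparency <= 1))
  expect_error(generator_config(transparency_floor = 0.6), "floor")
  expect_error(generator_config(n_very_strong = 10, n_strong = 5))
})

test_that("generated images honour targets, holes and exclusions", {
  img1 <- generate_shell_images(1.0, seed = 6)[[1]]
  expect_true(all(unclass(img1) == 255))
  expect_error(segment_shell(img1), "no shell detected")
  expect_error(generate_shell_images(1.2), "\\(0, 1\\]")
  # punched hole + exclusion leaves the score at the target
  plain <- generate_shell_images(0.6, seed = 7)[[1]]
  holed <- generate_shell_images(0.6, hole = TRUE, seed = 7)[[1]]
  s_plain <- transparency_score(plain, segment_shell(plain))
  m_holed <- segment_shell(holed,
                           excluded_regions = attr(holed, "exclusions"))
  expect_equal(transparency_score(holed, m_holed), s_plain,
               tolerance = 1e-12)
  expect_equal(s_plain, 0.6, tolerance = 0.005)
  # without the exclusion the dark hole pixels drag the score down
  expect_lt(transparency_score(holed, segment_shell(holed)), s_plain)
})

test_that("the calibration chain recovers the generating parameters", {
  # exponent: Day-4 seasonal datasets, uniform saturation states
  cfg7 <- generator_config(durations_days = 4, omega_range = c(0.6, 1.7))
  bs <- vapply(1:60, function(i)
    fit_transparency_model(generate_transparency_dataset(cfg7,
                                                         seed = i))$
      exponent_b, numeric(1))
  expect_lt(abs(mean(bs) - 0.255), 2 * sd(bs) / sqrt(length(bs)))
  # duration slope: linear-deficit duration datasets
  ss <- vapply(1:60, function(i) {
    d <- generate_duration_dataset(generator_config(), seed = i)
    fit_duration_effect(d, attr(d, "alpha_by_season"),
                        0.255)$duration_slope
  }, numeric(1))
  expect_lt(abs(mean(ss) + 0.0238), 2 * sd(ss) / sqrt(length(ss)))
  # seasonal exponent spread is consistent with a common true exponent
  # (no season-specific slopes, mirroring the no-interaction finding)
  d <- generate_transparency_dataset(cfg7, seed = 101)
  fit <- fit_transparency_model(d)
  per_se <- vapply(seq_len(nrow(fit$seasons)), function(i) {
    s <- fit$seasons$season[i]
    sub <- d[d$season == s, ]
    summary(fit_power_per_season(sub$omega_ar, sub$transparency)$fit)$
      coefficients[2, 2]
  }, numeric(1))
  z <- (fit$seasons$exponent - fit$exponent_b) / per_se
  expect_lt(sum(z^2), qchisq(0.999, df = nrow(fit$seasons) - 1))
})
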