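test_that("DIC-TA speciation reproduces the seasonal mean chemistry", {
  sol <- solve_from_dic_ta(chem$dic_umol_kg, chem$ta_umol_kg,
                           chem$salinity, chem$temperature_C)
  # omega and pCO2 were computed from the same DIC-TA pairs originally
  expect_true(all(abs(sol$omega_ar - chem$omega_ar) < 0.05))
  expect_true(all(abs(sol$pco2_uatm - chem$pco2_uatm) /
                    chem$pco2_uatm < 0.05))
  # headline rows
  jan_a <- sol[1, ]
  expect_equal(jan_a$omega_ar, 1.69, tolerance = 0.05 / 1.69)
  expect_equal(jan_a$pco2_uatm, 421, tolerance = 0.05)
  expect_equal(sol$omega_ar[12], 0.63, tolerance = 0.05 / 0.63)  # Nov high
  expect_equal(sol$ph[6], 7.60, tolerance = 0.02 / 7.60)         # Apr14 high
  # the April experiments' measured pH is consistent with the bottle means
  apr <- chem$season %in% c("Apr14", "Apr15")
  expect_true(all(abs(sol$ph[apr] - chem$ph[apr]) < 0.02))
})

test_that("pH-TA speciation round-trips with the DIC-TA solver", {
  sol <- solve_from_dic_ta(chem$dic_umol_kg, chem$ta_umol_kg,
                           chem$salinity, chem$temperature_C)
  back <- solve_from_ph_ta(sol$ph, chem$ta_umol_kg,
                           chem$salinity, chem$temperature_C)
  expect_true(all(abs(back$dic_umol_kg - chem$dic_umol_kg) < 0.01))
  expect_equal(back$omega_ar, sol$omega_ar, tolerance = 1e-6)
  expect_equal(back$pco2_uatm, sol$pco2_uatm, tolerance = 1e-6)
  # inverse direction of the January ambient row
  jan <- solve_from_ph_ta(7.95, 2248.2, 32, 8.02)
  expect_lt(abs(jan$dic_umol_kg - 2101), 35)
})

test_that("solver pH matches an independent bisection oracle to 1e-6", {
  set.seed(11)
  for (i in 1:100) {
    S <- runif(1, 28, 36); Tc <- runif(1, 2, 20)
    ta <- runif(1, 2100, 2400); dic <- ta * runif(1, 0.85, 0.99)
    sol <- solve_from_dic_ta(dic, ta, S, Tc)
    # plain bisection on the alkalinity residual over pH in [6, 9]
    k <- shellcal:::.carb_k(S, Tc)
    f <- function(p) shellcal:::.ta_from_h(10^(-p), dic * 1e-6, k) - ta * 1e-6
    lo <- 6; hi <- 9
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (sign(f(mid)) == sign(f(lo))) lo <- mid else hi <- mid
    }
    expect_lt(abs(sol$ph - (lo + hi) / 2), 1e-6)
  }
})

test_that("increasing DIC at fixed TA lowers pH and omega, raises pCO2", {
  dics <- seq(1950, 2250, by = 50)
  sol <- solve_from_dic_ta(dics, 2250, 33, 8)
  expect_true(all(diff(sol$ph) < 0))
  expect_true(all(diff(sol$omega_ar) < 0))
  expect_true(all(diff(sol$pco2_uatm) > 0))
})

test_that("omega_aragonite is the saturation ratio and is linear in CO3", {
  k <- shellcal:::.carb_k(32, 8.02)
  co3_sat <- k$Kar / k$Ca
  expect_equal(omega_aragonite(co3_sat, 32, 8.02), 1.0, tolerance = 1e-12)
  expect_equal(omega_aragonite(2 * co3_sat, 32, 8.02), 2.0,
               tolerance = 1e-12)
  # April 2015 high row: carbonate ion implied by the DIC-TA solution
  sol <- solve_from_dic_ta(2202.0, 2216.8, 33, 8.04)
  k15 <- shellcal:::.carb_k(33, 8.04)
  h <- 10^(-sol$ph)
  co3 <- 2202.0e-6 * k15$K1 * k15$K2 / (h^2 + k15$K1 * h + k15$K1 * k15$K2)
  expect_equal(omega_aragonite(co3, 33, 8.04), 0.70, tolerance = 0.05 / 0.70)
})

test_that("input validation and the batch interface work", {
  expect_error(solve_from_dic_ta(2100, 2250, 50, 8), "salinity")
  expect_error(solve_from_dic_ta(2100, 2250, 33, 45), "temperature")
  expect_error(solve_from_dic_ta(-1, 2250, 33, 8), "positive")
  expect_error(solve_from_ph_ta(5.2, 2250, 33, 8), "\\[6, 9\\]")

  tab <- data.frame(sample_id = c("a", "b"), salinity = 33,
                    temperature_C = 8, dic_umol_kg = c(2100, 2200),
                    ta_umol_kg = 2250)
  out <- carb_solve(tab, pair = "dic-ta")
  expect_named(out, c("sample_id", "salinity", "temperature_C",
                      "dic_umol_kg", "ta_umol_kg", "ph", "pco2_uatm",
                      "omega_ar"))
  expect_true(all(out$omega_ar > 0))
  expect_error(carb_solve(tab[, -4], pair = "dic-ta"), "missing columns")
  # Lee (2010) borate is selectable and shifts the solution only slightly
  alt <- solve_from_dic_ta(2100, 2250, 33, 8,
                           carb_constants(borate = "lee2010"))
  ref <- solve_from_dic_ta(2100, 2250, 33, 8)
  expect_false(alt$ph == ref$ph)
  expect_lt(abs(alt$ph - ref$ph), 0.01)
})
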