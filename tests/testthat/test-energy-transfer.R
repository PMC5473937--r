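test_that("transfer rate follows the inverse-power law in the distance ratio", {
  set4 <- energy_transfer_model(5, exponent = 4, tau_d = 2)
  fret <- energy_transfer_model(5, exponent = 6, tau_d = 2)
  # rate equals 1/tau_D at the characteristic distance
  expect_equal(transfer_rate(set4, 5), 1 / 2)
  expect_equal(transfer_rate(fret, 5), 1 / 2)
  # doubling the distance divides by 2^exponent
  expect_equal(transfer_rate(set4, 10), (1 / 2) / 16)
  expect_equal(transfer_rate(fret, 10), (1 / 2) / 64)
  # scale invariance: tau_D * rate depends only on the ratio x0/x
  for (s in c(0.5, 2, 7)) {
    m <- energy_transfer_model(5 * s, exponent = 4, tau_d = 1)
    expect_equal(transfer_rate(m, 12 * s) * m$tau_d,
                 transfer_rate(set4, 12) * set4$tau_d)
  }
  expect_error(transfer_rate(set4, 0), "> 0")
  expect_error(transfer_rate(set4, -3), "> 0")
  expect_error(energy_transfer_model(5, exponent = 5), "4 .*or 6")
})

test_that("attenuation factor is 1/2 at d0, monotone, and bounded", {
  for (expo in c(4, 6)) for (d0 in c(2, 5, 7, 10)) {
    m <- energy_transfer_model(d0, expo)
    expect_equal(set_attenuation(m, d0), 0.5)
    expect_equal(set_attenuation(m, Inf), 1)
    d <- seq(0.5, 100, by = 0.5)
    A <- set_attenuation(m, d)
    expect_true(all(diff(A) > 0))
    expect_true(all(A > 0 & A < 1))
  }
  m <- energy_transfer_model(10, 4)
  expect_equal(set_attenuation(m, 20), 1 / (1 + 0.0625))
  # larger d0 quenches more at every distance
  d <- seq(1, 50, by = 1)
  A5 <- set_attenuation(energy_transfer_model(5, 4), d)
  A10 <- set_attenuation(energy_transfer_model(10, 4), d)
  expect_true(all(A10 < A5))
  expect_error(set_attenuation(m, -1), ">= 0")
})

test_that("combined profile multiplies intensity by nearest-surface attenuation", {
  sheet <- fx_sheet(); sol <- fx_solution()
  probe <- probe_line(sheet, max_distance_nm = 200, n = 101)
  lspr <- lspr_profile(sheet, 561, probe, solution = sol)
  m5 <- energy_transfer_model(5, 4)
  comb <- combined_excitation_profile(lspr, sheet, probe, m5)
  expect_equal(unique(comb$label), "lspr_x_set")
  # attenuation can only reduce the excitation
  expect_true(all(comb$relative_intensity <= lspr$relative_intensity))
  # the product is exactly intensity x attenuation at the nearest surface
  d <- nearest_surface_distance(sheet, cbind(0, 0, probe$D_grid))
  expect_equal(comb$relative_intensity,
               lspr$relative_intensity * set_attenuation(m5, d))
  # both factors tend to 1 far from the sheet
  expect_equal(comb$relative_intensity[length(probe$D_grid)], 1,
               tolerance = 0.05)
  # stronger quenching (larger d0) lies pointwise below
  comb10 <- combined_excitation_profile(lspr, sheet, probe,
                                        energy_transfer_model(10, 4))
  expect_true(all(comb10$relative_intensity <= comb$relative_intensity))
  # grid mismatch is rejected
  probe2 <- probe_line(sheet, max_distance_nm = 200, n = 51)
  expect_error(combined_excitation_profile(lspr, sheet, probe2, m5),
               "grid mismatch")
})

test_that("distance exponent is recovered exactly from noiseless curves", {
  d <- seq(2, 15, length.out = 12)
  for (expo in c(4, 6)) {
    m <- energy_transfer_model(5, expo)
    fit <- fit_distance_exponent(d, set_attenuation(m, d))
    expect_equal(fit$exponent, expo, tolerance = 1e-10)
    expect_equal(fit$d0_nm, 5, tolerance = 1e-8)
  }
})

test_that("exponent recovery tolerates measurement noise", {
  d <- seq(2, 15, length.out = 20)
  m <- energy_transfer_model(5, 4)
  A <- withr::with_seed(101, {
    pmin(pmax(set_attenuation(m, d) * (1 + rnorm(20, 0, 0.01)), 1e-6),
         1 - 1e-6)
  })
  fit <- fit_distance_exponent(d, A)
  expect_true(fit$ci[1] <= 4 && 4 <= fit$ci[2])
  expect_equal(fit$exponent, 4, tolerance = 0.1)
})

test_that("degenerate exponent fits are rejected", {
  m <- energy_transfer_model(5, 4)
  d_narrow <- seq(4, 6, length.out = 8)
  expect_error(fit_distance_exponent(d_narrow, set_attenuation(m, d_narrow)),
               "factor of 3")
  d4 <- c(2, 4, 8, 16)
  expect_error(fit_distance_exponent(d4, set_attenuation(m, d4)),
               "at least 5 points")
  d <- seq(2, 15, length.out = 6)
  expect_error(fit_distance_exponent(d, rep(1, 6)), "inside \\(0, 1\\)")
})
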