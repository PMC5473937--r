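# The coupled-dipole solver is checked against two independent oracles: the
# quasi-static single-sphere closed form, and a brute-force two-dipole
# linear system assembled by hand in the test.

test_that("single-sphere enhancement has the closed-form limits", {
  au <- fx_material()
  a <- 6.3
  # field tends to the incident field far away
  far <- single_sphere_enhancement(au, a, 561, c(0, 0, 1e6))
  expect_equal(far, 1, tolerance = 1e-12)
  # pole-side surface intensity equals |3 eps / (eps + 2 eps_m)|^2
  eps <- permittivity(au, 561); eps_m <- 1.33^2
  pole <- single_sphere_enhancement(au, a, 561, c(a, 0, 0))
  expect_equal(pole, Mod(3 * eps / (eps + 2 * eps_m))^2, tolerance = 1e-10)
  expect_error(single_sphere_enhancement(au, a, 561, c(0, 0, 1)),
               "inside the sphere")
})

test_that("the enhancement diverges at the Frohlich resonance pole", {
  # a synthetic lossless material whose permittivity approaches -2 eps_m
  eps_m <- 1.33^2
  mk <- function(eps_re) {
    tab <- data.frame(wavelength_nm = seq(400, 700, by = 50),
                      eps_real = eps_re, eps_imag = 1e-6)
    gold_material(host_index = 1.33, table = tab,
                  fit_window_nm = c(450, 650))
  }
  near <- single_sphere_enhancement(mk(-2 * eps_m - 1e-3), 5, 561, c(5, 0, 0))
  nearer <- single_sphere_enhancement(mk(-2 * eps_m - 1e-5), 5, 561, c(5, 0, 0))
  expect_gt(nearer, near)
  expect_gt(nearer, 1e8)
})

test_that("one-particle coupled-dipole solve equals the closed form", {
  one <- nanoparticle_sheet(material = fx_material(),
                            positions = matrix(0, 1, 3))
  # distances >= 1 nm from the surface, several directions
  pts <- rbind(c(7.3, 0, 0), c(0, 7.3, 0), c(0, 0, 8), c(6, 6, 6), c(0, 0, 50))
  for (pol in list(c("x", 1, 0, 0), c("y", 0, 1, 0))) {
    cda <- compute_near_field(one, 561, pts, polarization = pol[1])
    oracle <- single_sphere_enhancement(fx_material(), 6.3, 561, pts,
                                        polarization = as.numeric(pol[2:4]))
    expect_equal(cda, oracle, tolerance = 0.01)
  }
})

test_that("dimer coupled-dipole solve matches a brute-force two-dipole system", {
  au <- fx_material()
  pitch <- 15.2; a <- 6.3
  dimer <- nanoparticle_sheet(material = au,
                              positions = rbind(c(-pitch / 2, 0, 0),
                                                c(pitch / 2, 0, 0)))
  # independent assembly: p1 = alpha (E0 + G12 p2), p2 = alpha (E0 + G21 p1)
  eps <- permittivity(au, 561); eps_m <- au$host_index^2
  alpha <- a^3 * (eps - eps_m) / (eps + 2 * eps_m)
  G <- function(d) {
    r <- sqrt(sum(d^2)); n <- d / r
    (3 * outer(n, n) - diag(3)) / r^3
  }
  r12 <- c(-pitch, 0, 0)
  A <- rbind(cbind(diag(3) / alpha, -G(r12)),
             cbind(-G(-r12), diag(3) / alpha))
  pts <- rbind(c(0, 0, 0.5), c(0, 0, 3), c(0, 1, 10), c(2, 0, 8))
  for (e0 in list(c(1, 0, 0), c(0, 1, 0))) {
    p <- solve(A, rep(e0, 2) + 0i)
    p1 <- p[1:3]; p2 <- p[4:6]
    oracle <- vapply(seq_len(nrow(pts)), function(i) {
      fld <- function(pv, cen) {
        d <- pts[i, ] - cen; r <- sqrt(sum(d^2)); n <- d / r
        (3 * n * sum(n * pv) - pv) / r^3
      }
      E <- e0 + fld(p1, c(-pitch / 2, 0, 0)) + fld(p2, c(pitch / 2, 0, 0))
      sum(Mod(E)^2)
    }, numeric(1))
    pol <- if (e0[1] == 1) "x" else "y"
    expect_equal(compute_near_field(dimer, 561, pts, polarization = pol),
                 oracle, tolerance = 1e-12)
  }
})

test_that("gap coupling enhances the field beyond the isolated sphere", {
  au <- fx_material()
  pitch <- 15.2
  dimer <- nanoparticle_sheet(material = au,
                              positions = rbind(c(-pitch / 2, 0, 0),
                                                c(pitch / 2, 0, 0)))
  # gap midpoint is 1.3 nm from both surfaces; compare with a point 1.3 nm
  # from an isolated sphere along the polarization axis
  gap <- compute_near_field(dimer, 561, c(0, 0, 0), polarization = "x")
  single <- single_sphere_enhancement(au, 6.3, 561, c(7.6, 0, 0))
  expect_gt(gap, single)
})

test_that("sheet near field respects lattice symmetry and the far-field limit", {
  sheet <- fx_sheet(); sol <- fx_solution()
  # mirror-equivalent points give equal intensity
  pts <- rbind(c(3, 2, 5), c(-3, 2, 5), c(3, -2, 5), c(-3, -2, 5))
  I <- compute_near_field(sheet, 561, pts, solution = sol)
  expect_equal(I, rep(I[1], 4), tolerance = 1e-9)
  # both half-spaces are equivalent
  expect_equal(compute_near_field(sheet, 561, rbind(c(0, 0, 9), c(0, 0, -9)),
                                  solution = sol),
               rep(compute_near_field(sheet, 561, c(0, 0, 9), solution = sol), 2),
               tolerance = 1e-9)
  # distance much larger than the pitch: intensity returns to the incident one
  expect_equal(compute_near_field(sheet, 561, c(0, 0, 500), solution = sol),
               1, tolerance = 0.05)
  expect_error(compute_near_field(sheet, 561, c(7.6, 0, 1), solution = sol),
               "inside a particle core")
})

test_that("plasmonic profile decays on the particle-radius scale", {
  sheet <- fx_sheet(); sol <- fx_solution()
  probe <- probe_line(sheet, D_grid = c(0.5, 1, 5, 3 * 12.6, 200))
  prof <- lspr_profile(sheet, 561, probe, solution = sol)
  expect_equal(unique(prof$label), "lspr")
  # at three core diameters the field is back to within 10% of incident
  expect_equal(prof$relative_intensity[prof$distance_nm == 3 * 12.6], 1,
               tolerance = 0.10)
  expect_equal(prof$relative_intensity[prof$distance_nm == 200], 1,
               tolerance = 0.05)
  # enhancement near the gap dwarfs the far field
  expect_gt(prof$relative_intensity[1], 50)
})

test_that("profile statistics converge with patch size", {
  stats21 <- fx_profile_stats()
  sheet25 <- nanoparticle_sheet(n_rows = 25, n_cols = 25,
                                material = fx_material())
  stats25 <- lspr_profile_summary(sheet25, 561)
  expect_equal(stats21$peak_intensity, stats25$peak_intensity,
               tolerance = 0.05)
  expect_equal(stats21$peak_distance_nm, stats25$peak_distance_nm,
               tolerance = 0.5)
  # the shallow unity crossing is the most patch-sensitive statistic; it
  # stays within a few nm between successive patch sizes
  expect_lt(abs(stats21$unity_crossing_nm - stats25$unity_crossing_nm), 3)
})
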