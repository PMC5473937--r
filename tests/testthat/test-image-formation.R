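test_that("excitation weights implement each modality's depth response", {
  pop <- interior_population(100)
  # homogeneous modalities
  expect_equal(excitation_weights(pop, imaging_setup("epi")), rep(1, 100))
  ob <- imaging_setup("oblique",
                      interface = interface_config(561, 1.52, 1.33, 55))
  expect_equal(excitation_weights(pop, ob), rep(1, 100))
  # evanescent decay at the penetration depth
  iface <- interface_config(561, 1.52, 1.33, 65)
  d <- penetration_depth(iface)  # ~124.4 nm
  pop$z_nm <- c(0, d, 2 * d, 500, rep(100, 96))
  w <- excitation_weights(pop, imaging_setup("tirf", interface = iface))
  expect_equal(w[1:3], c(1, exp(-1), exp(-2)))
  # a dorsal fluorophore 500 nm up is ~e^-4 ~ 2% excited
  expect_equal(w[4], exp(-500 / d), tolerance = 1e-10)
  expect_equal(w[4], 0.018, tolerance = 0.03)
  # sub-critical tirf is redirected to oblique, and vice versa
  expect_error(
    excitation_weights(pop, imaging_setup(
      "tirf", interface = interface_config(561, 1.52, 1.33, 55))),
    "oblique")
  expect_error(
    excitation_weights(pop, imaging_setup(
      "oblique", interface = interface_config(561, 1.52, 1.33, 75))),
    "tirf")
})

test_that("sheet excitation weights are surface-bound", {
  pop <- interior_population(60, z_range = c(0, 600))
  pop$z_nm <- seq(0, 590, by = 10)
  su <- imaging_setup("lspr_sheet", sheet = fx_sheet(),
                      transfer_model = energy_transfer_model(5, 4))
  w <- excitation_weights(pop, su, excitation_table = fx_excitation_table())
  # beyond the quenching zone the weight decays monotonically with height;
  # within a few nm of contact energy transfer carves a quenching valley,
  # so monotonicity is only asserted from 20 nm up
  tail_w <- w[pop$z_nm >= 20]
  expect_true(all(diff(tail_w) < 0))
  # a dorsal-height fluorophore sees orders of magnitude less excitation
  expect_lt(w[pop$z_nm == 500] / w[pop$z_nm == 20], 1e-3)
  # all weights are finite and non-negative
  expect_true(all(is.finite(w) & w >= 0))
})

test_that("rendering conserves photons and centers the point response", {
  pop <- interior_population(150)
  su <- imaging_setup("epi", field_of_view_px = 128, pixel_size_nm = 65)
  w <- rep(1, nrow(pop))
  img <- render_image(pop, w, su, noise = FALSE)
  total_expected <- sum(pop$brightness * w * su$exposure)
  expect_lt(abs(sum(img) - total_expected) / total_expected, 1e-6)
  # one emitter exactly at a pixel center -> argmax at that pixel
  one <- pop[1, ]; one$x_nm <- 10.5 * 65 - 64 * 65; one$y_nm <- 20.5 * 65 - 64 * 65
  class(one) <- class(pop)
  img1 <- render_image(one, 1, su, noise = FALSE)
  peak <- which(img1 == max(img1), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(21, 11))  # row = y, col = x, 1-based
  expect_error(render_image(pop[0, ], numeric(0), su), "empty population")
  expect_error(render_image(pop, w[-1], su), "align")
})

test_that("noisy renders average to the noiseless expectation", {
  pop <- interior_population(25, extent_nm = 700)
  su0 <- imaging_setup("epi", field_of_view_px = 32, pixel_size_nm = 65,
                       read_noise = 1.5)
  clean <- render_image(pop, rep(1, 25), su0, noise = FALSE)
  n_rep <- 200
  acc <- matrix(0, 32, 32)
  for (s in seq_len(n_rep)) {
    su <- imaging_setup("epi", field_of_view_px = 32, pixel_size_nm = 65,
                        read_noise = 1.5, rng_seed = 1000 + s)
    acc <- acc + unclass(render_image(pop, rep(1, 25), su))
  }
  m <- acc / n_rep
  # zero-clipping biases near-empty pixels upward, so mean consistency is
  # asserted on pixels carrying real signal (>= 10 expected counts)
  bright <- clean >= 10
  expect_gt(sum(bright), 50)
  se_total <- sqrt(sum(clean[bright] + 1.5^2)) / sqrt(n_rep)
  expect_lt(abs(sum(m[bright]) - sum(clean[bright])), 3 * se_total)
  # per-pixel deviations behave like shot + read noise (few > 3 se)
  se_px <- sqrt(clean + 1.5^2) / sqrt(n_rep)
  expect_lt(mean((abs(m - clean) > 3 * se_px)[bright]), 0.02)
  # determinism: the same seed reproduces the identical frame
  su <- imaging_setup("epi", field_of_view_px = 32, pixel_size_nm = 65,
                      rng_seed = 5)
  expect_identical(unclass(render_image(pop, rep(1, 25), su)),
                   unclass(render_image(pop, rep(1, 25), su)))
})

test_that("finer camera sampling improves the measured PSF width", {
  one <- interior_population(1)
  one$brightness <- 1e4
  fwhm_from_image <- function(pixel_size_nm) {
    su <- imaging_setup("epi", field_of_view_px = 64,
                        pixel_size_nm = pixel_size_nm)
    # place the emitter at a pixel center so the sampled profile is symmetric
    one$x_nm <- 0.5 * pixel_size_nm; one$y_nm <- 0.5 * pixel_size_nm
    img <- unclass(render_image(one, 1, su, noise = FALSE))
    pk <- which(img == max(img), arr.ind = TRUE)
    prof <- img[pk[1, 1], ]
    half <- max(prof) / 2
    above <- range(which(prof >= half))
    # linear interpolation at the two half-maximum crossings
    lo <- above[1]; hi <- above[2]
    f_lo <- lo - 1 + (prof[lo - 1] - half) / (prof[lo - 1] - prof[lo])
    f_hi <- hi + (prof[hi] - half) / (prof[hi] - prof[hi + 1])
    (f_hi - f_lo) * pixel_size_nm
  }
  su <- imaging_setup("epi")
  sigma_nm <- su$psf_k * su$emission_wavelength_nm / su$numerical_aperture
  fwhm_true <- 2 * sqrt(2 * log(2)) * sigma_nm
  err65 <- abs(fwhm_from_image(65) - fwhm_true)
  err160 <- abs(fwhm_from_image(160) - fwhm_true)
  expect_lt(err65, err160)
  expect_lt(err65 / fwhm_true, 0.05)
  # total photons are unchanged by resampling
  one$x_nm <- 0; one$y_nm <- 0
  su65 <- imaging_setup("epi", field_of_view_px = 128, pixel_size_nm = 65)
  su160 <- imaging_setup("epi", field_of_view_px = 52, pixel_size_nm = 160)
  expect_equal(sum(render_image(one, 1, su65, noise = FALSE)),
               sum(render_image(one, 1, su160, noise = FALSE)),
               tolerance = 1e-6)
})

test_that("undersampled PSF triggers the warning contract", {
  one <- interior_population(1)
  su <- imaging_setup("epi", pixel_size_nm = 2000, field_of_view_px = 16)
  expect_warning(render_image(one, 1, su, noise = FALSE), "undersampled")
})

test_that("ventral fraction summarizes axial selectivity", {
  pop <- interior_population(400)
  w1 <- rep(1, 400)
  # homogeneous excitation: the fraction is the count fraction
  expect_equal(ventral_fraction(pop, w1), mean(pop$tag == "ventral"))
  # evanescent weighting favors the bottom
  iface <- interface_config(561, 1.52, 1.33, 75)
  wt <- excitation_weights(pop, imaging_setup("tirf", interface = iface))
  expect_gt(ventral_fraction(pop, wt), ventral_fraction(pop, w1))
  top_only <- pop[pop$tag == "dorsal", ]
  class(top_only) <- class(pop)
  expect_error(ventral_fraction(top_only, rep(1, nrow(top_only))),
               "no ventral")
  bottom_only <- pop[pop$tag == "ventral", ]
  class(bottom_only) <- class(pop)
  expect_error(ventral_fraction(bottom_only, rep(1, nrow(bottom_only))),
               "no dorsal")
})

test_that("signal-to-background ratio behaves as a contrast metric", {
  img <- matrix(5, 40, 40)
  mask <- matrix(FALSE, 40, 40); mask[10:20, 10:20] <- TRUE
  # constant image -> zero contrast
  expect_equal(signal_to_background(img, mask), 0)
  # add noise outside, signal inside
  img2 <- img + withr::with_seed(1, matrix(rnorm(1600, 0, 1), 40, 40))
  img3 <- img2; img3[mask] <- img3[mask] + 10
  r1 <- signal_to_background(img3, mask)
  img4 <- img2; img4[mask] <- img4[mask] + 20
  expect_gt(signal_to_background(img4, mask), r1)
  expect_error(signal_to_background(img, matrix(TRUE, 40, 40)), "full frame")
  expect_error(signal_to_background(img, matrix(FALSE, 40, 40)), "non-empty")
})

test_that("modality comparison reports identical rows for identical setups", {
  pop <- interior_population(300)
  mask <- matrix(FALSE, 64, 64); mask[20:40, 20:40] <- TRUE
  su <- imaging_setup("epi", field_of_view_px = 64, rng_seed = 9)
  rep2 <- compare_modalities(pop, list(a = su, b = su), mask = mask)
  expect_equal(rep2$ventral_fraction[1], rep2$ventral_fraction[2])
  expect_equal(rep2$sbr[1], rep2$sbr[2])
})
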