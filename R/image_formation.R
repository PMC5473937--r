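# Camera image formation: per-fluorophore excitation weights for each
# illumination modality, Gaussian-PSF rendering with Poisson shot noise and
# read noise, and the contrast metrics used to compare modalities.

#' Imaging setup
#'
#' Describes one acquisition: the illumination modality and its optics, the
#' detection path (emission wavelength, numerical aperture, pixel size,
#' field of view) and the noise model.
#'
#' Modalities: `"epi"` (homogeneous excitation), `"oblique"` (sub-critical
#' inclined illumination, modeled as homogeneous excitation with an optional
#' elevated `background`), `"tirf"` (evanescent excitation, requires an
#' `interface` above the critical angle), and `"lspr_sheet"` (excitation by
#' the surface-bound plasmonic near field of a nanoparticle `sheet`,
#' attenuated by energy transfer per `transfer_model`).
#'
#' For `lspr_sheet` the fluorophore height z (measured from the substrate
#' top surface) maps to a distance `z + radius + capping_nm + spacer_nm`
#' from the plane of particle centers; the excitation weight is the lateral
#' unit-cell average of the bound (scattered) near-field intensity times the
#' energy-transfer attenuation at that height, because the sub-pixel lattice
#' structure (15.2 nm pitch versus >= 65 nm pixels) is not resolved.  The
#' uniform transmitted beam can be added back via `transmitted_fraction`.
#'
#' @param modality One of `"epi"`, `"oblique"`, `"tirf"`, `"lspr_sheet"`.
#' @param interface An [interface_config()]; required for `tirf`, optional
#'   for `oblique`.
#' @param sheet A [nanoparticle_sheet()]; required for `lspr_sheet`.
#' @param transfer_model An [energy_transfer_model()]; required for
#'   `lspr_sheet`.
#' @param spacer_nm Dielectric spacer thickness on top of the sheet (nm).
#' @param capping_nm Thickness of the organic capping layer separating a
#'   fluorophore at z = 0 from the gold surface (nm); half the interparticle
#'   gap by default.
#' @param transmitted_fraction Weight of the uniform transmitted-beam
#'   excitation added to the bound-field weight in `lspr_sheet` mode.
#' @param theta_deg Illumination angle bookkeeping for `epi`/`lspr_sheet`
#'   reports (the angle enters `tirf`/`oblique` through `interface`).
#' @param emission_wavelength_nm Emission wavelength (nm).
#' @param numerical_aperture Objective NA; must not exceed `n1` of the
#'   interface when one is given.
#' @param pixel_size_nm Camera pixel size in sample space (160 or 65 nm for
#'   the two cameras modeled, but any positive value is accepted).
#' @param field_of_view_px Image width/height in pixels.
#' @param exposure Exposure scale multiplying expected photons.
#' @param read_noise Additive Gaussian read noise (counts rms).
#' @param background Uniform expected background photons per pixel at unit
#'   exposure.
#' @param emission_gain Scalar emission-side enhancement factor for
#'   `lspr_sheet` (default 1).
#' @param psf_k PSF width factor: the Gaussian sd is
#'   `psf_k * emission_wavelength_nm / numerical_aperture` (0.21
#'   approximates the Airy core).
#' @param rng_seed Integer seed for the noise draws.
#'
#' @return An object of class `imaging_setup`.
#' @export
imaging_setup <- function(modality = c("epi", "oblique", "tirf", "lspr_sheet"),
                          interface = NULL, sheet = NULL,
                          transfer_model = NULL, spacer_nm = 0,
                          capping_nm = 1.3, transmitted_fraction = 0,
                          theta_deg = NULL,
                          emission_wavelength_nm = 580,
                          numerical_aperture = 1.49,
                          pixel_size_nm = 65, field_of_view_px = 256,
                          exposure = 1, read_noise = 1.5, background = 0,
                          emission_gain = 1, psf_k = 0.21, rng_seed = 1L) {
  modality <- match.arg(modality)
  assert_scalar_num(pixel_size_nm, "pixel_size_nm", 0, strict_lower = TRUE)
  assert_scalar_num(numerical_aperture, "numerical_aperture", 0,
                    strict_lower = TRUE)
  assert_scalar_num(spacer_nm, "spacer_nm", 0)
  assert_scalar_num(capping_nm, "capping_nm", 0)
  if (modality == "tirf" && is.null(interface))
    stopf("`tirf` requires an `interface` configuration")
  if (modality == "lspr_sheet" && (is.null(sheet) || is.null(transfer_model)))
    stopf("`lspr_sheet` requires `sheet` and `transfer_model`")
  if (!is.null(interface)) {
    stopifnot(inherits(interface, "interface_config"))
    if (numerical_aperture > interface$n1)
      stopf("numerical aperture exceeds the immersion index n1 = %g",
            interface$n1)
  }
  if (is.null(theta_deg))
    theta_deg <- if (!is.null(interface)) interface$theta_deg else 0
  structure(
    list(modality = modality, interface = interface, sheet = sheet,
         transfer_model = transfer_model, spacer_nm = spacer_nm,
         capping_nm = capping_nm, transmitted_fraction = transmitted_fraction,
         theta_deg = theta_deg,
         emission_wavelength_nm = emission_wavelength_nm,
         numerical_aperture = numerical_aperture,
         pixel_size_nm = pixel_size_nm,
         field_of_view_px = as.integer(field_of_view_px),
         exposure = exposure, read_noise = read_noise,
         background = background, emission_gain = emission_gain,
         psf_k = psf_k, rng_seed = as.integer(rng_seed)),
    class = "imaging_setup"
  )
}

#' Laterally averaged sheet excitation versus height
#'
#' Solves the coupled-dipole system once and tabulates, at each height D
#' above the plane of particle centers, the lateral unit-cell averages of
#' the total relative intensity, the bound (scattered) intensity, the
#' energy-transfer attenuation, and their products.  The table is the
#' height-response function of the `lspr_sheet` modality.
#'
#' @param sheet A [nanoparticle_sheet()].
#' @param wavelength_nm Excitation wavelength (nm).
#' @param transfer_model An [energy_transfer_model()].
#' @param heights_nm Heights D above the center plane (nm); must clear the
#'   particle surfaces (D > radius).
#' @param n_lateral Lateral sample points per pitch (the unit-cell grid is
#'   `n_lateral x round(sqrt(3) * n_lateral)`).
#' @param solution Optional precomputed [sheet_solution()].
#'
#' @return Data frame with columns `height_nm`, `mean_total`,
#'   `mean_scattered`, `mean_attenuation`, `excitation_bound`
#'   (mean of scattered x attenuation), `excitation_total`.
#' @export
sheet_excitation_table <- function(sheet, wavelength_nm, transfer_model,
                                   heights_nm, n_lateral = 8,
                                   solution = NULL) {
  stopifnot(inherits(sheet, "nanoparticle_sheet"))
  if (any(heights_nm <= sheet$radius_nm))
    stopf("heights must be above the particle tops (> %g nm)", sheet$radius_nm)
  if (is.null(solution)) solution <- sheet_solution(sheet, wavelength_nm)
  p <- sheet$pitch_nm
  xs <- seq(-p / 2, p / 2, length.out = n_lateral + 1)[-(n_lateral + 1)]
  ny <- max(2L, round(sqrt(3) * n_lateral))
  ys <- seq(-sqrt(3) * p / 2, sqrt(3) * p / 2, length.out = ny + 1)[-(ny + 1)]
  lat <- expand.grid(x = xs, y = ys)
  out <- lapply(heights_nm, function(h) {
    pts <- cbind(lat$x, lat$y, h)
    It <- compute_near_field(sheet, wavelength_nm, pts, solution = solution)
    Is <- compute_near_field(sheet, wavelength_nm, pts,
                             component = "scattered", solution = solution)
    att <- set_attenuation(transfer_model, nearest_surface_distance(sheet, pts))
    c(mean(It), mean(Is), mean(att), mean(Is * att), mean(It * att))
  })
  out <- do.call(rbind, out)
  data.frame(height_nm = heights_nm, mean_total = out[, 1],
             mean_scattered = out[, 2], mean_attenuation = out[, 3],
             excitation_bound = out[, 4], excitation_total = out[, 5])
}

# Interpolate a positive, rapidly decaying excitation table in log space.
interp_log <- function(x, y, xout) {
  y <- pmax(y, 1e-300)
  exp(approx(x, log(y), xout, rule = 2)$y)
}

#' Per-fluorophore excitation weights
#'
#' Relative excitation intensity experienced by each fluorophore of a
#' population under a given setup: 1 for `epi` and `oblique` (homogeneous
#' illumination), `exp(-z/d)` for `tirf`, and the laterally averaged bound
#' plasmonic field times energy-transfer attenuation for `lspr_sheet`
#' (plus `transmitted_fraction`).
#'
#' @param pop A `fluor_population` (z >= 0 for all fluorophores).
#' @param setup An [imaging_setup()].
#' @param excitation_wavelength_nm Excitation wavelength used by the
#'   `lspr_sheet` near-field solve; for `tirf` the wavelength comes from
#'   `setup$interface`.
#' @param excitation_table Optional precomputed [sheet_excitation_table()]
#'   covering the population's height range (reused across angles, which do
#'   not affect the substrate-bound field).
#'
#' @return Numeric vector of weights, one per fluorophore.
#' @export
excitation_weights <- function(pop, setup, excitation_wavelength_nm = 561,
                               excitation_table = NULL) {
  stopifnot(inherits(pop, "fluor_population"), inherits(setup, "imaging_setup"))
  if (nrow(pop) == 0) stopf("empty population")
  if (any(pop$z_nm < 0)) stopf("population has z < 0")
  switch(setup$modality,
    epi = rep(1, nrow(pop)),
    oblique = {
      if (!is.null(setup$interface) && setup$interface$n2 < setup$interface$n1) {
        thc <- critical_angle(setup$interface$n1, setup$interface$n2)
        if (setup$interface$theta_deg > thc)
          stopf("oblique setup is above the critical angle; use modality = 'tirf'")
      }
      rep(1, nrow(pop))
    },
    tirf = {
      thc <- critical_angle(setup$interface$n1, setup$interface$n2)
      if (setup$interface$theta_deg <= thc)
        stopf(paste0("tirf requested below the critical angle (%.2f deg); ",
                     "use modality = 'oblique' for sub-critical illumination"),
              thc)
      exp(-pop$z_nm / penetration_depth(setup$interface))
    },
    lspr_sheet = {
      offset <- setup$sheet$radius_nm + setup$capping_nm + setup$spacer_nm
      D <- pop$z_nm + offset
      if (is.null(excitation_table)) {
        hmax <- max(D) * 1.01
        heights <- unique(sort(c(
          seq(min(D) * 0.99, min(60, hmax), length.out = 40),
          if (hmax > 60) exp(seq(log(60), log(hmax), length.out = 25)))))
        excitation_table <- sheet_excitation_table(
          setup$sheet, excitation_wavelength_nm, setup$transfer_model, heights)
      }
      w <- interp_log(excitation_table$height_nm,
                      excitation_table$excitation_bound, D)
      w + setup$transmitted_fraction
    })
}

#' Render a camera image of a fluorophore population
#'
#' Each fluorophore contributes `brightness x weight x exposure` expected
#' photons, spread over pixels by an integrated 2D Gaussian PSF of sd
#' `psf_k * lambda_em / NA`; expected counts then receive Poisson shot
#' noise, Gaussian read noise, rounding and 16-bit saturation.  Noise-free
#' rendering conserves photons (up to the 6-sigma kernel truncation and any
#' emitter close to the field edge).
#'
#' @param pop A `fluor_population` centered on the field of view (the image
#'   is centered at x = y = 0).
#' @param weights Excitation weights aligned with `pop`.
#' @param setup An [imaging_setup()].
#' @param noise Apply shot/read noise?  `FALSE` returns the real-valued
#'   expected image.
#'
#' @return A `synthetic_image`: a `field_of_view_px`-square numeric matrix
#'   (rows = y, columns = x) with a `metadata` attribute.
#' @export
render_image <- function(pop, weights, setup, noise = TRUE) {
  stopifnot(inherits(pop, "fluor_population"), inherits(setup, "imaging_setup"))
  if (nrow(pop) == 0) stopf("empty population")
  if (length(weights) != nrow(pop))
    stopf("`weights` must align with the population (%d vs %d)",
          length(weights), nrow(pop))
  npx <- setup$field_of_view_px
  sigma_nm <- setup$psf_k * setup$emission_wavelength_nm / setup$numerical_aperture
  sigma_px <- sigma_nm / setup$pixel_size_nm
  if (sigma_px < 0.1)
    warning("PSF sd below 0.1 pixel: the image is undersampled", call. = FALSE)
  photons <- pop$brightness * weights * setup$exposure * setup$emission_gain
  # continuous pixel coordinates: pixel k covers [k-1, k) so the field is
  # centered at npx/2
  cx <- pop$x_nm / setup$pixel_size_nm + npx / 2
  cy <- pop$y_nm / setup$pixel_size_nm + npx / 2
  hw <- ceiling(6 * sigma_px) + 1L
  w <- 2L * hw + 1L
  n <- nrow(pop)
  # per-emitter 1D pixel masses from the integrated Gaussian
  edges <- 0:w - hw  # pixel boundaries relative to floor(center)
  mass_1d <- function(cc) {
    fr <- cc - floor(cc)
    M <- pnorm((matrix(edges, n, w + 1, byrow = TRUE) - fr) / sigma_px)
    M[, -1, drop = FALSE] - M[, -(w + 1), drop = FALSE]
  }
  mx <- mass_1d(cx)
  my <- mass_1d(cy)
  ix0 <- floor(cx) - hw
  iy0 <- floor(cy) - hw
  img <- matrix(0, npx, npx)
  for (i in seq_len(n)) {
    cols <- (ix0[i] + 1):(ix0[i] + w)  # 1-based pixel indices (x -> columns)
    rows <- (iy0[i] + 1):(iy0[i] + w)
    okc <- cols >= 1 & cols <= npx
    okr <- rows >= 1 & rows <= npx
    if (!any(okc) || !any(okr)) next
    img[rows[okr], cols[okc]] <- img[rows[okr], cols[okc]] +
      photons[i] * outer(my[i, okr], mx[i, okc])
  }
  img <- img + setup$background * setup$exposure
  if (noise) {
    img <- withr::with_seed(setup$rng_seed, {
      counts <- matrix(rpois(length(img), img), npx, npx)
      counts + matrix(round(rnorm(length(img), 0, setup$read_noise)), npx, npx)
    })
    img <- pmin(pmax(img, 0), 65535)
  }
  structure(img, class = c("synthetic_image", "matrix", "array"),
            metadata = list(modality = setup$modality,
                            theta_deg = setup$theta_deg,
                            pixel_size_nm = setup$pixel_size_nm,
                            noise = noise, rng_seed = setup$rng_seed))
}

#' Write a synthetic image as 16-bit grayscale TIFF
#'
#' @param image A `synthetic_image` (or numeric matrix of counts) or, for
#'   `write_mask()`, a logical matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(image, path) {
  m <- pmin(pmax(unclass(image), 0), 65535) / 65535
  tiff::writeTIFF(m, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
write_mask_tiff <- function(image, path) {
  tiff::writeTIFF(matrix(as.numeric(image), nrow(image)), path,
                  bits.per.sample = 8L, compression = "none")
  invisible(path)
}

#' Fraction of excitation reaching substrate-proximal structures
#'
#' Sum of excitation weights over the substrate-proximal tags (`ventral`,
#' `adhesion`, `fiber`) divided by the sum over all fluorophores: the
#' axial-selectivity metric of a modality.
#'
#' @param pop A `fluor_population` containing at least one
#'   ventral-or-adhesion-tagged and one dorsal-tagged fluorophore.
#' @param weights Excitation weights aligned with `pop`.
#' @param bottom_tags Tags counted as substrate-proximal.
#'
#' @return A number in (0, 1).
#' @export
ventral_fraction <- function(pop, weights,
                             bottom_tags = c("ventral", "adhesion", "fiber")) {
  stopifnot(inherits(pop, "fluor_population"))
  if (length(weights) != nrow(pop)) stopf("`weights` must align with `pop`")
  bottom <- pop$tag %in% bottom_tags
  if (!any(pop$tag %in% c("ventral", "adhesion")))
    stopf("population has no ventral- or adhesion-tagged fluorophores")
  if (!any(pop$tag == "dorsal"))
    stopf("population has no dorsal-tagged fluorophores")
  sum(weights[bottom]) / sum(weights)
}

#' Signal-to-background ratio of an image
#'
#' `(mean inside mask - mean outside mask) / sd outside mask`.  A constant
#' image gives 0.
#'
#' @param image Numeric matrix (a rendered image).
#' @param mask Logical matrix of the same dimensions marking the structure
#'   pixels; must be non-empty and not cover the whole frame.
#'
#' @return The ratio (dimensionless).
#' @export
signal_to_background <- function(image, mask) {
  image <- unclass(image)
  if (!is.logical(mask) || !all(dim(mask) == dim(image)))
    stopf("`mask` must be a logical matrix matching the image")
  if (!any(mask) || all(mask))
    stopf("`mask` must be non-empty and not cover the full frame")
  m_in <- mean(image[mask])
  m_out <- mean(image[!mask])
  s_out <- sd(image[!mask])
  if (s_out == 0) {
    if (m_in == m_out) return(0)
    stopf("zero out-of-mask variance: background statistics undefined")
  }
  (m_in - m_out) / s_out
}

#' Ground-truth structure mask
#'
#' Marks the pixels covered by selected structures (by default the focal
#' adhesions and stress fibers), dilated by a disk to account for the PSF
#' footprint.  Used as the in-mask region for [signal_to_background()].
#'
#' @param pop A `fluor_population`.
#' @param setup An [imaging_setup()] supplying pixel grid geometry.
#' @param tags Structure tags to include.
#' @param dilation_nm Dilation radius in nm.
#'
#' @return A logical `field_of_view_px`-square matrix.
#' @export
structure_mask <- function(pop, setup, tags = c("adhesion", "fiber"),
                           dilation_nm = 200) {
  npx <- setup$field_of_view_px
  sel <- pop$tag %in% tags
  if (!any(sel)) stopf("no fluorophores with the requested tags")
  px <- floor(pop$x_nm[sel] / setup$pixel_size_nm + npx / 2) + 1L
  py <- floor(pop$y_nm[sel] / setup$pixel_size_nm + npx / 2) + 1L
  ok <- px >= 1 & px <= npx & py >= 1 & py <= npx
  mask <- matrix(FALSE, npx, npx)
  mask[cbind(py[ok], px[ok])] <- TRUE
  r <- max(0L, round(dilation_nm / setup$pixel_size_nm))
  if (r > 0) {
    marked <- which(mask, arr.ind = TRUE)
    off <- expand.grid(dy = -r:r, dx = -r:r)
    off <- off[off$dx^2 + off$dy^2 <= r^2, ]
    out <- matrix(FALSE, npx, npx)
    for (k in seq_len(nrow(off))) {
      ry <- marked[, 1] + off$dy[k]
      rx <- marked[, 2] + off$dx[k]
      keep <- ry >= 1 & ry <= npx & rx >= 1 & rx <= npx
      out[cbind(ry[keep], rx[keep])] <- TRUE
    }
    mask <- out
  }
  mask
}

#' Compare illumination modalities on one population
#'
#' Computes, for each setup, the excitation weights, a rendered image, the
#' ventral fraction and the signal-to-background ratio, and evaluates the
#' qualitative orderings expected of a surface-confined excitation:
#' sheet-modality metrics should be (nearly) independent of the
#' illumination angle while glass-substrate metrics change strongly between
#' sub- and super-critical angles.
#'
#' @param pop A `fluor_population`.
#' @param setups Named list of [imaging_setup()]s.
#' @param mask Optional logical mask for [signal_to_background()]; computed
#'   from the population's adhesions and fibers by default.
#' @param excitation_wavelength_nm Excitation wavelength for sheet solves.
#' @param angle_tolerance Maximum relative spread of sheet-modality metrics
#'   across angles for the angle-independence flag.
#' @param glass_ratio Minimum max/min ventral-fraction ratio across glass
#'   setups for the angle-dependence flag.
#'
#' @return A `modality_report`: a data frame with one row per setup
#'   (columns `name`, `modality`, `theta_deg`, `ventral_fraction`, `sbr`)
#'   with an `orderings` attribute holding the boolean checks.
#' @export
compare_modalities <- function(pop, setups, mask = NULL,
                               excitation_wavelength_nm = 561,
                               angle_tolerance = 0.05, glass_ratio = 2) {
  stopifnot(length(setups) >= 2)
  if (is.null(names(setups)) || any(names(setups) == ""))
    names(setups) <- paste0(vapply(setups, `[[`, "", "modality"),
                            "_", seq_along(setups))
  if (is.null(mask)) mask <- structure_mask(pop, setups[[1]])
  # the bound near field does not depend on the illumination angle, so one
  # excitation table per (sheet, spacer) serves every lspr setup
  tables <- list()
  rows <- lapply(names(setups), function(nm) {
    s <- setups[[nm]]
    tab <- NULL
    if (s$modality == "lspr_sheet") {
      key <- sprintf("%d_%g_%g", s$sheet$n_particles, s$spacer_nm,
                     s$transfer_model$characteristic_distance_nm)
      if (is.null(tables[[key]])) {
        offset <- s$sheet$radius_nm + s$capping_nm + s$spacer_nm
        D <- pop$z_nm + offset
        hmax <- max(D) * 1.01
        heights <- unique(sort(c(
          seq(min(D) * 0.99, min(60, hmax), length.out = 40),
          if (hmax > 60) exp(seq(log(60), log(hmax), length.out = 25)))))
        tables[[key]] <<- sheet_excitation_table(
          s$sheet, excitation_wavelength_nm, s$transfer_model, heights)
      }
      tab <- tables[[key]]
    }
    w <- excitation_weights(pop, s, excitation_wavelength_nm, tab)
    img <- render_image(pop, w, s)
    data.frame(name = nm, modality = s$modality, theta_deg = s$theta_deg,
               ventral_fraction = ventral_fraction(pop, w),
               sbr = signal_to_background(img, mask))
  })
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  rel_spread <- function(x) if (length(x) < 2) 0 else diff(range(x)) / max(x)
  sheet_rows <- report$modality == "lspr_sheet"
  glass_rows <- !sheet_rows
  orderings <- list(
    lspr_angle_independent =
      sum(sheet_rows) >= 2 &&
      rel_spread(report$ventral_fraction[sheet_rows]) < angle_tolerance &&
      rel_spread(report$sbr[sheet_rows]) < angle_tolerance,
    glass_angle_dependent =
      sum(glass_rows) >= 2 &&
      max(report$ventral_fraction[glass_rows]) /
        min(report$ventral_fraction[glass_rows]) > glass_ratio,
    lspr_spread_vf = rel_spread(report$ventral_fraction[sheet_rows]),
    glass_vf_ratio = if (any(glass_rows))
      max(report$ventral_fraction[glass_rows]) /
        min(report$ventral_fraction[glass_rows]) else NA_real_)
  structure(report, orderings = orderings,
            class = c("modality_report", "data.frame"))
}

#' @export
print.modality_report <- function(x, ...) {
  cat("Modality comparison:\n")
  print.data.frame(x, digits = 4)
  o <- attr(x, "orderings")
  cat(sprintf("sheet metrics angle-independent: %s (vf spread %.2g)\n",
              o$lspr_angle_independent, o$lspr_spread_vf))
  cat(sprintf("glass metrics angle-dependent:   %s (vf ratio %.3g)\n",
              o$glass_angle_dependent, o$glass_vf_ratio))
  invisible(x)
}
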