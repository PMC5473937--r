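# Synthetic fluorophore populations emulating a fixed, actin-labeled
# adherent cell: a thin ventral actin layer with stress fibers and focal
# adhesions close to the substrate, and a dorsal actin layer a few hundred
# nanometers up.  z is measured from the top surface of the imaging
# substrate, positive into the sample.

#' Parameters of the synthetic adherent cell
#'
#' Defaults describe a ~12 um round adherent cell whose substrate-proximal
#' ("ventral") actin sits within a few tens of nm of the surface, with focal
#' adhesions concentrated at the cell edge and center, and a dorsal actin
#' layer 300-600 nm up.  Absolute z positions of real cells are not pinned
#' down by interface imaging alone, so every value is overridable.
#'
#' @param footprint_radius_nm Radius of the adhesion footprint (nm).
#' @param ventral_z_range_nm Height range of the ventral actin layer (nm).
#' @param dorsal_z_range_nm Height range of the dorsal actin layer (nm).
#' @param n_stress_fibers Number of ventral stress fibers (chords across the
#'   footprint).
#' @param fiber_width_nm Full width of a stress fiber (nm); labels scatter
#'   laterally with a Gaussian of sd `fiber_width_nm / 4`.
#' @param n_focal_adhesions Number of focal-adhesion spots.
#' @param adhesion_z_range_nm Height range of adhesion labels (nm); the
#'   "nano-contacting" region a few tens of nm from the substrate.
#' @param adhesion_radius_nm Lateral Gaussian radius of an adhesion spot.
#' @param adhesion_edge_fraction Fraction of adhesions placed at the
#'   footprint rim (the rest near the center), matching the rim-and-center
#'   localization seen in interface images of adherent cells.
#' @param ventral_density_um2,dorsal_density_um2 Expected labels per um^2 of
#'   footprint in the two layers.  The dorsal default exceeds the ventral
#'   one because the 300 nm-thick dorsal slab integrates cortical plus
#'   cytoplasmic actin, which is what buries the interface in wide-field
#'   images.
#' @param fiber_labels_per_um Expected labels per um of stress-fiber length.
#' @param adhesion_labels Expected labels per adhesion spot.
#' @param brightness_mean Mean expected photons per fluorophore at unit
#'   excitation and unit exposure.
#' @param brightness_sdlog Log-normal spread of per-fluorophore brightness.
#' @param rng_seed Integer seed fixing all randomness of the generator.
#'
#' @return An object of class `cell_geometry_params`.
#' @export
cell_geometry_params <- function(footprint_radius_nm = 6000,
                                 ventral_z_range_nm = c(5, 50),
                                 dorsal_z_range_nm = c(300, 600),
                                 n_stress_fibers = 8,
                                 fiber_width_nm = 150,
                                 n_focal_adhesions = 30,
                                 adhesion_z_range_nm = c(5, 30),
                                 adhesion_radius_nm = 500,
                                 adhesion_edge_fraction = 0.6,
                                 ventral_density_um2 = 50,
                                 dorsal_density_um2 = 120,
                                 fiber_labels_per_um = 30,
                                 adhesion_labels = 100,
                                 brightness_mean = 100,
                                 brightness_sdlog = 0.2,
                                 rng_seed = 1L) {
  assert_scalar_num(footprint_radius_nm, "footprint_radius_nm", 0,
                    strict_lower = TRUE)
  check_range <- function(r, name) {
    if (length(r) != 2 || any(r < 0) || r[1] >= r[2])
      stopf("`%s` must be an ordered positive range", name)
  }
  check_range(ventral_z_range_nm, "ventral_z_range_nm")
  check_range(dorsal_z_range_nm, "dorsal_z_range_nm")
  check_range(adhesion_z_range_nm, "adhesion_z_range_nm")
  for (nm in c("ventral_density_um2", "dorsal_density_um2",
               "fiber_labels_per_um", "adhesion_labels"))
    assert_scalar_num(get(nm), nm, 0)
  assert_scalar_num(adhesion_edge_fraction, "adhesion_edge_fraction", 0, 1)
  assert_scalar_num(brightness_mean, "brightness_mean", 0, strict_lower = TRUE)
  structure(
    list(footprint_radius_nm = footprint_radius_nm,
         ventral_z_range_nm = ventral_z_range_nm,
         dorsal_z_range_nm = dorsal_z_range_nm,
         n_stress_fibers = n_stress_fibers,
         fiber_width_nm = fiber_width_nm,
         n_focal_adhesions = n_focal_adhesions,
         adhesion_z_range_nm = adhesion_z_range_nm,
         adhesion_radius_nm = adhesion_radius_nm,
         adhesion_edge_fraction = adhesion_edge_fraction,
         ventral_density_um2 = ventral_density_um2,
         dorsal_density_um2 = dorsal_density_um2,
         fiber_labels_per_um = fiber_labels_per_um,
         adhesion_labels = adhesion_labels,
         brightness_mean = brightness_mean,
         brightness_sdlog = brightness_sdlog,
         rng_seed = as.integer(rng_seed)),
    class = "cell_geometry_params"
  )
}

new_population <- function(x, y, z, brightness, tag) {
  df <- data.frame(x_nm = x, y_nm = y, z_nm = z,
                   brightness = brightness, tag = tag)
  class(df) <- c("fluor_population", "data.frame")
  df
}

#' Generate the synthetic labeled cell
#'
#' Draws a fluorophore population from [cell_geometry_params()]: per-
#' structure counts are Poisson with mean density x structure measure,
#' positions follow the configured geometry, and per-fluorophore brightness
#' is log-normal.  Fully deterministic for a fixed `rng_seed`.
#'
#' @param params A [cell_geometry_params()].
#'
#' @return A `fluor_population` data frame with columns `x_nm`, `y_nm`,
#'   `z_nm`, `brightness`, `tag` (tags: `ventral`, `dorsal`, `fiber`,
#'   `adhesion`); the parameters are attached as attribute `params`.
#' @export
generate_cell <- function(params) {
  stopifnot(inherits(params, "cell_geometry_params"))
  p <- params
  if (p$ventral_density_um2 == 0 && p$dorsal_density_um2 == 0 &&
      (p$n_stress_fibers == 0 || p$fiber_labels_per_um == 0) &&
      (p$n_focal_adhesions == 0 || p$adhesion_labels == 0))
    stopf("all structure densities are zero: nothing to generate")
  R <- p$footprint_radius_nm
  area_um2 <- pi * (R / 1000)^2
  pop <- withr::with_seed(p$rng_seed, {
    parts <- list()
    disk_xy <- function(n, rmax = R) {
      r <- rmax * sqrt(runif(n)); phi <- runif(n, 0, 2 * pi)
      cbind(r * cos(phi), r * sin(phi))
    }
    layer <- function(density, z_range, tag) {
      n <- rpois(1, density * area_um2)
      if (n == 0) return(NULL)
      xy <- disk_xy(n)
      new_population(xy[, 1], xy[, 2], runif(n, z_range[1], z_range[2]),
                     brightness = NA_real_, tag = tag)
    }
    parts$ventral <- layer(p$ventral_density_um2, p$ventral_z_range_nm, "ventral")
    parts$dorsal <- layer(p$dorsal_density_um2, p$dorsal_z_range_nm, "dorsal")
    # stress fibers: random chords of the footprint disk
    if (p$n_stress_fibers > 0 && p$fiber_labels_per_um > 0) {
      fib <- lapply(seq_len(p$n_stress_fibers), function(k) {
        phi <- runif(1, 0, pi)
        b <- runif(1, -0.8, 0.8) * R          # chord offset from center
        half <- sqrt(R^2 - b^2)
        len_um <- 2 * half / 1000
        n <- rpois(1, p$fiber_labels_per_um * len_um)
        if (n == 0) return(NULL)
        t <- runif(n, -half, half)
        lat <- rnorm(n, 0, p$fiber_width_nm / 4)
        u <- c(cos(phi), sin(phi)); v <- c(-sin(phi), cos(phi))
        x <- t * u[1] + (b + lat) * v[1]
        y <- t * u[2] + (b + lat) * v[2]
        zr <- p$ventral_z_range_nm
        new_population(x, y, runif(n, zr[1], zr[2]), NA_real_, "fiber")
      })
      parts$fiber <- do.call(rbind, fib)
    }
    # focal adhesions: spots at the rim and near the center
    if (p$n_focal_adhesions > 0 && p$adhesion_labels > 0) {
      adh <- lapply(seq_len(p$n_focal_adhesions), function(k) {
        at_edge <- runif(1) < p$adhesion_edge_fraction
        rc <- if (at_edge) R * runif(1, 0.85, 0.97) else R * sqrt(runif(1)) * 0.3
        phi <- runif(1, 0, 2 * pi)
        n <- rpois(1, p$adhesion_labels)
        if (n == 0) return(NULL)
        x <- rc * cos(phi) + rnorm(n, 0, p$adhesion_radius_nm / 2)
        y <- rc * sin(phi) + rnorm(n, 0, p$adhesion_radius_nm / 2)
        zr <- p$adhesion_z_range_nm
        new_population(x, y, runif(n, zr[1], zr[2]), NA_real_, "adhesion")
      })
      parts$adhesion <- do.call(rbind, adh)
    }
    pop <- do.call(rbind, parts[!vapply(parts, is.null, logical(1))])
    pop$brightness <- p$brightness_mean *
      rlnorm(nrow(pop), -p$brightness_sdlog^2 / 2, p$brightness_sdlog)
    pop
  })
  rownames(pop) <- NULL
  class(pop) <- c("fluor_population", "data.frame")
  attr(pop, "params") <- params
  pop
}

#' Generate a labeled calibration bead
#'
#' Labels uniformly distributed inside a sphere of the given diameter
#' resting on the substrate at height `z_offset_nm` (the lowest point of the
#' bead), mirroring spacer-calibration experiments with fluorescent beads.
#'
#' @param z_offset_nm Height of the bottom of the bead above the substrate
#'   (nm, >= 0).
#' @param diameter_nm Bead diameter in nm.
#' @param n_labels Number of labels to place.
#' @param seed Integer seed.
#' @param brightness_mean Expected photons per label at unit excitation.
#'
#' @return A `fluor_population` with tag `"bead"`.
#' @export
generate_bead <- function(z_offset_nm, diameter_nm = 100, n_labels = 1000,
                          seed = 1L, brightness_mean = 100) {
  if (z_offset_nm < 0) stopf("`z_offset_nm` must be >= 0")
  assert_scalar_num(diameter_nm, "diameter_nm", 0, strict_lower = TRUE)
  Rb <- diameter_nm / 2
  withr::with_seed(seed, {
    r <- Rb * runif(n_labels)^(1 / 3)
    u <- rnorm(n_labels); v <- rnorm(n_labels); w <- rnorm(n_labels)
    norm <- sqrt(u^2 + v^2 + w^2)
    pop <- new_population(r * u / norm, r * v / norm,
                          z_offset_nm + Rb + r * w / norm,
                          brightness_mean, "bead")
    pop
  })
}

#' Write a fluorophore population to CSV
#'
#' @param pop A `fluor_population`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_population <- function(pop, path) {
  stopifnot(inherits(pop, "fluor_population"))
  write.csv(as.data.frame(pop), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
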