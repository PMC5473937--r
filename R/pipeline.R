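# Pipeline: the field-profile study and the modality-comparison imaging
# study, both driven by a single nested configuration (YAML-serializable),
# with reproducible seeded outputs.

#' Default run configuration
#'
#' Nested list of every tunable parameter of the two studies, with defaults
#' matching the modeled instrument: 12.6 nm cores with 2.6 nm gaps, glass
#' n1 = 1.52 against water n2 = 1.33, excitation at 561 nm (488 nm is the
#' other laser line), evanescent reference at 65 deg incidence, camera pixel
#' 65 nm (160 nm for the standard camera), spacer sweep over 0/10/20 nm.
#'
#' @return A nested list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    seed = 1L,
    optics = list(wavelength_nm = 561, n1 = 1.52, n2 = 1.33, theta_deg = 65),
    sheet = list(core_diameter_nm = 12.6, gap_nm = 2.6,
                 n_rows = 21L, n_cols = 21L, host_index = 1.33),
    energy_transfer = list(tau_d = 1, exponent = 4,
                           d0_sweep_nm = c(2, 5, 7, 10), imaging_d0_nm = 5),
    profile = list(max_distance_nm = 200, n_points = 501),
    cell = list(footprint_radius_nm = 6000,
                ventral_z_range_nm = c(5, 50),
                dorsal_z_range_nm = c(300, 600),
                n_stress_fibers = 8L, fiber_width_nm = 150,
                n_focal_adhesions = 30L, adhesion_z_range_nm = c(5, 30),
                ventral_density_um2 = 50, dorsal_density_um2 = 120,
                fiber_labels_per_um = 30, adhesion_labels = 100),
    imaging = list(excitation_wavelength_nm = 561,
                   emission_wavelength_nm = 580,
                   numerical_aperture = 1.49,
                   pixel_size_nm = 65, field_of_view_px = 256,
                   exposure = 1, read_noise = 1.5,
                   capping_nm = 1.3, spacer_sweep_nm = c(0, 10, 20),
                   angles_deg = c(0, 65, 75),
                   tirf_theta_deg = 75, oblique_theta_deg = 55)
  ), class = c("run_config", "list"))
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @param config A `run_config` list.
#' @return `read_run_config()` returns a validated `run_config`;
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(modifyList(default_run_config(), cfg))
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Validate a run configuration
#'
#' Checks types, ranges and cross-field consistency; returns the config
#' (classed) or fails with an informative message.
#'
#' @param config A nested list as produced by [default_run_config()].
#' @return The validated `run_config`.
#' @export
validate_run_config <- function(config) {
  need <- c("seed", "optics", "sheet", "energy_transfer", "profile",
            "cell", "imaging")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stopf("config is missing sections: %s", paste(miss, collapse = ", "))
  with(config$optics, {
    assert_scalar_num(wavelength_nm, "optics$wavelength_nm", 0,
                      strict_lower = TRUE)
    if (n2 >= n1) stopf("optics: need n2 < n1 for the TIR reference")
  })
  with(config$sheet, {
    assert_scalar_num(core_diameter_nm, "sheet$core_diameter_nm", 0,
                      strict_lower = TRUE)
    assert_scalar_num(gap_nm, "sheet$gap_nm", 0)
  })
  if (!config$energy_transfer$exponent %in% c(4, 6))
    stopf("energy_transfer$exponent must be 4 or 6")
  if (any(config$energy_transfer$d0_sweep_nm <= 0))
    stopf("energy_transfer$d0_sweep_nm must be positive")
  assert_scalar_num(config$imaging$pixel_size_nm, "imaging$pixel_size_nm", 0,
                    strict_lower = TRUE)
  if (!is.numeric(config$seed) || config$seed != as.integer(config$seed))
    stopf("seed must be an integer")
  structure(config, class = c("run_config", "list"))
}

config_sheet <- function(config) {
  nanoparticle_sheet(
    core_diameter_nm = config$sheet$core_diameter_nm,
    gap_nm = config$sheet$gap_nm,
    n_rows = config$sheet$n_rows, n_cols = config$sheet$n_cols,
    material = gold_material(host_index = config$sheet$host_index))
}

out_path <- function(outdir, name, overwrite) {
  path <- file.path(outdir, name)
  if (file.exists(path) && !overwrite)
    stopf("output %s exists; pass overwrite = TRUE to replace it", path)
  path
}

log_stage <- function(fmt, ...) {
  message(sprintf("[lsprsheet] %s", sprintf(fmt, ...)))
}

#' Run the field-profile study
#'
#' Computes, on a shared distance grid: the evanescent TIR profile, the
#' plasmonic sheet profile at the configured wavelength, the energy-transfer
#' attenuation curve for each configured characteristic distance, and their
#' products.  Writes one CSV per curve plus a summary JSON (penetration
#' depth, peak enhancement and position, unity-crossing distance).
#'
#' @param config A `run_config` (defaults to [default_run_config()]).
#' @param outdir Output directory (created if missing).
#' @param overwrite Overwrite existing outputs?
#'
#' @return The summary list, invisibly; side effect: files under `outdir`.
#' @export
run_profile_study <- function(config = default_run_config(),
                              outdir = "lsprsheet-output",
                              overwrite = FALSE) {
  config <- validate_run_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  oc <- config$optics
  iface <- interface_config(oc$wavelength_nm, oc$n1, oc$n2, oc$theta_deg)
  D <- seq(0, config$profile$max_distance_nm,
           length.out = config$profile$n_points)
  log_stage("profile study: evanescent reference (theta = %g deg)",
            oc$theta_deg)
  ev <- evanescent_profile(iface, D)
  write_profile(ev, out_path(outdir, "profile_evanescent.csv", overwrite))
  log_stage("profile study: coupled-dipole solve (%d x %d patch)",
            config$sheet$n_rows, config$sheet$n_cols)
  sheet <- config_sheet(config)
  sol <- sheet_solution(sheet, oc$wavelength_nm)
  probe <- probe_line(sheet, D_grid = D)
  lspr <- lspr_profile(sheet, oc$wavelength_nm, probe, solution = sol)
  write_profile(lspr, out_path(outdir, "profile_lspr.csv", overwrite))
  et <- config$energy_transfer
  for (d0 in et$d0_sweep_nm) {
    model <- energy_transfer_model(d0, et$exponent, et$tau_d)
    sp <- set_profile(model, sheet, probe)
    cp <- combined_excitation_profile(lspr, sheet, probe, model)
    write_profile(sp, out_path(outdir, sprintf("profile_set_d0_%g.csv", d0),
                               overwrite))
    write_profile(cp, out_path(outdir,
                               sprintf("profile_lspr_x_set_d0_%g.csv", d0),
                               overwrite))
  }
  log_stage("profile study: locating peak and unity crossing")
  stats <- lspr_profile_summary(sheet, oc$wavelength_nm, solution = sol)
  summary <- list(
    wavelength_nm = oc$wavelength_nm,
    evanescent_depth_nm = penetration_depth(iface),
    critical_angle_deg = critical_angle(oc$n1, oc$n2),
    peak_enhancement = stats$peak_intensity,
    peak_distance_nm = stats$peak_distance_nm,
    unity_crossing_nm = stats$unity_crossing_nm,
    n_particles = sheet$n_particles,
    d0_sweep_nm = et$d0_sweep_nm,
    config = unclass(config))
  jsonlite::write_json(summary,
                       out_path(outdir, "profile_summary.json", overwrite),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  log_stage("profile study done in %.1f s",
            as.numeric(Sys.time() - t0, units = "secs"))
  invisible(summary)
}

config_cell_params <- function(config) {
  cc <- config$cell
  cell_geometry_params(
    footprint_radius_nm = cc$footprint_radius_nm,
    ventral_z_range_nm = cc$ventral_z_range_nm,
    dorsal_z_range_nm = cc$dorsal_z_range_nm,
    n_stress_fibers = cc$n_stress_fibers,
    fiber_width_nm = cc$fiber_width_nm,
    n_focal_adhesions = cc$n_focal_adhesions,
    adhesion_z_range_nm = cc$adhesion_z_range_nm,
    ventral_density_um2 = cc$ventral_density_um2,
    dorsal_density_um2 = cc$dorsal_density_um2,
    fiber_labels_per_um = cc$fiber_labels_per_um,
    adhesion_labels = cc$adhesion_labels,
    rng_seed = config$seed)
}

#' Build the standard comparison setups from a configuration
#'
#' Three glass-substrate setups (epi, oblique below the critical angle,
#' TIRF above it) and one sheet setup per configured angle.
#'
#' @param config A `run_config`.
#' @param sheet Optional prebuilt [nanoparticle_sheet()].
#' @param spacer_nm Spacer thickness for the sheet setups.
#' @return Named list of [imaging_setup()]s.
#' @export
config_setups <- function(config, sheet = NULL, spacer_nm = 0) {
  im <- config$imaging
  oc <- config$optics
  if (is.null(sheet)) sheet <- config_sheet(config)
  model <- energy_transfer_model(config$energy_transfer$imaging_d0_nm,
                                 config$energy_transfer$exponent,
                                 config$energy_transfer$tau_d)
  common <- list(emission_wavelength_nm = im$emission_wavelength_nm,
                 numerical_aperture = im$numerical_aperture,
                 pixel_size_nm = im$pixel_size_nm,
                 field_of_view_px = im$field_of_view_px,
                 exposure = im$exposure, read_noise = im$read_noise)
  mk <- function(...) do.call(imaging_setup, c(list(...), common))
  lam <- im$excitation_wavelength_nm
  setups <- list(
    glass_epi = mk(modality = "epi", theta_deg = 0, rng_seed = config$seed + 11L),
    glass_oblique = mk(
      modality = "oblique",
      interface = interface_config(lam, oc$n1, oc$n2, im$oblique_theta_deg),
      rng_seed = config$seed + 12L),
    glass_tirf = mk(
      modality = "tirf",
      interface = interface_config(lam, oc$n1, oc$n2, im$tirf_theta_deg),
      rng_seed = config$seed + 13L))
  for (i in seq_along(im$angles_deg)) {
    ang <- im$angles_deg[i]
    setups[[sprintf("sheet_%g", ang)]] <- mk(
      modality = "lspr_sheet", sheet = sheet, transfer_model = model,
      spacer_nm = spacer_nm, capping_nm = im$capping_nm, theta_deg = ang,
      rng_seed = config$seed + 20L + i)
  }
  setups
}

#' Run the modality-comparison imaging study
#'
#' Generates the synthetic cell, renders it under the glass setups (epi /
#' oblique / TIRF) and the sheet setups at each configured angle, writes
#' every image as 16-bit TIFF plus the structure mask, evaluates the
#' ventral-fraction and signal-to-background metrics and the angle-
#' (in)dependence orderings, sweeps the spacer thickness for the sheet
#' modality, and writes everything to a metrics JSON.
#'
#' @inheritParams run_profile_study
#'
#' @return The metrics list, invisibly; side effect: files under `outdir`.
#' @export
run_imaging_study <- function(config = default_run_config(),
                              outdir = "lsprsheet-output",
                              overwrite = FALSE) {
  config <- validate_run_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  log_stage("imaging study: generating synthetic cell")
  pop <- generate_cell(config_cell_params(config))
  sheet <- config_sheet(config)
  setups <- config_setups(config, sheet = sheet)
  mask <- structure_mask(pop, setups[[1]])
  write_mask_tiff(mask, out_path(outdir, "structure_mask.tif", overwrite))
  log_stage("imaging study: rendering %d modalities (%d fluorophores)",
            length(setups), nrow(pop))
  report <- compare_modalities(
    pop, setups, mask = mask,
    excitation_wavelength_nm = config$imaging$excitation_wavelength_nm)
  # one dipole solve + one excitation table serve every sheet render
  sol <- sheet_solution(sheet, config$imaging$excitation_wavelength_nm)
  model <- energy_transfer_model(config$energy_transfer$imaging_d0_nm,
                                 config$energy_transfer$exponent,
                                 config$energy_transfer$tau_d)
  D0 <- pop$z_nm + sheet$radius_nm + config$imaging$capping_nm
  heights <- unique(sort(c(seq(min(D0) * 0.99, 60, length.out = 40),
                           exp(seq(log(60), log(max(D0) * 1.01),
                                   length.out = 25)))))
  exc_tab <- sheet_excitation_table(sheet,
                                    config$imaging$excitation_wavelength_nm,
                                    model, heights, solution = sol)
  for (nm in names(setups)) {
    tab <- if (setups[[nm]]$modality == "lspr_sheet") exc_tab else NULL
    w <- excitation_weights(pop, setups[[nm]],
                            config$imaging$excitation_wavelength_nm, tab)
    img <- render_image(pop, w, setups[[nm]])
    write_image_tiff(img, out_path(outdir, sprintf("image_%s.tif", nm),
                                   overwrite))
  }
  # spacer sweep: mean bound excitation over substrate-proximal fluorophores
  log_stage("imaging study: spacer sweep")
  bottom <- pop$tag %in% c("ventral", "adhesion", "fiber")
  spacer <- lapply(config$imaging$spacer_sweep_nm, function(t) {
    su <- imaging_setup(modality = "lspr_sheet", sheet = sheet,
                        transfer_model = model, spacer_nm = t,
                        capping_nm = config$imaging$capping_nm)
    Dt <- pop$z_nm + sheet$radius_nm + config$imaging$capping_nm + t
    ht <- unique(sort(c(seq(min(Dt) * 0.99, min(60, max(Dt)), length.out = 40),
                        if (max(Dt) > 60) exp(seq(log(60), log(max(Dt) * 1.01),
                                                  length.out = 25)))))
    tab <- sheet_excitation_table(sheet,
                                  config$imaging$excitation_wavelength_nm,
                                  model, ht, solution = sol)
    w <- excitation_weights(pop, su, config$imaging$excitation_wavelength_nm,
                            tab)
    list(spacer_nm = t,
         mean_bottom_excitation = mean(w[bottom]),
         total_bottom_signal = sum(w[bottom] * pop$brightness[bottom]))
  })
  metrics <- list(
    n_fluorophores = nrow(pop),
    per_modality = lapply(seq_len(nrow(report)), function(i)
      as.list(report[i, , drop = FALSE])),
    orderings = attr(report, "orderings"),
    spacer_sweep = spacer,
    config = unclass(config))
  jsonlite::write_json(metrics, out_path(outdir, "metrics.json", overwrite),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  log_stage("imaging study done in %.1f s",
            as.numeric(Sys.time() - t0, units = "secs"))
  invisible(metrics)
}

#' Run the full pipeline
#'
#' @inheritParams run_profile_study
#' @param stages Which stages to run: any of `"profile"`, `"image"`.
#' @return Invisible list with the stage summaries.
#' @export
run_pipeline <- function(config = default_run_config(),
                         outdir = "lsprsheet-output",
                         stages = c("profile", "image"),
                         overwrite = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  out <- list()
  if ("profile" %in% stages)
    out$profile <- run_profile_study(config, outdir, overwrite)
  if ("image" %in% stages)
    out$image <- run_imaging_study(config, outdir, overwrite)
  invisible(out)
}
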