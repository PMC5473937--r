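# Shared fixtures, computed lazily and cached for the whole test run.
# The default 21 x 21 sheet solve takes ~1 s; the synthetic cell ~1 s.

.fx <- new.env(parent = emptyenv())

fx_material <- function() {
  if (is.null(.fx$material)) .fx$material <- gold_material()
  .fx$material
}

fx_sheet <- function() {
  if (is.null(.fx$sheet))
    .fx$sheet <- nanoparticle_sheet(material = fx_material())
  .fx$sheet
}

fx_solution <- function() {
  if (is.null(.fx$solution)) .fx$solution <- sheet_solution(fx_sheet(), 561)
  .fx$solution
}

fx_profile_stats <- function() {
  if (is.null(.fx$stats))
    .fx$stats <- lspr_profile_summary(fx_sheet(), 561, solution = fx_solution())
  .fx$stats
}

fx_cell <- function() {
  if (is.null(.fx$cell)) .fx$cell <- generate_cell(cell_geometry_params())
  .fx$cell
}

# Laterally averaged sheet excitation table covering the default cell,
# shared by the imaging tests (the slow part of lspr_sheet weights).
fx_excitation_table <- function(transfer_model = energy_transfer_model(5, 4),
                                capping_nm = 1.3) {
  if (is.null(.fx$exc_table)) {
    pop <- fx_cell()
    D <- pop$z_nm + fx_sheet()$radius_nm + capping_nm
    heights <- unique(sort(c(seq(min(D) * 0.99, 60, length.out = 40),
                             exp(seq(log(60), log(max(D) * 1.01),
                                     length.out = 25)))))
    .fx$exc_table <- sheet_excitation_table(fx_sheet(), 561, transfer_model,
                                            heights, solution = fx_solution())
  }
  .fx$exc_table
}

# Small population laid out well inside the field of view, for photon-
# accounting tests where edge truncation must be negligible.
interior_population <- function(n = 200, seed = 7, extent_nm = 3000,
                                z_range = c(5, 500)) {
  withr::with_seed(seed, {
    tag <- sample(c("ventral", "dorsal"), n, replace = TRUE)
    # ventral-tagged emitters sit in the bottom tenth of the z range
    z_lo <- c(z_range[1], z_range[1] + 0.1 * diff(z_range))
    z_hi <- c(z_range[1] + 0.6 * diff(z_range), z_range[2])
    df <- data.frame(
      x_nm = runif(n, -extent_nm, extent_nm),
      y_nm = runif(n, -extent_nm, extent_nm),
      z_nm = ifelse(tag == "ventral",
                    runif(n, z_lo[1], z_lo[2]), runif(n, z_hi[1], z_hi[2])),
      brightness = runif(n, 50, 150),
      tag = tag)
    class(df) <- c("fluor_population", "data.frame")
    df
  })
}
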