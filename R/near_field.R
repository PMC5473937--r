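# Quasi-static coupled-dipole solver for the collective near field of the
# nanoparticle sheet.  Each core carries a point dipole p_i = alpha * E_loc,i
# where the local field is the incident field plus the near-field of every
# other dipole; the self-consistent system is solved directly and the total
# field at any query point is incident + sum of dipole fields.  All lengths
# are in nm, fields in units of the incident amplitude in the host medium.
# Retardation is neglected: the cores (6.3 nm radius) are far smaller than
# the excitation wavelength.

#' Field enhancement of a single metal sphere (quasi-static closed form)
#'
#' Intensity `|E/E0|^2` around an isolated sphere from the quasi-static
#' polarizability `alpha = a^3 (eps - eps_m) / (eps + 2 eps_m)` and the
#' point-dipole field added to the incident field.  Valid for spheres much
#' smaller than the wavelength; serves as the analytic oracle for the
#' coupled-dipole solver.  The enhancement diverges at the Frohlich
#' condition `eps -> -2 eps_m`.
#'
#' @param material A [gold_material()].
#' @param radius_nm Sphere radius in nm.
#' @param wavelength_nm Vacuum wavelength in nm.
#' @param points Length-3 vector or n x 3 matrix of query points (nm),
#'   relative to the sphere center; none may lie inside the sphere.
#' @param polarization Unit vector of the incident polarization.
#'
#' @return Numeric vector of relative intensities.
#' @export
single_sphere_enhancement <- function(material, radius_nm, wavelength_nm,
                                      points, polarization = c(1, 0, 0)) {
  assert_scalar_num(radius_nm, "radius_nm", 0, strict_lower = TRUE)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  r <- sqrt(rowSums(points^2))
  if (any(r < radius_nm - 1e-9)) stopf("query point inside the sphere")
  e0 <- polarization / sqrt(sum(polarization^2))
  alpha <- quasistatic_polarizability(material, radius_nm, wavelength_nm)
  p <- alpha * e0
  E <- dipole_field(points, matrix(0, 1, 3), matrix(p, 1, 3)) +
    matrix(rep(e0, each = nrow(points)), ncol = 3)
  rowSums(Mod(E)^2)
}

# Sum of near-field dipole contributions at `points` from dipoles `P` (n x 3,
# complex) located at `pos` (n x 3). Returns an m x 3 complex matrix.
dipole_field <- function(points, pos, P) {
  E <- matrix(0 + 0i, nrow(points), 3)
  for (j in seq_len(nrow(pos))) {
    dx <- points[, 1] - pos[j, 1]
    dy <- points[, 2] - pos[j, 2]
    dz <- points[, 3] - pos[j, 3]
    r2 <- dx * dx + dy * dy + dz * dz
    r <- sqrt(r2)
    inv_r3 <- 1 / (r2 * r)
    ndp <- (dx * P[j, 1] + dy * P[j, 2] + dz * P[j, 3]) / r
    E[, 1] <- E[, 1] + (3 * ndp * dx / r - P[j, 1]) * inv_r3
    E[, 2] <- E[, 2] + (3 * ndp * dy / r - P[j, 2]) * inv_r3
    E[, 3] <- E[, 3] + (3 * ndp * dz / r - P[j, 3]) * inv_r3
  }
  E
}

#' Solve the coupled-dipole system of a sheet
#'
#' Computes the self-consistent induced dipole moments of every particle for
#' the two orthogonal in-plane polarizations.  The solution depends only on
#' the sheet and wavelength, so it can be reused across many field
#' evaluations.
#'
#' @param sheet A [nanoparticle_sheet()].
#' @param wavelength_nm Vacuum wavelength in nm (inside the tabulated range).
#' @param method Permittivity evaluation method, see [permittivity()].
#'
#' @return An object of class `sheet_solution` with complex dipole-moment
#'   matrices `Px`, `Py` (n x 3, for x- and y-polarized incidence).
#' @export
sheet_solution <- function(sheet, wavelength_nm, method = "table") {
  stopifnot(inherits(sheet, "nanoparticle_sheet"))
  alpha <- quasistatic_polarizability(sheet$material, sheet$radius_nm,
                                      wavelength_nm, method)
  pos <- sheet$positions
  N <- nrow(pos)
  A <- matrix(0 + 0i, 3 * N, 3 * N)
  dx <- outer(pos[, 1], pos[, 1], "-")
  dy <- outer(pos[, 2], pos[, 2], "-")
  dz <- outer(pos[, 3], pos[, 3], "-")
  r2 <- dx * dx + dy * dy + dz * dz
  diag(r2) <- Inf
  r <- sqrt(r2)
  inv_r3 <- 1 / (r2 * r)
  nx <- dx / r; ny <- dy / r; nz <- dz / r
  comp <- list(nx, ny, nz)
  idx <- function(a) 3 * (seq_len(N) - 1) + a
  for (a in 1:3) for (b in 1:3) {
    K <- (3 * comp[[a]] * comp[[b]] - (a == b)) * inv_r3
    A[idx(a), idx(b)] <- -K
  }
  diag(A) <- diag(A) + 1 / alpha
  b <- cbind(rep(c(1, 0, 0), N), rep(c(0, 1, 0), N)) + 0i
  P <- tryCatch(solve(A, b), error = function(e)
    stopf(paste0("coupled-dipole system is singular: the sheet is driven at a ",
                 "collective resonance of the lossless model (%s)"),
          conditionMessage(e)))
  structure(
    list(Px = matrix(P[, 1], ncol = 3, byrow = TRUE),
         Py = matrix(P[, 2], ncol = 3, byrow = TRUE),
         wavelength_nm = wavelength_nm, alpha = alpha),
    class = "sheet_solution"
  )
}

#' Near-field intensity of the sheet at query points
#'
#' Relative intensity `|E/E0|^2` of the self-consistent coupled-dipole
#' field.  With `polarization = "average"` the intensities for the two
#' orthogonal in-plane polarizations are averaged, emulating unpolarized
#' epi-illumination.  `component = "scattered"` returns the intensity of the
#' bound (dipole-only) part `|E - E0|^2`, the surface-confined excitation
#' used by the imaging model.
#'
#' @param sheet A [nanoparticle_sheet()].
#' @param wavelength_nm Vacuum wavelength in nm.
#' @param points Length-3 vector or n x 3 matrix of query points (nm), all
#'   outside the cores.
#' @param polarization `"average"`, `"x"` or `"y"`.
#' @param component `"total"` or `"scattered"`.
#' @param solution Optional precomputed [sheet_solution()] to reuse.
#'
#' @return Numeric vector of relative intensities, one per query point.
#' @export
compute_near_field <- function(sheet, wavelength_nm, points,
                               polarization = c("average", "x", "y"),
                               component = c("total", "scattered"),
                               solution = NULL) {
  polarization <- match.arg(polarization)
  component <- match.arg(component)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  nearest_surface_distance(sheet, points)  # errors if any point is inside a core
  if (is.null(solution)) solution <- sheet_solution(sheet, wavelength_nm)
  one_pol <- function(P, e0) {
    E <- dipole_field(points, sheet$positions, P)
    if (component == "total")
      E <- E + matrix(rep(e0, each = nrow(points)), ncol = 3)
    rowSums(Mod(E)^2)
  }
  switch(polarization,
    x = one_pol(solution$Px, c(1, 0, 0)),
    y = one_pol(solution$Py, c(0, 1, 0)),
    average = (one_pol(solution$Px, c(1, 0, 0)) +
               one_pol(solution$Py, c(0, 1, 0))) / 2)
}

#' Plasmonic intensity profile along the probe line
#'
#' Samples [compute_near_field()] along a [probe_line()] and returns the
#' polarization-averaged relative intensity as a [field_profile()] with
#' label `"lspr"`.
#'
#' @param sheet A [nanoparticle_sheet()].
#' @param wavelength_nm Vacuum wavelength in nm.
#' @param probe A [probe_line()].
#' @param solution Optional precomputed [sheet_solution()].
#'
#' @return A [field_profile()] with label `"lspr"`.
#' @export
lspr_profile <- function(sheet, wavelength_nm, probe, solution = NULL) {
  stopifnot(inherits(probe, "probe_line"))
  I <- compute_near_field(sheet, wavelength_nm, probe_points(probe),
                          solution = solution)
  field_profile(probe$D_grid, I, "lspr")
}

#' Summary statistics of a plasmonic profile
#'
#' Peak enhancement, peak position and the first distance beyond the peak at
#' which the relative intensity crosses below 1 (located by root finding on
#' the continuous solver output, not on the sampled grid).
#'
#' @param sheet,wavelength_nm,solution As in [lspr_profile()].
#' @param search_max_nm Upper bound of the crossing search (nm).
#'
#' @return A list with `peak_intensity`, `peak_distance_nm`,
#'   `unity_crossing_nm` (NA if the profile never drops below 1 before
#'   `search_max_nm`).
#' @export
lspr_profile_summary <- function(sheet, wavelength_nm, solution = NULL,
                                 search_max_nm = 60) {
  if (is.null(solution)) solution <- sheet_solution(sheet, wavelength_nm)
  f <- function(D) compute_near_field(sheet, wavelength_nm, cbind(0, 0, D),
                                      solution = solution)
  D_coarse <- seq(0, search_max_nm, by = 0.25)
  I_coarse <- f(D_coarse)
  i_pk <- which.max(I_coarse)
  # refine the peak on a fine local grid
  D_fine <- seq(max(0, D_coarse[i_pk] - 0.5), D_coarse[i_pk] + 0.5, by = 0.01)
  I_fine <- f(D_fine)
  peak_D <- D_fine[which.max(I_fine)]
  peak_I <- max(I_fine)
  below <- which(D_coarse > peak_D & I_coarse < 1)
  crossing <- NA_real_
  if (length(below)) {
    hi <- D_coarse[below[1]]
    lo <- D_coarse[max(below[1] - 1L, 1L)]
    crossing <- uniroot(function(D) f(D) - 1, c(lo, hi), tol = 1e-4)$root
  }
  list(peak_intensity = peak_I, peak_distance_nm = peak_D,
       unity_crossing_nm = crossing)
}
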