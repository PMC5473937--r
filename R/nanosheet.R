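# Geometry of the close-packed 2D nanoparticle sheet and the probe line used
# for intensity-versus-distance profiles.

#' Close-packed gold nanoparticle sheet
#'
#' Builds a finite hexagonally close-packed patch of spherical gold cores in
#' the z = 0 plane.  The center-to-center pitch is
#' `core_diameter_nm + gap_nm` (15.2 nm for the defaults, set by the
#' interdigitated capping ligands).  The patch is constructed so that two
#' adjacent particles straddle the origin at `(+-pitch/2, 0, 0)` — the pair
#' probed by [probe_line()] — and so that it is mirror-symmetric in x and y.
#'
#' @param core_diameter_nm Gold core diameter in nm (default 12.6).
#' @param gap_nm Surface-to-surface gap between neighboring cores in nm
#'   (default 2.6).
#' @param n_rows,n_cols Patch extent in rows and particles per row.  The
#'   default 21 x 21 is the smallest patch for which the computed profile
#'   satisfies the far-field checks (see the package vignette); rows offset
#'   by half a pitch get one extra particle to preserve mirror symmetry.
#' @param material A [gold_material()] describing the cores and host medium.
#' @param positions Optional explicit n x 3 matrix of particle centers (nm),
#'   overriding the lattice construction; used for single-particle and dimer
#'   oracle checks.  Centers must be at least one core diameter apart.
#'
#' @return An object of class `nanoparticle_sheet` with fields `positions`
#'   (n x 3 matrix, nm), `radius_nm`, `pitch_nm`, `gap_nm`, `n_particles`,
#'   `material`.
#' @examples
#' sheet <- nanoparticle_sheet(n_rows = 5, n_cols = 5)
#' sheet$pitch_nm  # 15.2
#' @export
nanoparticle_sheet <- function(core_diameter_nm = 12.6, gap_nm = 2.6,
                               n_rows = 21, n_cols = 21,
                               material = gold_material(),
                               positions = NULL) {
  assert_scalar_num(core_diameter_nm, "core_diameter_nm", 0, strict_lower = TRUE)
  assert_scalar_num(gap_nm, "gap_nm", 0)
  stopifnot(inherits(material, "material_model"))
  pitch <- core_diameter_nm + gap_nm
  if (is.null(positions)) {
    if (n_rows < 1 || n_cols < 1) stopf("patch must have >= 1 row and column")
    if (n_rows %% 2 == 0 || n_cols %% 2 == 0)
      stopf("`n_rows` and `n_cols` must be odd so the probed pair is central")
    rows <- seq(-(n_rows - 1) / 2, (n_rows - 1) / 2)
    pos <- do.call(rbind, lapply(rows, function(n) {
      if (n %% 2 == 0) {
        # offset rows: particles at (m + 1/2) * pitch, one extra to stay symmetric
        m <- seq(-(n_cols / 2 + 0.5), n_cols / 2 - 0.5) + 0.5
      } else {
        m <- seq(-(n_cols - 1) / 2, (n_cols - 1) / 2)
      }
      cbind(x = m * pitch, y = n * pitch * sqrt(3) / 2, z = 0)
    }))
  } else {
    pos <- as.matrix(positions)
    if (ncol(pos) != 3) stopf("`positions` must be n x 3")
    n_rows <- NA_integer_; n_cols <- NA_integer_
  }
  if (nrow(pos) > 1 && min(stats::dist(pos)) < core_diameter_nm - 1e-9)
    stopf("particle cores overlap: minimum center distance %.3g nm < diameter",
          min(stats::dist(pos)))
  structure(
    list(positions = pos, radius_nm = core_diameter_nm / 2,
         core_diameter_nm = core_diameter_nm, gap_nm = gap_nm,
         pitch_nm = pitch, n_particles = nrow(pos),
         n_rows = n_rows, n_cols = n_cols, material = material),
    class = "nanoparticle_sheet"
  )
}

#' @export
print.nanoparticle_sheet <- function(x, ...) {
  cat(sprintf(
    "<nanoparticle_sheet> %d particles (%d x %d patch), core %g nm, gap %g nm, pitch %g nm\n",
    x$n_particles, x$n_rows, x$n_cols, x$core_diameter_nm, x$gap_nm, x$pitch_nm))
  invisible(x)
}

#' Probe line normal to the sheet through a gap midpoint
#'
#' The intensity-versus-distance profiles are sampled along the line normal
#' to the sheet through the midpoint of the two central adjacent particles;
#' D = 0 lies in the plane of the particle centers, so the closest particle
#' surface at D = 0 is `sqrt((pitch/2)^2) - radius = gap/2` away.
#'
#' @param sheet A [nanoparticle_sheet()].
#' @param max_distance_nm Largest D when `D_grid` is not supplied.
#' @param n Number of grid points when `D_grid` is not supplied.
#' @param D_grid Optional explicit strictly increasing grid of D values (nm,
#'   >= 0).
#'
#' @return An object of class `probe_line` with fields `origin`, `direction`
#'   and `D_grid`.
#' @export
probe_line <- function(sheet, max_distance_nm = 200, n = 401, D_grid = NULL) {
  stopifnot(inherits(sheet, "nanoparticle_sheet"))
  if (is.null(D_grid)) D_grid <- seq(0, max_distance_nm, length.out = n)
  if (is.unsorted(D_grid, strictly = TRUE) || any(D_grid < 0))
    stopf("`D_grid` must be strictly increasing and non-negative")
  structure(
    list(origin = c(0, 0, 0), direction = c(0, 0, 1), D_grid = D_grid),
    class = "probe_line"
  )
}

probe_points <- function(probe) {
  cbind(probe$origin[1], probe$origin[2], probe$D_grid)
}

#' Distance from query points to the closest particle surface
#'
#' @param sheet A [nanoparticle_sheet()].
#' @param points Numeric vector of length 3 or an n x 3 matrix of query
#'   points (nm).  Points must not lie inside any core.
#'
#' @return Numeric vector of distances in nm (0 on a particle surface).
#' @examples
#' sheet <- nanoparticle_sheet(n_rows = 3, n_cols = 3)
#' nearest_surface_distance(sheet, c(0, 0, 0))  # gap/2 = 1.3 nm
#' @export
nearest_surface_distance <- function(sheet, points) {
  stopifnot(inherits(sheet, "nanoparticle_sheet"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  if (ncol(points) != 3) stopf("`points` must be n x 3")
  pos <- sheet$positions
  d <- vapply(seq_len(nrow(points)), function(i) {
    dx <- pos[, 1] - points[i, 1]
    dy <- pos[, 2] - points[i, 2]
    dz <- pos[, 3] - points[i, 3]
    sqrt(min(dx * dx + dy * dy + dz * dz))
  }, numeric(1)) - sheet$radius_nm
  if (any(d < -1e-9))
    stopf("query point inside a particle core (%.3g nm below the surface)",
          -min(d))
  pmax(d, 0)
}
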