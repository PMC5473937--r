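# Dielectric function of gold: tabulated Johnson & Christy optical constants
# bundled with the package, plus a Drude free-electron fit over a stated
# wavelength window.

#' Tabulated gold permittivity (Johnson & Christy)
#'
#' Returns the bundled table of complex relative permittivity of gold versus
#' vacuum wavelength, derived from the Johnson & Christy n,k measurements.
#'
#' @return A data frame with columns `wavelength_nm`, `eps_real`, `eps_imag`.
#' @export
jc_gold_table <- function() {
  path <- system.file("extdata", "johnson_christy_gold.csv",
                      package = "lsprsheet", mustWork = TRUE)
  read.csv(path)
}

#' Fit a Drude model to a permittivity table
#'
#' Least-squares fit of `eps(omega) = eps_inf - wp^2 / (omega^2 + i g omega)`
#' (photon energies in eV) to the tabulated complex permittivity over
#' `fit_window_nm`.  For gold the free-electron model is a good description
#' at the red side of the visible; interband transitions below ~520 nm are
#' not captured, which is why the fit window defaults to 500-700 nm and the
#' achieved residual is recorded on the returned object.
#'
#' @param table Data frame with columns `wavelength_nm`, `eps_real`,
#'   `eps_imag`.
#' @param fit_window_nm Length-2 wavelength window (nm) over which to fit.
#'
#' @return A list with elements `eps_inf`, `wp_ev` (plasma energy, eV),
#'   `gamma_ev` (damping, eV), `fit_window_nm` and `max_residual`
#'   (max |eps_fit - eps_table| over table nodes inside the window).
#' @export
fit_drude <- function(table, fit_window_nm = c(500, 700)) {
  stopifnot(all(c("wavelength_nm", "eps_real", "eps_imag") %in% names(table)))
  if (min(fit_window_nm) < min(table$wavelength_nm) ||
      max(fit_window_nm) > max(table$wavelength_nm))
    stopf("fit window [%g, %g] nm extends beyond the table range [%g, %g] nm",
          min(fit_window_nm), max(fit_window_nm),
          min(table$wavelength_nm), max(table$wavelength_nm))
  keep <- table$wavelength_nm >= min(fit_window_nm) &
    table$wavelength_nm <= max(fit_window_nm)
  if (sum(keep) < 3L) stopf("fewer than 3 table nodes inside the fit window")
  ev <- 1239.84193 / table$wavelength_nm[keep]
  eps <- complex(real = table$eps_real[keep], imaginary = table$eps_imag[keep])
  drude <- function(p, w) p[1] - p[2]^2 / (w^2 + 1i * p[3] * w)
  obj <- function(p) {
    if (p[2] <= 0 || p[3] <= 0) return(1e12)
    sum(Mod(drude(p, ev) - eps)^2)
  }
  fit <- optim(c(9, 9, 0.1), obj, control = list(maxit = 5000, reltol = 1e-12))
  p <- fit$par
  list(eps_inf = p[1], wp_ev = p[2], gamma_ev = p[3],
       fit_window_nm = range(fit_window_nm),
       max_residual = max(Mod(drude(p, ev) - eps)))
}

#' Material model for the nanoparticle metal
#'
#' Combines the tabulated permittivity, its Drude fit, and the refractive
#' index of the host medium surrounding the particles.
#'
#' @param host_index Refractive index of the surrounding medium (water 1.33
#'   by default; the substrate is not modeled by the dipole solver).
#' @param table Permittivity table; defaults to the bundled gold data.
#' @param fit_window_nm Window passed to [fit_drude()].
#'
#' @return An object of class `material_model` with fields `table`, `drude`,
#'   `host_index`.
#' @examples
#' au <- gold_material()
#' permittivity(au, 561)
#' @export
gold_material <- function(host_index = 1.33, table = jc_gold_table(),
                          fit_window_nm = c(500, 700)) {
  assert_scalar_num(host_index, "host_index", 0, strict_lower = TRUE)
  structure(
    list(table = table,
         drude = fit_drude(table, fit_window_nm),
         host_index = host_index),
    class = "material_model"
  )
}

#' @export
print.material_model <- function(x, ...) {
  cat(sprintf(
    "<material_model> %d table nodes (%.0f-%.0f nm), host index %g\n",
    nrow(x$table), min(x$table$wavelength_nm), max(x$table$wavelength_nm),
    x$host_index))
  cat(sprintf(
    "  Drude fit over %g-%g nm: eps_inf = %.2f, wp = %.2f eV, gamma = %.3f eV (max resid %.2f)\n",
    x$drude$fit_window_nm[1], x$drude$fit_window_nm[2], x$drude$eps_inf,
    x$drude$wp_ev, x$drude$gamma_ev, x$drude$max_residual))
  invisible(x)
}

#' Complex relative permittivity at a wavelength
#'
#' @param material A [gold_material()].
#' @param wavelength_nm Vacuum wavelength(s) in nm.
#' @param method `"table"` (default) linearly interpolates the tabulated
#'   values; `"drude"` evaluates the fitted free-electron model (only inside
#'   its fit window).
#'
#' @return Complex permittivity value(s).
#' @export
permittivity <- function(material, wavelength_nm, method = c("table", "drude")) {
  stopifnot(inherits(material, "material_model"))
  method <- match.arg(method)
  if (method == "table") {
    rng <- range(material$table$wavelength_nm)
    if (any(wavelength_nm < rng[1] | wavelength_nm > rng[2]))
      stopf("wavelength outside the tabulated range [%g, %g] nm",
            rng[1], rng[2])
    complex(
      real = approx(material$table$wavelength_nm, material$table$eps_real,
                    wavelength_nm)$y,
      imaginary = approx(material$table$wavelength_nm, material$table$eps_imag,
                         wavelength_nm)$y)
  } else {
    win <- material$drude$fit_window_nm
    if (any(wavelength_nm < win[1] | wavelength_nm > win[2]))
      stopf("Drude fit is only valid inside its window [%g, %g] nm",
            win[1], win[2])
    w <- 1239.84193 / wavelength_nm
    material$drude$eps_inf -
      material$drude$wp_ev^2 / (w^2 + 1i * material$drude$gamma_ev * w)
  }
}

# Quasi-static dipole polarizability of a sphere in the host medium, in nm^3.
# Defined so that the field of the induced dipole in the host is
# E(r) = (3 n (n.p) - p) / r^3 with p = alpha * E_local.
quasistatic_polarizability <- function(material, radius_nm, wavelength_nm,
                                       method = "table") {
  eps <- permittivity(material, wavelength_nm, method)
  eps_m <- material$host_index^2
  radius_nm^3 * (eps - eps_m) / (eps + 2 * eps_m)
}
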