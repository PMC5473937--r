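# Closed-form total-internal-reflection (TIRF) excitation optics at a planar
# dielectric interface: critical angle, evanescent penetration depth and the
# exponential intensity-versus-height profile.

#' Interface configuration for evanescent-field excitation
#'
#' Bundles the optical parameters of a planar two-medium interface
#' illuminated from the dense side: vacuum wavelength, the two refractive
#' indices, the incidence angle measured from the surface normal, and the
#' reference intensity at the interface.
#'
#' @param wavelength_nm Vacuum wavelength of the excitation light in nm.
#' @param n1 Refractive index on the incidence side (glass, typically 1.52).
#' @param n2 Refractive index on the transmission side (water 1.33, or a
#'   glycerol-based mounting medium 1.46).
#' @param theta_deg Incidence angle from the normal, in degrees, in
#'   `[0, 90)`.
#' @param I0 Reference intensity of the evanescent wave at the interface
#'   (z = 0).  Profiles are relative, so the default of 1 is rarely changed.
#'
#' @return An object of class `interface_config`.
#' @examples
#' cfg <- interface_config(561, n1 = 1.52, n2 = 1.33, theta_deg = 65)
#' penetration_depth(cfg)
#' @export
interface_config <- function(wavelength_nm, n1 = 1.52, n2 = 1.33,
                             theta_deg, I0 = 1) {
  assert_scalar_num(wavelength_nm, "wavelength_nm", 0, strict_lower = TRUE)
  assert_scalar_num(n1, "n1", 0, strict_lower = TRUE)
  assert_scalar_num(n2, "n2", 0, strict_lower = TRUE)
  assert_scalar_num(theta_deg, "theta_deg", 0)
  if (theta_deg >= 90) stopf("`theta_deg` must be < 90")
  assert_scalar_num(I0, "I0", 0, strict_lower = TRUE)
  structure(
    list(wavelength_nm = wavelength_nm, n1 = n1, n2 = n2,
         theta_deg = theta_deg, I0 = I0),
    class = "interface_config"
  )
}

#' @export
print.interface_config <- function(x, ...) {
  cat(sprintf(
    "<interface_config> lambda = %g nm, n1 = %g, n2 = %g, theta = %g deg\n",
    x$wavelength_nm, x$n1, x$n2, x$theta_deg))
  if (x$n2 < x$n1) {
    thc <- critical_angle(x$n1, x$n2)
    cat(sprintf("  critical angle: %.2f deg (%s)\n", thc,
                if (x$theta_deg > thc) "evanescent regime"
                else "propagating regime"))
  }
  invisible(x)
}

#' Critical angle of total internal reflection
#'
#' @param n1 Refractive index on the incidence side.
#' @param n2 Refractive index on the transmission side; must satisfy
#'   `n2 < n1` for total internal reflection to exist.
#'
#' @return The critical angle `asin(n2 / n1)` in degrees.
#' @examples
#' critical_angle(1.52, 1.33)  # glass/water, ~61.0 deg
#' critical_angle(1.52, 1.46)  # glass/mounting medium, ~73.9 deg
#' @export
critical_angle <- function(n1, n2) {
  assert_scalar_num(n1, "n1", 0, strict_lower = TRUE)
  assert_scalar_num(n2, "n2", 0, strict_lower = TRUE)
  if (n2 >= n1)
    stopf("no total internal reflection: requires n2 < n1 (got n1 = %g, n2 = %g)",
          n1, n2)
  asin(n2 / n1) * 180 / pi
}

#' Evanescent-field penetration depth
#'
#' Depth at which the evanescent intensity decays to 1/e of its value at the
#' interface: `d = lambda / (4 * pi * sqrt(n1^2 sin^2(theta) - n2^2))`.
#' Defined only above the critical angle.
#'
#' @param config An [interface_config()].
#'
#' @return Penetration depth in nm.
#' @examples
#' # the canonical glass/water value at 561 nm and 65 degrees: ~124.4 nm
#' penetration_depth(interface_config(561, 1.52, 1.33, theta_deg = 65))
#' @export
penetration_depth <- function(config) {
  stopifnot(inherits(config, "interface_config"))
  theta_c <- critical_angle(config$n1, config$n2)
  if (config$theta_deg <= theta_c)
    stopf(paste0("propagating regime, depth undefined: theta = %g deg is not ",
                 "above the critical angle %.3f deg"),
          config$theta_deg, theta_c)
  th <- config$theta_deg * pi / 180
  config$wavelength_nm /
    (4 * pi * sqrt(config$n1^2 * sin(th)^2 - config$n2^2))
}

#' Incidence angle giving a target penetration depth
#'
#' Inverse of [penetration_depth()]: the angle (in degrees) at which the
#' evanescent depth equals `depth_nm`.  Useful to set up a TIRF arm with a
#' prescribed sectioning depth.
#'
#' @param wavelength_nm,n1,n2 As in [interface_config()].
#' @param depth_nm Target penetration depth in nm.
#'
#' @return Incidence angle in degrees (above the critical angle, below 90).
#' @export
theta_for_depth <- function(wavelength_nm, n1, n2, depth_nm) {
  assert_scalar_num(depth_nm, "depth_nm", 0, strict_lower = TRUE)
  q <- (wavelength_nm / (4 * pi * depth_nm))^2 + n2^2
  s <- sqrt(q) / n1
  if (s >= 1)
    stopf("depth %g nm is not reachable below grazing incidence", depth_nm)
  asin(s) * 180 / pi
}

# Field profiles ---------------------------------------------------------------

profile_labels <- c("evanescent", "lspr", "set", "lspr_x_set")

#' Construct a relative-intensity field profile
#'
#' A field profile is a data frame with columns `distance_nm` (a strictly
#' increasing grid), `relative_intensity` (I/I0, finite and non-negative) and
#' `label` (one of `"evanescent"`, `"lspr"`, `"set"`, `"lspr_x_set"`).
#'
#' @param distance_nm Strictly increasing numeric grid of distances in nm.
#' @param relative_intensity Non-negative finite intensities relative to the
#'   incident intensity.
#' @param label Curve label from the closed set above.
#'
#' @return A data frame of class `field_profile`.
#' @export
field_profile <- function(distance_nm, relative_intensity, label) {
  if (!is.numeric(distance_nm) || length(distance_nm) < 1L ||
      anyNA(distance_nm) || any(!is.finite(distance_nm)))
    stopf("`distance_nm` must be a finite numeric grid")
  if (is.unsorted(distance_nm, strictly = TRUE))
    stopf("`distance_nm` must be strictly increasing")
  if (!is.numeric(relative_intensity) ||
      length(relative_intensity) != length(distance_nm) ||
      any(!is.finite(relative_intensity)) || any(relative_intensity < 0))
    stopf("`relative_intensity` must be finite, non-negative and match the grid")
  label <- match.arg(label, profile_labels)
  structure(
    data.frame(distance_nm = distance_nm,
               relative_intensity = relative_intensity,
               label = label),
    class = c("field_profile", "data.frame")
  )
}

#' Evanescent intensity profile above a TIR interface
#'
#' Exponential decay `I(z) = I0 * exp(-z / d)` with `d` from
#' [penetration_depth()]; the returned profile is normalized to `I0`.
#'
#' @param config An [interface_config()] above the critical angle.
#' @param distance_nm Grid of heights z above the interface, in nm (z >= 0,
#'   strictly increasing).
#'
#' @return A [field_profile()] with label `"evanescent"`.
#' @export
evanescent_profile <- function(config, distance_nm) {
  if (any(distance_nm < 0)) stopf("`distance_nm` must be >= 0")
  d <- penetration_depth(config)
  field_profile(distance_nm, exp(-distance_nm / d), "evanescent")
}

#' Write or read a field profile as CSV
#'
#' The on-disk dialect is a plain CSV with columns `distance_nm`,
#' `relative_intensity`, `label`, shared by every profile-producing module.
#'
#' @param profile A [field_profile()].
#' @param path File path.
#' @return `write_profile()` returns `path` invisibly; `read_profile()`
#'   returns a validated [field_profile()].
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "field_profile"))
  write.csv(as.data.frame(profile), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("distance_nm", "relative_intensity", "label")
  if (!all(need %in% names(df)))
    stopf("profile CSV must have columns %s", paste(need, collapse = ", "))
  field_profile(df$distance_nm, df$relative_intensity, unique(df$label))
}
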