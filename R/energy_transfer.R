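# Distance-dependent non-radiative energy transfer from a fluorophore to the
# metal: the Forster (FRET, r^-6) and nanometal surface energy transfer
# (NSET, d^-4) rate laws and the resulting fluorescence attenuation factor.

#' Energy-transfer model
#'
#' @param characteristic_distance_nm The 50%-transfer distance: `r0` for
#'   FRET, `d0` for surface energy transfer.
#' @param exponent Distance exponent of the rate law: 4 for surface energy
#'   transfer to a metal, 6 for Forster transfer between molecular dipoles.
#' @param tau_d Donor excited-state lifetime in the absence of the acceptor
#'   (arbitrary time units; rates are reported in its inverse).
#'
#' @return An object of class `energy_transfer_model`.
#' @examples
#' set_model <- energy_transfer_model(5, exponent = 4)
#' set_attenuation(set_model, 5)   # 0.5 at d = d0
#' @export
energy_transfer_model <- function(characteristic_distance_nm, exponent = 4,
                                  tau_d = 1) {
  assert_scalar_num(characteristic_distance_nm, "characteristic_distance_nm",
                    0, strict_lower = TRUE)
  assert_scalar_num(tau_d, "tau_d", 0, strict_lower = TRUE)
  if (!exponent %in% c(4, 6))
    stopf("`exponent` must be 4 (surface energy transfer) or 6 (FRET)")
  structure(
    list(characteristic_distance_nm = characteristic_distance_nm,
         exponent = exponent, tau_d = tau_d),
    class = "energy_transfer_model"
  )
}

#' @export
print.energy_transfer_model <- function(x, ...) {
  cat(sprintf("<energy_transfer_model> %s: x0 = %g nm, tau_D = %g\n",
              if (x$exponent == 4) "surface energy transfer (d^-4)"
              else "FRET (r^-6)",
              x$characteristic_distance_nm, x$tau_d))
  invisible(x)
}

#' Energy-transfer rate at a distance
#'
#' `k(x) = (1 / tau_D) * (x0 / x)^n` with `n` and `x0` from the model.  The
#' rate equals the donor's radiative rate `1/tau_D` at the characteristic
#' distance.
#'
#' @param model An [energy_transfer_model()].
#' @param distance_nm Positive distance(s) in nm.
#'
#' @return Transfer rate(s) in units of `1/tau_d`.
#' @export
transfer_rate <- function(model, distance_nm) {
  stopifnot(inherits(model, "energy_transfer_model"))
  if (any(distance_nm <= 0)) stopf("`distance_nm` must be > 0")
  (1 / model$tau_d) *
    (model$characteristic_distance_nm / distance_nm)^model$exponent
}

#' Fluorescence attenuation factor near the metal surface
#'
#' The fraction of fluorescence surviving energy transfer,
#' `I_d / I_inf = 1 / (1 + (d0 / d)^n)`, which is the transfer-rate
#' competition with the unperturbed decay.  Strictly increasing in distance,
#' 1/2 at `d = d0`, and tends to 1 far from the surface.
#'
#' @param model An [energy_transfer_model()].
#' @param distance_nm Positive distance(s) to the metal surface in nm
#'   (`Inf` allowed, giving 1; 0 allowed, giving 0 as the limiting value).
#'
#' @return Attenuation factor(s) in `[0, 1]`.
#' @export
set_attenuation <- function(model, distance_nm) {
  stopifnot(inherits(model, "energy_transfer_model"))
  if (any(distance_nm < 0)) stopf("`distance_nm` must be >= 0")
  ifelse(distance_nm == 0, 0,
         1 / (1 + (model$characteristic_distance_nm / distance_nm)^model$exponent))
}

#' Attenuation curve along the probe line
#'
#' Evaluates [set_attenuation()] along a [probe_line()], measuring the
#' transfer distance at each D as the distance to the closest particle
#' surface ([nearest_surface_distance()]).
#'
#' @param model An [energy_transfer_model()].
#' @param sheet A [nanoparticle_sheet()].
#' @param probe A [probe_line()].
#'
#' @return A [field_profile()] with label `"set"`.
#' @export
set_profile <- function(model, sheet, probe) {
  stopifnot(inherits(probe, "probe_line"))
  d <- nearest_surface_distance(sheet, probe_points(probe))
  field_profile(probe$D_grid, set_attenuation(model, d), "set")
}

#' Combined plasmonic excitation and energy-transfer profile
#'
#' Pointwise product of the plasmonic intensity profile and the
#' energy-transfer attenuation factor, the expected fluorescence
#' excitation-enhancement curve.  The two factors use different distance
#' variables on purpose: the intensity is sampled at height D on the probe
#' line while the attenuation uses the distance from that point to the
#' closest particle surface.
#'
#' @param lspr A [field_profile()] with label `"lspr"`.
#' @param sheet A [nanoparticle_sheet()].
#' @param probe The [probe_line()] the profile was sampled on; its grid must
#'   match the profile grid exactly.
#' @param model An [energy_transfer_model()].
#'
#' @return A [field_profile()] with label `"lspr_x_set"`.
#' @export
combined_excitation_profile <- function(lspr, sheet, probe, model) {
  stopifnot(inherits(lspr, "field_profile"), inherits(probe, "probe_line"))
  if (unique(lspr$label) != "lspr")
    stopf("`lspr` must be a profile with label 'lspr'")
  if (length(lspr$distance_nm) != length(probe$D_grid) ||
      any(lspr$distance_nm != probe$D_grid))
    stopf("grid mismatch: profile and probe line must share the same D grid")
  att <- set_attenuation(model,
                         nearest_surface_distance(sheet, probe_points(probe)))
  field_profile(probe$D_grid, lspr$relative_intensity * att, "lspr_x_set")
}

#' Recover the distance exponent from an attenuation curve
#'
#' Rearranges the attenuation law to
#' `log(1/A - 1) = n log(d0) - n log(d)` and estimates the exponent `n`
#' (and `d0`) by ordinary least squares.  Useful to check whether measured
#' or simulated quenching follows the d^-4 surface-transfer law or the d^-6
#' Forster law.
#'
#' @param distance_nm Distances in nm; at least 5 points spanning at least a
#'   factor of 3.
#' @param attenuation Attenuation factors strictly inside (0, 1).
#' @param conf_level Confidence level of the reported interval.
#'
#' @return A list with `exponent`, `se`, `ci` (confidence interval),
#'   `d0_nm`, and the underlying `fit`.
#' @export
fit_distance_exponent <- function(distance_nm, attenuation,
                                  conf_level = 0.95) {
  if (length(distance_nm) != length(attenuation))
    stopf("`distance_nm` and `attenuation` must have equal length")
  if (length(distance_nm) < 5L)
    stopf("need at least 5 points to estimate the exponent")
  if (max(distance_nm) / min(distance_nm) < 3)
    stopf("degenerate spread: distances must span at least a factor of 3")
  if (any(attenuation <= 0 | attenuation >= 1))
    stopf("`attenuation` values must lie strictly inside (0, 1)")
  y <- log(1 / attenuation - 1)
  x <- log(distance_nm)
  fit <- lm(y ~ x)
  n_hat <- -coef(fit)[["x"]]
  # noiseless curves give an exact fit; the perfect-fit warning from the
  # inferential summaries is expected there and not informative
  ci <- suppressWarnings(-rev(confint(fit, "x", level = conf_level)[1, ]))
  names(ci) <- NULL
  list(exponent = n_hat,
       se = suppressWarnings(
         summary(fit)$coefficients["x", "Std. Error"]),
       ci = ci,
       d0_nm = exp(coef(fit)[["(Intercept)"]] / n_hat),
       fit = fit)
}
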