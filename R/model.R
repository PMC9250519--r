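#' Collagen model parameters
#'
#' Bundle of the single-axis collagen model parameters used throughout the
#' package: an intensity scale and the two independent second-order
#' susceptibility tensor ratios, plus the in-plane fibril orientation.
#'
#' Under cylindrical symmetry the collagen \eqn{\chi^{(2)}} tensor has three
#' nonzero elements \eqn{\chi_{15}, \chi_{31}, \chi_{33}}; all intensities are
#' normalised by \eqn{\chi_{15}}, so the model is parameterised by the ratios
#' \eqn{b = \chi_{31}/\chi_{15}} and \eqn{c = \chi_{33}/\chi_{15}}.
#'
#' @param i0 Intensity scale (arbitrary units), must be positive.
#' @param chi3115 Ratio \eqn{\chi_{31}/\chi_{15}} (dimensionless).
#' @param chi3315 Ratio \eqn{\chi_{33}/\chi_{15}} (dimensionless).
#' @param phi In-plane collagen orientation in degrees; normalised modulo 180.
#' @return An object of class `pshg_params`.
#' @examples
#' p <- pshg_params(i0 = 1, chi3115 = 1, chi3315 = 2, phi = 30)
#' shg_intensity(p, alpha = 30)
#' @export
pshg_params <- function(i0 = 1, chi3115 = 1, chi3315 = 2, phi = 0) {
  stopifnot(is.numeric(i0), length(i0) == 1, is.finite(i0),
            is.numeric(chi3115), length(chi3115) == 1, is.finite(chi3115),
            is.numeric(chi3315), length(chi3315) == 1, is.finite(chi3315),
            is.numeric(phi), length(phi) == 1, is.finite(phi))
  if (i0 <= 0) stop("`i0` must be > 0")
  structure(
    list(i0 = i0, chi3115 = chi3115, chi3315 = chi3315, phi = phi %% 180),
    class = "pshg_params"
  )
}

#' @export
print.pshg_params <- function(x, ...) {
  cat(sprintf(
    "<pshg_params> i0 = %g, chi31/chi15 = %g, chi33/chi15 = %g, phi = %g deg\n",
    x$i0, x$chi3115, x$chi3315, x$phi))
  invisible(x)
}

#' Canonical representative of the model parameters
#'
#' The single-axis model intensity is exactly invariant under the relabelling
#' \eqn{(b, c, \varphi) \to (c, b, \varphi + 90^\circ)}: the sign of the
#' first-harmonic Fourier coefficient cannot be determined from the data.
#' Fits and phantom ground truth are therefore reported in the canonical
#' representative with \eqn{\chi_{33}/\chi_{15} \ge \chi_{31}/\chi_{15}},
#' which matches the physically expected ordering for collagen
#' (\eqn{\chi_{31}/\chi_{15} \approx 1}, Kleinman symmetry, and
#' \eqn{\chi_{33}/\chi_{15} \approx 2}).
#'
#' @param params A [pshg_params()] object.
#' @return A `pshg_params` object with `chi3315 >= chi3115`.
#' @export
canonicalize_params <- function(params) {
  stopifnot(inherits(params, "pshg_params"))
  if (params$chi3315 >= params$chi3115) return(params)
  pshg_params(i0 = params$i0, chi3115 = params$chi3315,
              chi3315 = params$chi3115, phi = (params$phi + 90) %% 180)
}

#' Polarization-angle grids
#'
#' The acquisition grid holds 10 linear excitation polarization angles, 0 to
#' 180 degrees in 20-degree steps; since the SHG response has a 180-degree
#' period, the 0- and 180-degree frames are redundant and are averaged before
#' processing, leaving the 9-angle processing grid 0 to 160 degrees.
#'
#' @param which `"acquisition"` (10 angles, default) or `"processing"`
#'   (9 angles).
#' @return Numeric vector of angles in degrees.
#' @export
pshg_angles <- function(which = c("acquisition", "processing")) {
  which <- match.arg(which)
  if (which == "acquisition") seq(0, 180, by = 20) else seq(0, 160, by = 20)
}

#' Single-axis collagen model intensity
#'
#' SHG intensity generated by an in-plane collagen fibril under linearly
#' polarized excitation at angle `alpha`:
#' \deqn{I(\alpha) = I_0\,[\sin^2 2(\varphi-\alpha) +
#'   (b \sin^2(\varphi-\alpha) + c \cos^2(\varphi-\alpha))^2]}
#' with \eqn{b = \chi_{31}/\chi_{15}}, \eqn{c = \chi_{33}/\chi_{15}}.
#' The intensity is 180-degree periodic in `alpha` and depends on the angles
#' only through \eqn{\varphi - \alpha}.
#'
#' @param params A [pshg_params()] object.
#' @param alpha Excitation polarization angle(s) in degrees; vectorised.
#' @return Non-negative intensity, same length as `alpha`.
#' @export
shg_intensity <- function(params, alpha) {
  stopifnot(inherits(params, "pshg_params"), is.numeric(alpha))
  d <- deg2rad(params$phi - alpha)
  params$i0 * (sin(2 * d)^2 +
                 (params$chi3115 * sin(d)^2 + params$chi3315 * cos(d)^2)^2)
}

#' Closed-form Fourier coefficients of the collagen model
#'
#' The model intensity is a finite cosine series in \eqn{\Delta=\varphi-\alpha}:
#' \deqn{I(\alpha) = I_0\,[c_0 + c_1\cos 2\Delta + c_2\cos 4\Delta]}
#' with, writing \eqn{u = c - b} and \eqn{v = c + b},
#' \eqn{c_0 = 1/2 + v^2/4 + u^2/8}, \eqn{c_1 = uv/2 = (c^2-b^2)/2},
#' \eqn{c_2 = u^2/8 - 1/2}. All three are scaled by `i0`.
#'
#' @param params A [pshg_params()] object.
#' @return Named numeric vector `c(c0 = , c1 = , c2 = )` including the `i0`
#'   scale.
#' @export
fourier_coeffs_from_params <- function(params) {
  stopifnot(inherits(params, "pshg_params"))
  u <- params$chi3315 - params$chi3115
  v <- params$chi3315 + params$chi3115
  params$i0 * c(c0 = 0.5 + v^2 / 4 + u^2 / 8,
                c1 = u * v / 2,
                c2 = u^2 / 8 - 0.5)
}

#' Helical pitch angle from the chi33/chi15 ratio
#'
#' The orientation of the dominant hyperpolarizability axis, interpreted as
#' the collagen triple-helix pitch angle, satisfies
#' \eqn{\cos^2\theta_e = r/(2+r)} with \eqn{r = \chi_{33}/\chi_{15}},
#' equivalently \eqn{\tan^2\theta_e = 2/r}. The function is strictly
#' decreasing in `r`, maps `r = 2` to exactly 45 degrees, and tends to 0
#' degrees as `r` grows.
#'
#' @param r Ratio \eqn{\chi_{33}/\chi_{15}}; must be positive. Vectorised;
#'   `NA`/`NaN` pass through.
#' @return Pitch angle in degrees, in (0, 90).
#' @export
theta_from_ratio <- function(r) {
  stopifnot(is.numeric(r))
  bad <- is.finite(r) & r <= 0
  if (any(bad)) stop("`r` must be > 0 (chi33/chi15 ratio)")
  .theta_from_ratio(r)
}

# vectorised, NaN-tolerant version used on maps (non-positive -> NaN)
.theta_from_ratio <- function(r) {
  out <- rep(NaN, length(r))
  ok <- is.finite(r) & r > 0
  out[ok] <- rad2deg(acos(sqrt(r[ok] / (2 + r[ok]))))
  out
}
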