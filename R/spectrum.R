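#' Average the redundant endpoint frames of a stack
#'
#' The SHG response is 180-degree periodic, so the 0- and 180-degree frames
#' of a 10-frame acquisition are ideally identical; the pair is averaged
#' (in floating point) and the processing stack keeps 9 frames at 0 to 160
#' degrees.
#'
#' @param stack A `height x width x 10` array (frames ordered by angle).
#' @return A `height x width x 9` array of class `pshg_stack`, frames at
#'   0, 20, ..., 160 degrees.
#' @export
average_endpoint_frames <- function(stack) {
  stack <- unclass(stack)
  d <- dim(stack)
  if (length(d) != 3 || d[3] != 10)
    stop(sprintf("expected a 10-frame stack, got %s frames",
                 if (length(d) == 3) d[3] else "a non-3D array"))
  out <- stack[, , 1:9, drop = FALSE]
  out[, , 1] <- (stack[, , 1] + stack[, , 10]) / 2
  structure(out, angles = pshg_angles("processing"), class = "pshg_stack")
}

# 9-point forward DFT matrix: G_k = sum_n x_n exp(-2*pi*i*k*n/9)
.dft9 <- function() {
  n <- 0:8
  exp(-2i * pi * outer(n, n) / 9)
}

new_harmonic_spectrum <- function(g, valid = TRUE) {
  chat <- c(Mod(g[1]) / 9, 2 * Mod(g[2:5]) / 9)
  structure(
    list(g = g, chat = chat, phase1 = Arg(g[2]), phase2 = Arg(g[3]),
         valid = valid),
    class = "harmonic_spectrum"
  )
}

#' Discrete Fourier spectrum of one pixel's polarization series
#'
#' Computes the 9-point DFT (forward convention
#' \eqn{G_k = \sum_n x_n e^{-2\pi i k n/9}}) of the endpoint-averaged
#' polarization series of a pixel. Because the angular step is 20 degrees
#' over a 180-degree period, the model's \eqn{\cos 2(\varphi-\alpha)} and
#' \eqn{\cos 4(\varphi-\alpha)} terms land exactly in frequency bins 1
#' and 2. The folded real amplitudes are
#' \eqn{\hat c_0 = |G_0|/9}, \eqn{\hat c_k = 2|G_k|/9} for k = 1..4;
#' bins 5..8 are conjugates of 4..1 for real input.
#'
#' @param series Numeric vector of 9 intensities, ordered by the processing
#'   grid 0, 20, ..., 160 degrees.
#' @return An object of class `harmonic_spectrum` with elements `g`
#'   (complex bins 0..8), `chat` (folded amplitudes 0..4), `phase1`,
#'   `phase2` (arguments of bins 1 and 2), and `valid`. Non-finite input
#'   yields an invalid spectrum (all-`NaN`).
#' @export
pixel_dft <- function(series) {
  stopifnot(is.numeric(series))
  if (length(series) != 9)
    stop("expected 9 values (endpoint-averaged series); see average_endpoint_frames()")
  if (!all(is.finite(series)))
    return(new_harmonic_spectrum(rep(NaN + 0i, 9), valid = FALSE))
  new_harmonic_spectrum(fft(series))
}

#' @export
print.harmonic_spectrum <- function(x, ...) {
  cat("<harmonic_spectrum> folded amplitudes c0..c4:\n")
  print(signif(x$chat, 6))
  invisible(x)
}

#' Invert signed harmonic moments to model parameters
#'
#' Solves the closed-form relations between the signed harmonic amplitudes
#' \eqn{M_0 = I_0 c_0}, \eqn{M_1 = I_0 c_1}, \eqn{M_2 = I_0 c_2} of the
#' collagen model and its parameters. Eliminating \eqn{u = c-b},
#' \eqn{v = c+b} gives the quadratic
#' \deqn{I_0^2 + I_0 (3M_2 - M_0) + (M_1^2/4 - 2 M_2 M_0 + 2 M_2^2) = 0,}
#' then \eqn{u^2 = (8M_2 + 4I_0)/I_0} and \eqn{v^2 = 4(M_0 - M_2 - I_0)/I_0}.
#' Root selection: among real roots with \eqn{I_0 > 0}, \eqn{u^2 \ge 0},
#' \eqn{v^2 \ge 0}, roots giving \eqn{b \ge 0} are preferred; if both
#' qualify the one with smaller \eqn{|b - 1|} wins (Kleinman-symmetry
#' prior, \eqn{\chi_{31}/\chi_{15}} close to unity). The sign of \eqn{u}
#' follows the sign of \eqn{M_1}; \eqn{v \ge 0} always.
#'
#' @param m0,m1,m2 Signed moment vectors (equal length); vectorised.
#' @return List of vectors `i0`, `b`, `c`; `NaN` where no admissible
#'   (physical) root exists.
#' @export
invert_moments <- function(m0, m1, m2) {
  stopifnot(length(m0) == length(m1), length(m1) == length(m2))
  n <- length(m0)
  B <- 3 * m2 - m0
  C <- m1^2 / 4 - 2 * m2 * m0 + 2 * m2^2
  disc <- B^2 - 4 * C
  # tolerate tiny negative discriminants from rounding
  disc[disc < 0 & disc > -.ffpshg_eps * pmax(B^2, 1)] <- 0
  sq <- sqrt(ifelse(disc >= 0, disc, NaN))
  roots <- cbind((-B + sq) / 2, (-B - sq) / 2)

  eval_root <- function(i0) {
    u2 <- (8 * m2 + 4 * i0) / i0
    v2 <- 4 * (m0 - m2 - i0) / i0
    scale <- pmax(abs(m0), 1)
    u2[u2 < 0 & u2 > -.ffpshg_eps * scale] <- 0
    v2[v2 < 0 & v2 > -.ffpshg_eps * scale] <- 0
    ok <- is.finite(i0) & i0 > 0 & u2 >= 0 & v2 >= 0
    u <- ifelse(m1 < 0, -1, 1) * sqrt(ifelse(ok, u2, NaN))
    v <- sqrt(ifelse(ok, v2, NaN))
    b <- (v - u) / 2
    b[ok & b < 0 & b > -.ffpshg_eps * scale] <- 0
    list(ok = ok, i0 = i0, b = b, c = (v + u) / 2)
  }
  r1 <- eval_root(roots[, 1])
  r2 <- eval_root(roots[, 2])

  # preference: admissible & b >= 0 first, then admissible; tie-break |b-1|
  score <- function(r) {
    s <- rep(Inf, n)
    adm <- r$ok
    s[adm] <- abs(r$b[adm] - 1) + 1e6           # admissible but b < 0
    good <- adm & r$b >= 0
    s[good] <- abs(r$b[good] - 1)               # physical solution
    s
  }
  s1 <- score(r1); s2 <- score(r2)
  use1 <- s1 <= s2
  pick <- function(f) ifelse(use1, r1[[f]], r2[[f]])
  none <- !is.finite(s1) & !is.finite(s2)
  bad_b <- pmin(s1, s2) >= 1e6                  # only b < 0 solutions exist
  out_i0 <- pick("i0"); out_b <- pick("b"); out_c <- pick("c")
  drop <- none | bad_b
  out_i0[drop] <- NaN; out_b[drop] <- NaN; out_c[drop] <- NaN
  list(i0 = out_i0, b = out_b, c = out_c)
}

# Orientation and signed moments from DFT bins; vectorised over pixels.
# g1, g2: complex bins 1 and 2; g0: real bin 0; returns phi (deg), m0, m1, m2.
.moments_from_bins <- function(g0, g1, g2) {
  c0 <- Mod(g0) / 9
  c1 <- 2 * Mod(g1) / 9
  c2 <- 2 * Mod(g2) / 9
  tol <- .ffpshg_eps * pmax(c0, .Machine$double.eps)
  use1 <- c1 > tol
  # from bin 1 (model: G1 = (9/2) I0 c1 e^{-2 i phi}, with c1 >= 0 canonical)
  phi1 <- (-rad2deg(Arg(g1)) / 2) %% 180
  # from bin 2 with c2 < 0 (b = c case): G2 = (9/2) I0 c2 e^{-4 i phi}
  phi2 <- (rad2deg(pi - Arg(g2)) / 4) %% 180
  phi <- ifelse(use1, phi1, phi2)
  ph <- deg2rad(phi)
  m0 <- Re(g0) / 9
  m1 <- 2 * Re(g1 * exp(2i * ph)) / 9
  m2 <- 2 * Re(g2 * exp(4i * ph)) / 9
  list(phi = phi, m0 = m0, m1 = m1, m2 = m2, degenerate = !use1 & c2 <= tol)
}

#' Invert a harmonic spectrum to collagen parameters
#'
#' Recovers the orientation from the harmonic phases
#' (\eqn{\varphi = -\arg G_1 / 2} mod 180, with \eqn{\arg G_2} fixing the
#' sign of the second harmonic when the first vanishes), forms signed
#' moments by projecting the bins onto the recovered orientation, and
#' solves the closed-form inversion of [invert_moments()]. The result is
#' reported in the canonical representative
#' \eqn{\chi_{33}/\chi_{15} \ge \chi_{31}/\chi_{15}}
#' (see [canonicalize_params()]).
#'
#' @param spectrum A `harmonic_spectrum` from [pixel_dft()].
#' @return An object of class `collagen_fit`: list with `i0`, `chi3115`,
#'   `chi3315`, `chi3331`, `phi` (degrees in \[0, 180)), `theta_e`
#'   (degrees). All `NaN` for degenerate spectra (no harmonic content) or
#'   when no physical solution exists.
#' @export
invert_spectrum <- function(spectrum) {
  stopifnot(inherits(spectrum, "harmonic_spectrum"))
  nan_fit <- structure(
    list(i0 = NaN, chi3115 = NaN, chi3315 = NaN, chi3331 = NaN,
         phi = NaN, theta_e = NaN),
    class = "collagen_fit")
  if (!isTRUE(spectrum$valid)) return(nan_fit)
  mm <- .moments_from_bins(spectrum$g[1], spectrum$g[2], spectrum$g[3])
  if (mm$degenerate) return(nan_fit)
  sol <- invert_moments(mm$m0, mm$m1, mm$m2)
  if (!is.finite(sol$i0)) return(nan_fit)
  structure(
    list(i0 = sol$i0, chi3115 = sol$b, chi3315 = sol$c,
         chi3331 = sol$c / sol$b, phi = mm$phi,
         theta_e = .theta_from_ratio(sol$c)),
    class = "collagen_fit")
}

#' @export
print.collagen_fit <- function(x, ...) {
  cat(sprintf(paste0(
    "<collagen_fit> i0 = %.6g, chi31/chi15 = %.6g, chi33/chi15 = %.6g,\n",
    "  chi33/chi31 = %.6g, phi = %.4g deg, theta_e = %.4g deg\n"),
    x$i0, x$chi3115, x$chi3315, x$chi3331, x$phi, x$theta_e))
  invisible(x)
}

#' Coefficient of determination of a per-pixel fit
#'
#' \eqn{R^2 = 1 - SSR/SST} over the 10 originally acquired values:
#' predictions come from the fitted model evaluated at all 10 acquisition
#' angles, \eqn{SSR = \sum (x_i - y_i)^2},
#' \eqn{SST = \sum (x_i - \bar x)^2}.
#'
#' @param series Numeric vector of the 10 acquired intensities.
#' @param fit A `collagen_fit` object.
#' @param angles Acquisition angles (degrees), default 0..180 step 20.
#' @return `r2`, or `NaN` for an invalid fit or a constant series
#'   (`SST = 0`).
#' @export
compute_r2 <- function(series, fit, angles = pshg_angles()) {
  stopifnot(inherits(fit, "collagen_fit"), is.numeric(series),
            length(series) == length(angles))
  if (!is.finite(fit$i0)) return(NaN)
  p <- pshg_params(fit$i0, fit$chi3115, fit$chi3315, fit$phi)
  y <- shg_intensity(p, angles)
  sst <- sum((series - mean(series))^2)
  if (sst == 0) return(NaN)
  1 - sum((series - y)^2) / sst
}

#' Spectral error ratio
#'
#' Ratio of the mean non-model harmonic amplitude to the mean model
#' harmonic amplitude. With 9 samples only harmonics 0..4 exist; the
#' model occupies harmonics 0..2, so
#' \eqn{ERR = \mathrm{mean}(\hat c_3, \hat c_4) /
#'   \mathrm{mean}(\hat c_0, \hat c_1, \hat c_2)}. Clean model data give
#' ERR near 0; pure noise gives ERR near 1.
#'
#' @param spectrum A `harmonic_spectrum`.
#' @return `err >= 0`, or `NaN` when the denominator is zero or the
#'   spectrum invalid.
#' @export
compute_err <- function(spectrum) {
  stopifnot(inherits(spectrum, "harmonic_spectrum"))
  if (!isTRUE(spectrum$valid)) return(NaN)
  den <- mean(spectrum$chat[1:3])
  if (!is.finite(den) || den <= 0) return(NaN)
  mean(spectrum$chat[4:5]) / den
}

#' Spectral signal-to-noise ratio in dB
#'
#' \eqn{SNR_{dB} = 10\log_{10}[(|G_1|^2 + |G_2|^2) /
#'   (|G_3|^2 + |G_4|^2 + |G_5|^2 + |G_6|^2)]} on the 9-point DFT. Bins 1
#' and 2 hold the model's harmonic content; bins 3..6 have no biophysical
#' meaning (5 and 6 are the conjugates of 4 and 3). The value is capped at
#' +99 dB; `NaN` when both sums vanish.
#'
#' @param spectrum A `harmonic_spectrum`.
#' @return SNR in dB, at most 99.
#' @export
compute_snr <- function(spectrum) {
  stopifnot(inherits(spectrum, "harmonic_spectrum"))
  if (!isTRUE(spectrum$valid)) return(NaN)
  sig <- sum(Mod(spectrum$g[2:3])^2)
  noi <- sum(Mod(spectrum$g[4:7])^2)
  if (noi == 0) {
    if (sig > 0) return(99)
    return(NaN)
  }
  min(99, 10 * log10(sig / noi))
}
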