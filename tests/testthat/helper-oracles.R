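# Independent oracles used across the suite. These never call the
# package's inversion path.

# model intensity written out directly (degrees)
oracle_intensity <- function(i0, b, c, phi, alpha) {
  d <- (phi - alpha) * pi / 180
  i0 * (sin(2 * d)^2 + (b * sin(d)^2 + c * cos(d)^2)^2)
}

# numeric projection of the model onto cos(2k * (phi - alpha)) over a
# dense alpha grid: independent route to the closed-form coefficients
oracle_fourier_coeffs <- function(i0, b, c, phi, n = 3600) {
  alpha <- seq(0, 180, length.out = n + 1)[-(n + 1)]
  ii <- oracle_intensity(i0, b, c, phi, alpha)
  d <- (phi - alpha) * pi / 180
  c(c0 = mean(ii),
    c1 = 2 * mean(ii * cos(2 * d)),
    c2 = 2 * mean(ii * cos(4 * d)))
}

# multi-start nonlinear least-squares fit of the model to one 9-sample
# series; returns parameters in the canonical representative (c >= b)
oracle_nls_fit <- function(series, angles = seq(0, 160, by = 20)) {
  best <- NULL
  dat <- data.frame(y = series, alpha = angles)
  for (phi0 in seq(5, 175, by = 30)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ i0 * (sin(2 * (phi - alpha) * pi / 180)^2 +
                    (b * sin((phi - alpha) * pi / 180)^2 +
                       c * cos((phi - alpha) * pi / 180)^2)^2),
        data = dat,
        start = list(i0 = max(mean(series), 1e-3), b = 1, c = 2, phi = phi0),
        lower = c(1e-9, 0, 0, -360), upper = c(Inf, 10, 10, 540),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                             ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ss <- sum(residuals(fit)^2)
    if (is.null(best) || ss < best$ss)
      best <- c(as.list(coef(fit)), list(ss = ss))
  }
  stopifnot(!is.null(best))
  b <- best$b; cc <- best$c; phi <- best$phi %% 180
  if (cc < b) { tmp <- b; b <- cc; cc <- tmp; phi <- (phi + 90) %% 180 }
  list(i0 = best$i0, b = b, c = cc, phi = phi, ss = best$ss)
}

# absolute difference between two orientations defined modulo 180 degrees
phi_dist <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# single-region full-frame phantom, optionally noiseless floating point
flat_phantom <- function(h = 8, w = 8, i0 = 50, b = 1, c = 2, phi = 30,
                         noise = "none", noise_sd = 2, background = 0,
                         bit_depth = NA, seed = 1) {
  phantom_spec(h, w,
               list(list(mask = matrix(TRUE, h, w),
                         params = pshg_params(i0, b, c, phi))),
               background_level = background, noise = noise,
               noise_sd = noise_sd, bit_depth = bit_depth, seed = seed)
}

# tiled phantom covering a parameter sweep; returns spec
sweep_phantom <- function(h, w, bs, cs, phis, i0 = 50) {
  combos <- expand.grid(b = bs, c = cs, phi = phis)
  n <- nrow(combos)
  ncol_t <- ceiling(sqrt(n))
  nrow_t <- ceiling(n / ncol_t)
  rcut <- round(seq(0, h, length.out = nrow_t + 1))
  ccut <- round(seq(0, w, length.out = ncol_t + 1))
  regions <- vector("list", n)
  for (k in seq_len(n)) {
    ti <- (k - 1) %/% ncol_t + 1
    tj <- (k - 1) %% ncol_t + 1
    m <- matrix(FALSE, h, w)
    m[(rcut[ti] + 1):rcut[ti + 1], (ccut[tj] + 1):ccut[tj + 1]] <- TRUE
    regions[[k]] <- list(mask = m,
                         params = pshg_params(i0, combos$b[k], combos$c[k],
                                              combos$phi[k]))
  }
  phantom_spec(h, w, regions, background_level = 0, noise = "none",
               bit_depth = NA)
}
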