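test_that("endpoint averaging reduces 10 frames to 9", {
  st <- array(runif(4 * 4 * 10), dim = c(4, 4, 10))
  out <- average_endpoint_frames(st)
  expect_equal(dim(out), c(4, 4, 9))
  expect_equal(attr(out, "angles"), seq(0, 160, by = 20))
  expect_equal(unclass(out)[, , 1], (st[, , 1] + st[, , 10]) / 2)
  expect_equal(unclass(out)[, , 2:9], st[, , 2:9])
  # idempotent when the endpoints agree
  st[, , 10] <- st[, , 1]
  expect_equal(unclass(average_endpoint_frames(st))[, , 1], st[, , 1])
  expect_error(average_endpoint_frames(st[, , 1:9]), "10-frame")
})

test_that("pixel DFT recovers the harmonic content of model data", {
  # constant series: DC only
  sp <- pixel_dft(rep(5, 9))
  expect_equal(sp$chat, c(5, 0, 0, 0, 0))
  # model series at phi = 0 with known coefficients (2.875, 1.5, -0.375)
  a <- seq(0, 160, by = 20)
  s <- oracle_intensity(1, 1, 2, 0, a)
  sp <- pixel_dft(s)
  expect_equal(sp$chat[1], 2.875, tolerance = 1e-12)
  expect_equal(sp$chat[2], 1.5, tolerance = 1e-12)
  expect_equal(sp$chat[3], 0.375, tolerance = 1e-12)
  expect_equal(sp$chat[4], 0, tolerance = 1e-12)
  expect_equal(sp$chat[5], 0, tolerance = 1e-12)
  # the negative c2 appears as a pi phase in bin 2
  expect_equal(abs(sp$phase2), pi, tolerance = 1e-9)
  # cross-check against direct trigonometric regression on the 9 samples
  X <- cbind(1, cos(2 * -a * pi / 180), cos(4 * -a * pi / 180))
  beta <- solve(crossprod(X), crossprod(X, s))
  expect_equal(as.numeric(beta), c(2.875, 1.5, -0.375), tolerance = 1e-9)
})

test_that("DFT satisfies conjugate symmetry and Parseval's identity", {
  set.seed(5)
  for (i in 1:100) {
    s <- runif(9, 0, 100)
    sp <- pixel_dft(s)
    expect_equal(Mod(sp$g[9:6]), Mod(sp$g[2:5]), tolerance = 1e-9)
    expect_equal(sum((s - mean(s))^2), sum(Mod(sp$g[2:9])^2) / 9,
                 tolerance = 1e-8)
  }
})

test_that("non-finite series yields an invalid spectrum and NaN fit", {
  sp <- pixel_dft(c(1, 2, NA, 4:9))
  expect_false(sp$valid)
  expect_true(is.nan(invert_spectrum(sp)$i0))
  expect_true(is.nan(compute_err(sp)))
  expect_error(pixel_dft(1:10), "9 values")
})

test_that("moment inversion solves the quadratic and applies the root rules", {
  # hand-expanded case: roots I0 in {1, 3}; root 3 gives b < 0, rejected
  sol <- invert_moments(2.875, 1.5, -0.375)
  expect_equal(sol$i0, 1)
  expect_equal(sol$b, 1)
  expect_equal(sol$c, 2)
  # round trips through the closed-form coefficients
  set.seed(6)
  for (i in 1:50) {
    b <- runif(1, 0.2, 3); cc <- runif(1, b, 4); i0 <- runif(1, 0.5, 20)
    co <- fourier_coeffs_from_params(pshg_params(i0, b, cc, 0))
    sol <- invert_moments(co[["c0"]], co[["c1"]], co[["c2"]])
    expect_equal(sol$i0, i0, tolerance = 1e-8)
    expect_equal(sol$b, b, tolerance = 1e-8)
    expect_equal(sol$c, cc, tolerance = 1e-8)
  }
})

test_that("spectrum inversion recovers clean pixels and flags degenerate ones", {
  a <- seq(0, 160, by = 20)
  f <- invert_spectrum(pixel_dft(oracle_intensity(1, 1, 2, 30, a)))
  expect_equal(f$i0, 1, tolerance = 1e-9)
  expect_equal(f$chi3115, 1, tolerance = 1e-9)
  expect_equal(f$chi3315, 2, tolerance = 1e-9)
  expect_equal(f$chi3331, 2, tolerance = 1e-9)
  expect_equal(f$phi, 30, tolerance = 1e-9)
  expect_equal(f$theta_e, 45, tolerance = 1e-9)
  # internal consistency of the derived fields
  expect_equal(f$chi3331 * f$chi3115, f$chi3315, tolerance = 1e-9)
  expect_equal(f$theta_e, theta_from_ratio(f$chi3315), tolerance = 1e-12)
  # constant series has no harmonic content
  expect_true(all(is.nan(unlist(invert_spectrum(pixel_dft(rep(3, 9)))))))
})

test_that("degenerate b = c pixels still recover the ratio pair", {
  # with b = c the model is 90-degree periodic; orientation comes from the
  # second harmonic alone, defined modulo 90
  a <- seq(0, 160, by = 20)
  f <- invert_spectrum(pixel_dft(oracle_intensity(2, 1.5, 1.5, 70, a)))
  expect_equal(f$chi3115, 1.5, tolerance = 1e-8)
  expect_equal(f$chi3315, 1.5, tolerance = 1e-8)
  expect_equal(f$i0, 2, tolerance = 1e-8)
  expect_lt(phi_dist(f$phi %% 90, 70 %% 90), 1e-6)
})

test_that("R-squared follows its definition", {
  a10 <- seq(0, 180, by = 20)
  s <- oracle_intensity(3, 1, 2, 40, a10)
  f <- invert_spectrum(pixel_dft(oracle_intensity(3, 1, 2, 40,
                                                  seq(0, 160, by = 20))))
  expect_equal(compute_r2(s, f), 1, tolerance = 1e-9)
  # residuals constructed for SSR/SST = 0.25 exactly
  y <- oracle_intensity(3, 1, 2, 40, a10)
  resid <- rep(c(1, -1), 5)
  x <- y + resid
  # rescale the residual pattern so SSR/SST hits 0.25 on the perturbed data
  ssr <- sum((x - y)^2); sst <- sum((x - mean(x))^2)
  lam <- sqrt(0.25 * sst / ssr)  # first-order; iterate to convergence
  for (k in 1:60) {
    x <- y + lam * resid
    ssr <- sum((x - y)^2); sst <- sum((x - mean(x))^2)
    lam <- lam * sqrt(0.25 * sst / ssr)
  }
  expect_equal(1 - ssr / sst, 0.75, tolerance = 1e-6)
  expect_equal(compute_r2(x, f), 1 - ssr / sst, tolerance = 1e-9)
  # constant series: SST = 0 -> NaN
  fconst <- invert_spectrum(pixel_dft(oracle_intensity(3, 1, 2, 40,
                                                       seq(0, 160, 20))))
  expect_true(is.nan(compute_r2(rep(2, 10), fconst)))
})

test_that("spectral error ratio separates clean signal from noise", {
  a <- seq(0, 160, by = 20)
  expect_lt(compute_err(pixel_dft(oracle_intensity(5, 1, 2, 25, a))), 1e-12)
  # constructed series with c3 = c4 = mean(c0, c1, c2) gives exactly 1
  g <- rep(0 + 0i, 9)
  g[1] <- 9 * 3            # c0 = 3
  g[2] <- 9 / 2 * 3        # c1 = 3
  g[3] <- 9 / 2 * 3        # c2 = 3
  g[4] <- 9 / 2 * 3; g[5] <- 9 / 2 * 3
  sp <- ffpshg:::new_harmonic_spectrum(g)
  expect_equal(compute_err(sp), 1)
  # iid noise with small positive mean: median over many draws near unity
  set.seed(8)
  errs <- replicate(1000, compute_err(pixel_dft(pmax(rnorm(9, 2, 2), 0))))
  expect_gt(median(errs), 0.5)
  expect_lt(median(errs), 1.5)
})

test_that("SNR handles the cap, exact ratios and conjugate folding", {
  a <- seq(0, 160, by = 20)
  expect_equal(compute_snr(pixel_dft(oracle_intensity(5, 1, 2, 25, a))), 99)
  mk <- function(g) ffpshg:::new_harmonic_spectrum(g)
  # signal power exactly 10x the noise power
  g <- rep(0 + 0i, 9); g[2] <- sqrt(10); g[4] <- 1
  expect_equal(compute_snr(mk(g)), 10)
  # |G1| = |G2| = |G3| = |G4| with conjugate bins doubles the noise sum
  g <- rep(1 + 0i, 9)
  expect_equal(compute_snr(mk(g)), 10 * log10(2 / 4), tolerance = 1e-9)
  expect_equal(compute_snr(mk(g)), -3.0103, tolerance = 1e-4)
  # all-zero spectrum
  expect_true(is.nan(compute_snr(mk(rep(0 + 0i, 9)))))
})
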