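test_that("window masks enumerate the stated pixel memberships", {
  expect_equal(sum(window_mask("square", 3)), 9)
  expect_equal(sum(window_mask("square", 7)), 49)
  expect_equal(sum(window_mask("square", 15)), 225)
  # brute-force enumeration of dx^2 + dy^2 <= r^2
  for (sz in c(3, 7, 15)) {
    r <- (sz - 1) / 2
    cnt <- sum(outer(-r:r, -r:r, function(dy, dx) dx^2 + dy^2 <= r^2))
    expect_equal(sum(window_mask("circular", sz)), cnt)
  }
  expect_equal(sum(window_mask("circular", 3)), 5)
  expect_equal(sum(window_mask("circular", 7)), 29)
  expect_equal(sum(window_mask("circular", 15)), 149)
  expect_error(window_mask("square", 4), "unsupported")
  expect_error(window_mask("circular", 9), "unsupported")
})

test_that("constant images have zero entropy, SD and MAD", {
  img <- matrix(3.3, 9, 9)
  for (est in c("ENT", "SD", "MAD")) {
    m <- local_dispersion(img, est, "square", 3, range = c(0, 5))
    expect_true(all(m[2:8, 2:8] == 0))
  }
})

test_that("entropy follows the occurrence-rate formula", {
  # centre window holds 5 pixels of one value and 4 of another
  img <- matrix(c(rep(1, 5), rep(2, 4)), 3, 3)
  e <- local_dispersion(img, "ENT", "square", 3, range = c(0, 5))
  expect_equal(e[2, 2], -(5 / 9 * log2(5 / 9) + 4 / 9 * log2(4 / 9)),
               tolerance = 1e-9)
  expect_equal(e[2, 2], 0.9911, tolerance = 1e-4)
  # nine all-distinct bins: uniform maximum log2(9)
  img9 <- matrix(seq(0.1, 4.9, length.out = 9), 3, 3)
  e9 <- local_dispersion(img9, "ENT", "square", 3, range = c(0, 5))
  expect_equal(e9[2, 2], log2(9), tolerance = 1e-9)
})

test_that("entropy is invariant to bin-preserving monotone relabeling", {
  set.seed(41)
  img <- matrix(runif(49, 0, 5), 7, 7)
  e1 <- local_dispersion(img, "ENT", "square", 3, range = c(0, 5))
  # affine map onto a new range, quantized over that range: same bins
  e2 <- local_dispersion(img * 2 + 1, "ENT", "square", 3, range = c(1, 11))
  expect_equal(e1, e2, tolerance = 1e-12)
})

test_that("SD and MAD match direct formulas on a known window", {
  # centre 5-window (circular size 3) holding exactly {1, 2, 3, 4, 100}
  img <- matrix(0, 3, 3)
  img[2, 2] <- 3; img[1, 2] <- 1; img[3, 2] <- 2; img[2, 1] <- 4
  img[2, 3] <- 100
  v <- c(1, 2, 3, 4, 100)
  sd_o <- sqrt(mean((v - mean(v))^2))   # population SD, 39.0128
  mad_o <- median(abs(v - median(v)))   # 1
  expect_equal(local_dispersion(img, "SD", "circular", 3)[2, 2], sd_o,
               tolerance = 1e-9)
  expect_equal(local_dispersion(img, "MAD", "circular", 3)[2, 2], mad_o,
               tolerance = 1e-12)
})

test_that("MAD is less outlier-sensitive than SD", {
  set.seed(42)
  base <- matrix(rnorm(15 * 15, 50, 2), 15, 15)
  out <- base; out[8, 8] <- out[8, 8] + 500
  d_sd <- abs(local_dispersion(out, "SD", "square", 15)[8, 8] -
                local_dispersion(base, "SD", "square", 15)[8, 8])
  d_mad <- abs(local_dispersion(out, "MAD", "square", 15)[8, 8] -
                 local_dispersion(base, "MAD", "square", 15)[8, 8])
  expect_lt(d_mad, d_sd)
})

test_that("SD and MAD are translation invariant and scale equivariant", {
  set.seed(43)
  img <- matrix(runif(64, 0, 10), 8, 8)
  for (est in c("SD", "MAD")) {
    m <- local_dispersion(img, est, "square", 3)
    expect_equal(local_dispersion(img + 7, est, "square", 3), m,
                 tolerance = 1e-9)
    expect_equal(local_dispersion(img * -2.5, est, "square", 3), 2.5 * m,
                 tolerance = 1e-9)
  }
})

test_that("valid-fraction rule yields NaN at borders and over NaN fields", {
  img <- matrix(1, 6, 6)
  m <- local_dispersion(img, "SD", "square", 3, min_valid_fraction = 0.5)
  expect_true(is.nan(m[1, 1]))      # corner: 4/9 coverage
  expect_false(is.nan(m[1, 2]))     # edge: 6/9 coverage
  img[2:5, 2:5] <- NaN
  m2 <- local_dispersion(img, "SD", "square", 3, min_valid_fraction = 0.5)
  expect_true(is.nan(m2[3, 3]))
  all_nan <- matrix(NaN, 5, 5)
  for (est in c("ENT", "SD", "MAD"))
    expect_true(all(is.nan(local_dispersion(all_nan, est, "square", 3,
                                            range = c(0, 5)))))
})

test_that("broad orientation spread raises local SD and MAD over narrow spread", {
  set.seed(44)
  h <- 21; w <- 40
  fi <- matrix(NA_real_, h, w)
  fi[, 1:20] <- (90 + rnorm(h * 20, sd = 2)) %% 180    # narrow
  fi[, 21:40] <- runif(h * 20, 0, 180)                 # broad
  for (est in c("SD", "MAD")) {
    m <- local_dispersion(fi, est, "circular", 15)
    narrow <- median(m[, 8:13], na.rm = TRUE)
    broad <- median(m[, 28:33], na.rm = TRUE)
    expect_gt(broad, narrow)
  }
})

test_that("circular orientation statistics remove the 0/180 seam bias", {
  set.seed(45)
  # tight distribution straddling the seam: linear SD is inflated,
  # axial-circular SD stays small
  img <- matrix((rnorm(11 * 11, 0, 2)) %% 180, 11, 11)
  lin <- local_dispersion(img, "SD", "square", 7)
  circ <- local_dispersion(img, "SD", "square", 7, circular = TRUE)
  expect_gt(lin[6, 6], 45)
  expect_lt(circ[6, 6], 5)
})

test_that("the full dispersion set holds 90 correctly named maps", {
  spec <- flat_phantom(9, 9, noise = "gaussian", noise_sd = 2, seed = 3,
                       background = 2, bit_depth = 8)
  f <- fit_stack(generate_stack(spec))
  dm <- dispersion_set(f)
  expect_length(dm, 90)
  expect_true(all(grepl(
    "^(CHI3115|CHI3315|CHI3331|FI|THETA)_(ENT|SD|MAD)_(square|circular)_(3|7|15)$",
    names(dm))))
  expect_equal(length(unique(names(dm))), 90)
  expect_true(all(vapply(dm, function(m) identical(dim(m), c(9L, 9L)),
                         logical(1))))
  # all-NaN parameter maps propagate
  blank <- list(CHI3115 = matrix(NaN, 4, 4), CHI3315 = matrix(NaN, 4, 4),
                CHI3331 = matrix(NaN, 4, 4), FI = matrix(NaN, 4, 4),
                THETA = matrix(NaN, 4, 4))
  dmn <- dispersion_set(blank, windows = data.frame(shape = "square",
                                                    size = 3))
  expect_true(all(vapply(dmn, function(m) all(is.nan(m)), logical(1))))
  expect_error(dispersion_set(blank[-1], windows = data.frame(
    shape = "square", size = 3)), "missing parameter map")
})
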