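#' Fit the collagen model to every pixel of a polarization stack
#'
#' Runs the full FF-PSHG analysis: endpoint averaging, per-pixel 9-point
#' DFT, closed-form inversion to the model parameters, and the three
#' fitting-quality estimators. All pixels are processed in one vectorised
#' pass. Pixels whose series is non-finite, has no harmonic content
#' (constant series), or admits no physical solution carry `NaN` in the
#' five structural maps and in `R2`; `ERR` and `SNR` are computed wherever
#' the spectrum is finite since they describe the data, not the fit.
#'
#' @param stack A `height x width x 10` array, frames ordered by the
#'   acquisition angles 0..180 in 20-degree steps.
#' @return An object of class `pshg_maps`: a list with element `maps`
#'   holding the eight planar maps `CHI3115`, `CHI3315`, `CHI3331`, `FI`,
#'   `THETA`, `R2`, `SNR`, `ERR` (each `height x width`).
#' @examples
#' msk <- matrix(TRUE, 8, 8)
#' spec <- phantom_spec(8, 8, list(list(mask = msk, params = pshg_params())),
#'                      background_level = 0, noise = "none", bit_depth = NA)
#' fit <- fit_stack(generate_stack(spec))
#' range(fit$maps$FI)
#' @export
fit_stack <- function(stack) {
  stack <- unclass(stack)
  d <- dim(stack)
  if (length(d) != 3 || d[3] != 10)
    stop("expected a height x width x 10 stack")
  h <- d[1]; w <- d[2]; npix <- h * w
  angles <- pshg_angles()

  x10 <- matrix(stack, npix, 10)
  x9 <- x10[, 1:9, drop = FALSE]
  x9[, 1] <- (x10[, 1] + x10[, 10]) / 2

  finite <- rowSums(is.finite(x9)) == 9L & rowSums(is.finite(x10)) == 10L
  x9f <- x9
  x9f[!finite, ] <- 0  # placeholder rows; masked out below

  g <- mvfft(t(x9f))                      # 9 x npix, bins 0..8
  c0 <- Mod(g[1, ]) / 9
  c1 <- 2 * Mod(g[2, ]) / 9
  c2 <- 2 * Mod(g[3, ]) / 9
  tol <- .ffpshg_eps * pmax(c0, .Machine$double.eps)
  use1 <- c1 > tol
  degenerate <- !use1 & c2 <= tol

  phi <- ifelse(use1,
                (-rad2deg(Arg(g[2, ])) / 2) %% 180,
                (rad2deg(pi - Arg(g[3, ])) / 4) %% 180)
  ph <- deg2rad(phi)
  m0 <- Re(g[1, ]) / 9
  m1 <- 2 * Re(g[2, ] * exp(2i * ph)) / 9
  m2 <- 2 * Re(g[3, ] * exp(4i * ph)) / 9

  sol <- invert_moments(m0, m1, m2)
  ok <- finite & !degenerate & is.finite(sol$i0)
  i0 <- ifelse(ok, sol$i0, NaN)
  b <- ifelse(ok, sol$b, NaN)
  cc <- ifelse(ok, sol$c, NaN)
  phi[!ok] <- NaN

  # quality estimators ------------------------------------------------
  # R2 against the 10 original values, predictions from the fitted model
  dmat <- outer(deg2rad(phi), deg2rad(angles), function(p, a) p - a)
  pred <- i0 * (sin(2 * dmat)^2 +
                  (b * sin(dmat)^2 + cc * cos(dmat)^2)^2)
  ssr <- rowSums((x10 - pred)^2)
  sst <- rowSums((x10 - rowMeans(x10))^2)
  r2 <- ifelse(ok & sst > 0, 1 - ssr / sst, NaN)

  c34 <- (2 * Mod(g[4, ]) / 9 + 2 * Mod(g[5, ]) / 9) / 2
  den <- (c0 + c1 + c2) / 3
  err <- ifelse(finite & den > 0, c34 / den, NaN)

  sig <- Mod(g[2, ])^2 + Mod(g[3, ])^2
  noi <- Mod(g[4, ])^2 + Mod(g[5, ])^2 + Mod(g[6, ])^2 + Mod(g[7, ])^2
  snr <- rep(NaN, npix)
  pos <- finite & noi > 0
  snr[pos] <- pmin(99, 10 * log10(sig[pos] / noi[pos]))
  snr[finite & noi == 0 & sig > 0] <- 99

  as_map <- function(v) matrix(v, h, w)
  structure(
    list(maps = list(CHI3115 = as_map(b), CHI3315 = as_map(cc),
                     CHI3331 = as_map(cc / b), FI = as_map(phi),
                     THETA = as_map(.theta_from_ratio(cc)),
                     R2 = as_map(r2), SNR = as_map(snr), ERR = as_map(err)),
         i0 = as_map(i0), dim = c(h, w)),
    class = "pshg_maps")
}

#' Map names produced by the analysis
#'
#' The eight planar maps written per stack, in canonical order; the first
#' five carry collagen structural information, the last three are
#' fitting-quality estimators.
#' @return Character vector of map names.
#' @export
pshg_map_names <- function() {
  c("CHI3115", "CHI3315", "CHI3331", "FI", "THETA", "R2", "SNR", "ERR")
}

# names of the five structural parameter maps (dispersion inputs)
structural_map_names <- function() c("CHI3115", "CHI3315", "CHI3331", "FI", "THETA")

#' @export
print.pshg_maps <- function(x, ...) {
  cat(sprintf("<pshg_maps> %d x %d pixels, maps: %s\n",
              x$dim[1], x$dim[2], paste(names(x$maps), collapse = ", ")))
  ok <- is.finite(x$maps$R2)
  cat(sprintf("  fitted pixels: %d/%d (%.1f%%)\n",
              sum(ok), length(ok), 100 * mean(ok)))
  invisible(x)
}

#' Tidy a set of fitted parameter maps
#'
#' @param x A `pshg_maps` object.
#' @param ... Unused.
#' @return A tibble with columns `row`, `col`, `parameter`, `value`, one
#'   row per pixel and map.
#' @importFrom generics tidy
#' @export
tidy.pshg_maps <- function(x, ...) {
  h <- x$dim[1]; w <- x$dim[2]
  base <- tibble::tibble(row = rep(seq_len(h), w), col = rep(seq_len(w), each = h))
  out <- lapply(names(x$maps), function(nm)
    dplyr::mutate(base, parameter = nm, value = as.vector(x$maps[[nm]])))
  dplyr::bind_rows(out)
}

#' One-row summary of a fit
#'
#' @param x A `pshg_maps` object.
#' @param r2_threshold Threshold used for the good-fit pixel fraction.
#' @param ... Unused.
#' @return A tibble with pixel counts, the fraction of pixels at or above
#'   `r2_threshold`, and medians of the structural maps over fitted pixels.
#' @importFrom generics glance
#' @export
glance.pshg_maps <- function(x, r2_threshold = 0.8, ...) {
  r2 <- x$maps$R2
  ok <- is.finite(r2)
  med <- function(m) median(m[is.finite(m)])
  tibble::tibble(
    n_pixels = length(r2),
    n_fitted = sum(ok),
    frac_good_fit = if (any(ok)) mean(r2[ok] >= r2_threshold) else NaN,
    median_r2 = med(r2),
    median_chi3115 = med(x$maps$CHI3115),
    median_chi3315 = med(x$maps$CHI3315),
    median_theta = med(x$maps$THETA)
  )
}

#' Plot fitted parameter maps
#'
#' @param object A `pshg_maps` object.
#' @param parameters Which maps to draw (default all eight).
#' @param ... Unused.
#' @return A ggplot object: one raster panel per map.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.pshg_maps <- function(object, parameters = pshg_map_names(), ...) {
  dat <- tidy(object)
  dat <- dat[dat$parameter %in% parameters, ]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$col, y = .data$row,
                                    fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL)
}

#' @importFrom rlang .data
NULL
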