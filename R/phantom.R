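#' Specify a synthetic phantom stack
#'
#' A phantom emulates one polarization-resolved SHG acquisition: a set of
#' disjoint collagen regions, each following the single-axis model with its
#' own parameters, embedded in an SHG-inactive background of constant mean.
#' Background pixels carry no polarization dependence, only noise, which is
#' what quality estimators see outside SHG-active tissue.
#'
#' Defaults emulate the deposited 8-bit tissue stacks: a dark background of
#' 2 counts, Gaussian detection noise with a standard deviation of 2 counts,
#' and 8-bit quantization. Set `bit_depth = NA` for exact floating-point
#' output (used to verify parameter recovery to machine precision).
#'
#' @param height,width Image size in pixels.
#' @param regions List of regions, each a `list(mask = , params = )` where
#'   `mask` is a logical `height x width` matrix and `params` a
#'   [pshg_params()] object. Masks must be pairwise disjoint.
#' @param background_level Mean counts of non-collagen pixels.
#' @param noise One of `"none"`, `"gaussian"`, `"poisson"`.
#' @param noise_sd Standard deviation of Gaussian noise (counts).
#' @param gain Poisson gain: counts recorded per photon;
#'   samples are `rpois(lambda = intensity / gain) * gain`.
#' @param bit_depth `8` for 8-bit quantized output (stack maximum scaled to
#'   255 before rounding, mimicking detector export), or `NA` for
#'   unquantized floating point.
#' @param seed Integer RNG seed; generation is deterministic given the seed.
#' @return An object of class `phantom_spec`.
#' @seealso [generate_stack()], [phantom_truth()]
#' @export
phantom_spec <- function(height, width, regions = list(),
                         background_level = 2,
                         noise = c("none", "gaussian", "poisson"),
                         noise_sd = 2, gain = 1,
                         bit_depth = 8, seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(height >= 1, width >= 1, background_level >= 0,
            noise_sd >= 0, gain > 0, is.na(bit_depth) || bit_depth == 8)
  covered <- matrix(FALSE, height, width)
  for (i in seq_along(regions)) {
    reg <- regions[[i]]
    if (!is.list(reg) || is.null(reg$mask) || is.null(reg$params))
      stop("each region must be a list(mask = , params = )")
    if (!inherits(reg$params, "pshg_params"))
      stop("region params must be a pshg_params object")
    m <- reg$mask
    if (!is.logical(m) || !is.matrix(m) ||
        nrow(m) != height || ncol(m) != width)
      stop(sprintf("region %d mask out of bounds: need a logical %dx%d matrix",
                   i, height, width))
    if (any(covered & m)) stop(sprintf("region %d overlaps a previous region", i))
    covered <- covered | m
  }
  structure(
    list(height = height, width = width, regions = regions,
         background_level = background_level, noise = noise,
         noise_sd = noise_sd, gain = gain, bit_depth = bit_depth,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Generate a phantom polarization stack
#'
#' Produces one frame per acquisition angle (default 0 to 180 degrees in
#' 20-degree steps, 10 frames). Collagen pixels follow the single-axis model
#' exactly before noise and quantization; background pixels have constant
#' mean. Although the ideal signal at 0 and 180 degrees is identical
#' (180-degree periodicity), the two frames receive independent noise draws,
#' so endpoint averaging is meaningful under noise.
#'
#' @param spec A [phantom_spec()] object.
#' @param angles Acquisition angle grid; must be the 10-angle default.
#' @return A `height x width x 10` array of class `pshg_stack` with an
#'   `angles` attribute. When `bit_depth = 8` the array holds integers in
#'   0..255 and a `quant_scale` attribute giving the counts-per-model-unit
#'   factor applied before rounding.
#' @export
generate_stack <- function(spec, angles = pshg_angles()) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!identical(as.numeric(angles), as.numeric(pshg_angles())))
    stop("`angles` must be the default 10-angle acquisition grid")
  h <- spec$height; w <- spec$width; na <- length(angles)

  ideal <- array(spec$background_level, dim = c(h, w, na))
  for (reg in spec$regions) {
    idx <- which(reg$mask)
    vals <- shg_intensity(reg$params, angles)  # length 10
    for (k in seq_len(na)) {
      frame <- ideal[, , k]
      frame[idx] <- vals[k]
      ideal[, , k] <- frame
    }
  }

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(spec$seed)
  stack <- switch(
    spec$noise,
    none = ideal,
    gaussian = ideal + array(rnorm(h * w * na, sd = spec$noise_sd), dim = dim(ideal)),
    poisson = array(rpois(h * w * na, lambda = pmax(ideal, 0) / spec$gain) * spec$gain,
                    dim = dim(ideal))
  )

  qs <- NA_real_
  if (!is.na(spec$bit_depth)) {
    stack[stack < 0] <- 0
    mx <- max(stack)
    qs <- if (mx > 0) 255 / mx else 1
    stack <- round(stack * qs)
  }
  structure(stack, angles = as.numeric(angles), quant_scale = qs,
            class = "pshg_stack")
}

#' Ground-truth parameter maps of a phantom
#'
#' Returns the per-pixel model parameters used by [generate_stack()], in the
#' canonical representative (see [canonicalize_params()]), with `NaN` on
#' background pixels. These are the maps a perfect fit of a noiseless,
#' unquantized phantom must reproduce.
#'
#' @param spec A [phantom_spec()] object.
#' @return Named list of `height x width` matrices: `I0`, `CHI3115`,
#'   `CHI3315`, `CHI3331`, `FI`, `THETA`.
#' @export
phantom_truth <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$height; w <- spec$width
  blank <- matrix(NaN, h, w)
  out <- list(I0 = blank, CHI3115 = blank, CHI3315 = blank,
              CHI3331 = blank, FI = blank, THETA = blank)
  for (reg in spec$regions) {
    p <- canonicalize_params(reg$params)
    idx <- which(reg$mask)
    out$I0[idx] <- p$i0
    out$CHI3115[idx] <- p$chi3115
    out$CHI3315[idx] <- p$chi3315
    out$CHI3331[idx] <- p$chi3315 / p$chi3115
    out$FI[idx] <- p$phi
    out$THETA[idx] <- .theta_from_ratio(p$chi3315)
  }
  out
}

#' @export
print.pshg_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<pshg_stack> %d x %d pixels, %d frames at %s deg\n",
              d[1], d[2], d[3],
              paste(attr(x, "angles"), collapse = ", ")))
  invisible(x)
}
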