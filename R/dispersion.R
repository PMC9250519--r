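#' Computational window mask
#'
#' Centered boolean offset masks used for local dispersion estimation: a
#' full `size x size` block for `"square"`, and for `"circular"` the
#' offsets with \eqn{dx^2 + dy^2 \le ((size-1)/2)^2}. Under this
#' convention the circular masks of size 3, 7, 15 contain 5, 29 and 149
#' pixels. The estimated value is assigned to the centre pixel.
#'
#' @param shape `"square"` or `"circular"`.
#' @param size Window side (square) or diameter (circular); one of 3, 7, 15.
#' @return A logical `size x size` matrix.
#' @export
window_mask <- function(shape = c("square", "circular"), size) {
  shape <- match.arg(shape)
  if (length(size) != 1 || !size %in% c(3, 7, 15))
    stop(sprintf("unsupported window size %s: must be 3, 7 or 15", size))
  if (shape == "square") return(matrix(TRUE, size, size))
  r <- (size - 1) / 2
  off <- seq(-r, r)
  outer(off, off, function(dy, dx) dx^2 + dy^2 <= r^2)
}

# neighbour-value matrix: one row per pixel, one column per mask offset,
# NA outside the image (windows clipped at borders, no padding)
.window_values <- function(img, mask) {
  h <- nrow(img); w <- ncol(img)
  r <- (nrow(mask) - 1) / 2
  off <- which(mask, arr.ind = TRUE) - (r + 1)  # dy, dx offsets
  rows <- rep(seq_len(h), w)
  cols <- rep(seq_len(w), each = h)
  v <- matrix(NA_real_, h * w, nrow(off))
  for (k in seq_len(nrow(off))) {
    rr <- rows + off[k, 1]
    cc <- cols + off[k, 2]
    inb <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    col_k <- rep(NA_real_, h * w)
    col_k[inb] <- img[cbind(rr[inb], cc[inb])]
    v[, k] <- col_k
  }
  v
}

#' Local dispersion map of a parameter image
#'
#' Slides a computational window over the image and summarises the valid
#' (finite) values in each window with one of three estimators:
#' \describe{
#'   \item{`SD`}{population standard deviation (divisor n).}
#'   \item{`MAD`}{median absolute deviation,
#'     \eqn{\mathrm{median}(|x - \mathrm{median}(x)|)}; robust to outliers.}
#'   \item{`ENT`}{Shannon entropy in bits,
#'     \eqn{-\sum p(x_i)\log_2 p(x_i)}, of the occurrence rates after
#'     quantizing the window values to `entropy_bins` levels over the fixed
#'     `range` (not the window-local range, so values are comparable across
#'     the image).}
#' }
#' Windows are clipped at image borders (no padding). Pixels whose window
#' holds fewer than `min_valid_fraction` of the full mask size in finite
#' values get `NaN`; `NaN` input pixels never contribute.
#'
#' @param img Numeric matrix (a parameter map; may contain `NaN`).
#' @param estimator `"SD"`, `"MAD"` or `"ENT"`.
#' @param shape,size Window specification, see [window_mask()].
#' @param entropy_bins Number of quantization levels for `ENT`.
#' @param range Length-2 numeric giving the fixed quantization range for
#'   `ENT`; values are clipped to it. Defaults to the finite range of
#'   `img`.
#' @param min_valid_fraction Minimum fraction of the full mask that must be
#'   finite and in-bounds.
#' @param circular Treat values as axial orientations in degrees (period
#'   180) for `SD` and `MAD`: deviations are measured as the axial angular
#'   distance to the window's mean axis, removing the wraparound bias at
#'   the 0/180 seam. Off by default; the linear statistics in degrees match
#'   the published maps.
#' @return A matrix of the same size as `img`.
#' @export
local_dispersion <- function(img, estimator = c("SD", "MAD", "ENT"),
                             shape = "square", size = 3,
                             entropy_bins = 256, range = NULL,
                             min_valid_fraction = 0.5, circular = FALSE) {
  estimator <- match.arg(estimator)
  stopifnot(is.matrix(img), is.numeric(img))
  mask <- window_mask(shape, size)
  v <- .window_values(img, mask)
  nmask <- sum(mask)
  nvalid <- rowSums(is.finite(v))
  keep <- nvalid >= min_valid_fraction * nmask & nvalid > 0

  out <- rep(NaN, nrow(v))
  if (circular && estimator %in% c("SD", "MAD")) {
    # axial data, period 180: deviations to the mean axis of each window
    a2 <- deg2rad(2 * v)
    cs <- rowMeans(cos(a2), na.rm = TRUE)
    sn <- rowMeans(sin(a2), na.rm = TRUE)
    ctr <- rad2deg(atan2(sn, cs)) / 2          # mean axis, degrees
    dev <- abs((v - ctr + 90) %% 180 - 90)     # axial distance, [0, 90]
    if (estimator == "SD") {
      out[keep] <- sqrt(rowMeans(dev^2, na.rm = TRUE))[keep]
    } else {
      idx <- which(keep)
      out[idx] <- vapply(idx, function(i) {
        x <- dev[i, ]
        median(x[is.finite(x)])
      }, numeric(1))
    }
    return(matrix(out, nrow(img), ncol(img)))
  }
  if (estimator == "SD") {
    m <- rowMeans(v, na.rm = TRUE)
    m2 <- rowMeans(v^2, na.rm = TRUE)
    out[keep] <- sqrt(pmax(m2 - m^2, 0))[keep]
  } else if (estimator == "MAD") {
    idx <- which(keep)
    out[idx] <- vapply(idx, function(i) {
      x <- v[i, ]
      x <- x[is.finite(x)]
      median(abs(x - median(x)))
    }, numeric(1))
  } else {
    if (is.null(range)) {
      fin <- img[is.finite(img)]
      range <- if (length(fin)) c(min(fin), max(fin)) else c(0, 1)
    }
    stopifnot(length(range) == 2, range[2] >= range[1])
    span <- range[2] - range[1]
    if (span == 0) span <- 1
    bin <- floor((pmin(pmax(v, range[1]), range[2]) - range[1]) /
                   span * entropy_bins)
    bin[bin >= entropy_bins] <- entropy_bins - 1
    idx <- which(keep)
    out[idx] <- vapply(idx, function(i) {
      z <- bin[i, ]
      z <- z[is.finite(z)]
      p <- tabulate(as.integer(z) + 1L, nbins = entropy_bins) / length(z)
      p <- p[p > 0]
      -sum(p * log2(p))
    }, numeric(1))
  }
  matrix(out, nrow(img), ncol(img))
}

# Fixed quantization ranges for entropy of each structural parameter.
# FI is an orientation in [0, 180); THETA a pitch angle in [0, 90]; the
# susceptibility ratios are clipped to [0, 5], covering the physiological
# range reported for collagen.
dispersion_ranges <- function() {
  list(CHI3115 = c(0, 5), CHI3315 = c(0, 5), CHI3331 = c(0, 5),
       FI = c(0, 180), THETA = c(0, 90))
}

#' Default window set
#'
#' Square and circular windows of size 3, 7 and 15: the six windows used
#' for the local-dispersion maps.
#' @return A data frame with columns `shape` and `size`.
#' @export
dispersion_windows <- function() {
  expand.grid(shape = c("square", "circular"), size = c(3, 7, 15),
              stringsAsFactors = FALSE)
}

#' All local-dispersion maps of a fitted stack
#'
#' Applies the three estimators (ENT, SD, MAD) over the six windows to the
#' five collagen structural maps, yielding 5 x 3 x 6 = 90 maps named
#' `[parameter]_[estimator]_[shape]_[size]` after the collection
#' nomenclature.
#'
#' @param maps A `pshg_maps` object from [fit_stack()], or a named list of
#'   matrices containing at least the five structural maps `CHI3115`,
#'   `CHI3315`, `CHI3331`, `FI`, `THETA`.
#' @param windows Data frame of windows (columns `shape`, `size`); default
#'   [dispersion_windows()].
#' @param estimators Estimators to apply, default `c("ENT", "SD", "MAD")`.
#' @param entropy_bins Quantization levels for ENT (over the fixed
#'   per-parameter ranges: ratios clipped to \[0, 5\], FI \[0, 180), THETA
#'   \[0, 90\]).
#' @param min_valid_fraction See [local_dispersion()].
#' @param circular_phi Use axial circular statistics for SD/MAD of the
#'   orientation map `FI` (see [local_dispersion()]); off by default.
#' @return Named list of 90 matrices.
#' @export
dispersion_set <- function(maps, windows = dispersion_windows(),
                           estimators = c("ENT", "SD", "MAD"),
                           entropy_bins = 256, min_valid_fraction = 0.5,
                           circular_phi = FALSE) {
  if (inherits(maps, "pshg_maps")) maps <- maps$maps
  need <- structural_map_names()
  missing <- setdiff(need, names(maps))
  if (length(missing))
    stop("missing parameter map(s): ", paste(missing, collapse = ", "))
  ranges <- dispersion_ranges()
  out <- list()
  for (par in need) {
    for (est in estimators) {
      for (i in seq_len(nrow(windows))) {
        sh <- windows$shape[i]; sz <- windows$size[i]
        nm <- paste(par, est, sh, sz, sep = "_")
        out[[nm]] <- local_dispersion(
          maps[[par]], estimator = est, shape = sh, size = sz,
          entropy_bins = entropy_bins, range = ranges[[par]],
          min_valid_fraction = min_valid_fraction,
          circular = circular_phi && par == "FI")
      }
    }
  }
  out
}
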