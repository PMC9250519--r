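#' Simulate a phantom collection
#'
#' Writes a small collection in the deposited layout from synthetic
#' phantoms: per ROI a folder `phantom_[roi]` with `FSHG` and `BSHG`
#' detection subfolders of ten 8-bit frames each, a TPEF stand-in image
#' (the maximum intensity projection of the FSHG stack), and per-detection
#' ground-truth parameter maps as 32-bit float TIFFs under `GroundTruth/`.
#' Generation is deterministic given `seed`; each (ROI, detection) stack
#' receives its own derived seed.
#'
#' Default phantoms hold two vertical collagen bands with distinct
#' parameters over a dark background, under the default noise conditions
#' of [phantom_spec()].
#'
#' @param out_root Output root directory (created if needed).
#' @param n_roi Number of phantom ROIs.
#' @param height,width Frame size in pixels.
#' @param region_params List of [pshg_params()] for the vertical bands.
#' @param noise,noise_sd,background_level,bit_depth Passed to
#'   [phantom_spec()].
#' @param seed Base integer seed.
#' @return Tibble manifest of written stacks, invisibly.
#' @export
simulate_collection <- function(out_root, n_roi = 2, height = 32, width = 32,
                                region_params = list(
                                  pshg_params(i0 = 100, chi3115 = 1,
                                              chi3315 = 2, phi = 30),
                                  pshg_params(i0 = 80, chi3115 = 0.8,
                                              chi3315 = 2.5, phi = 120)),
                                noise = "gaussian", noise_sd = 2,
                                background_level = 2, bit_depth = 8,
                                seed = 1L) {
  dir.create(out_root, showWarnings = FALSE, recursive = TRUE)
  nb <- length(region_params)
  cuts <- round(seq(0, width, length.out = nb + 1))
  regions <- lapply(seq_len(nb), function(i) {
    m <- matrix(FALSE, height, width)
    lo <- cuts[i] + 1; hi <- cuts[i + 1]
    if (hi >= lo) m[, lo:hi] <- TRUE
    # leave a one-pixel background gutter between bands
    if (i > 1 && lo <= width) m[, lo] <- FALSE
    list(mask = m, params = region_params[[i]])
  })
  rows <- list()
  for (roi in seq_len(n_roi)) {
    stem <- paste0("phantom_", roi)
    rd <- file.path(out_root, stem)
    mip <- NULL
    for (di in seq_along(.detections)) {
      det <- .detections[di]
      dd <- file.path(rd, det)
      dir.create(dd, showWarnings = FALSE, recursive = TRUE)
      sseed <- (seed * 1000L + roi * 10L + di) %% .Machine$integer.max
      spec <- phantom_spec(height, width, regions,
                           background_level = background_level,
                           noise = noise, noise_sd = noise_sd,
                           bit_depth = bit_depth, seed = sseed)
      stack <- generate_stack(spec)
      angles <- attr(stack, "angles")
      for (k in seq_along(angles))
        write_frame_tiff(pmin(pmax(stack[, , k], 0), 255),
                         file.path(dd, paste0(stem, "_", det, "_",
                                              angles[k], ".tif")))
      gt <- phantom_truth(spec)
      gdir <- file.path(dd, "GroundTruth")
      dir.create(gdir, showWarnings = FALSE)
      for (nm in names(gt))
        write_float_tiff(gt[[nm]], file.path(gdir, paste0(nm, "_synthetic_truth.tif")))
      if (det == "FSHG") mip <- apply(unclass(stack), c(1, 2), max)
      rows[[length(rows) + 1]] <- tibble::tibble(
        roi = stem, detection = det, seed = sseed, path = dd)
    }
    write_frame_tiff(pmin(pmax(mip, 0), 255),
                     file.path(rd, paste0(stem, "_TPEF.tif")))
  }
  invisible(dplyr::bind_rows(rows))
}

# detection folders of a collection root, as a tibble
.detection_folders <- function(root, detection = "both") {
  roi_dirs <- list.dirs(root, recursive = FALSE)
  roi_dirs <- roi_dirs[grepl("^(breast|skin|thyroid|phantom)(_HE)?_[0-9]+$",
                             basename(roi_dirs))]
  dets <- if (detection == "both") .detections else detection
  out <- expand.grid(roi = roi_dirs, det = dets, stringsAsFactors = FALSE)
  out$path <- file.path(out$roi, out$det)
  out[dir.exists(out$path), ]
}

#' Run the FF-PSHG fit over a collection
#'
#' Applies [fit_stack()] to every detection folder under `root` and writes
#' the eight parameter maps into each `Results` subfolder. Optionally also
#' writes a binary good-fit mask (`R2_MASK.tif`, pixels with
#' `R2 >= r2_threshold`) and 256-bin histograms of each map as delimited
#' text (`histograms.tsv`).
#'
#' @param root Collection root.
#' @param detection `"FSHG"`, `"BSHG"` or `"both"`.
#' @param r2_threshold Optional threshold in \[0, 1\] for the good-fit mask.
#' @param histograms Write per-map histogram tables (default `FALSE`).
#' @return A tibble with one row per detection folder: `path`, `ok`,
#'   `error` (`NA` on success).
#' @export
process_collection <- function(root, detection = "both", r2_threshold = NULL,
                               histograms = FALSE) {
  if (!is.null(r2_threshold))
    stopifnot(r2_threshold >= 0, r2_threshold <= 1)
  folders <- .detection_folders(root, detection)
  if (!nrow(folders)) stop("no detection folders found under ", root)
  res <- lapply(folders$path, function(p) {
    tryCatch({
      stack <- read_stack(p)
      maps <- fit_stack(stack)
      write_parameter_maps(maps, p)
      if (!is.null(r2_threshold)) {
        mask <- ifelse(is.finite(maps$maps$R2) &
                         maps$maps$R2 >= r2_threshold, 255, 0)
        write_frame_tiff(matrix(mask, nrow(mask), ncol(mask)),
                         file.path(p, "Results", "R2_MASK.tif"))
      }
      if (histograms)
        write_map_histograms(maps$maps, file.path(p, "Results",
                                                  "histograms.tsv"))
      tibble::tibble(path = p, ok = TRUE, error = NA_character_)
    }, error = function(e)
      tibble::tibble(path = p, ok = FALSE, error = conditionMessage(e)))
  })
  dplyr::bind_rows(res)
}

#' 256-bin histograms of a set of maps, as delimited text
#'
#' Bins each map's finite values into 256 equal-width bins over its finite
#' range and writes a long TSV with columns `map`, `bin_lo`, `bin_hi`,
#' `count` (enables mode/mean readouts without reloading the maps).
#'
#' @param maps Named list of matrices.
#' @param path Output TSV path.
#' @param bins Number of bins.
#' @return `path`, invisibly.
#' @export
write_map_histograms <- function(maps, path, bins = 256) {
  rows <- lapply(names(maps), function(nm) {
    x <- maps[[nm]][is.finite(maps[[nm]])]
    if (!length(x)) return(NULL)
    rng <- range(x)
    if (rng[1] == rng[2]) rng[2] <- rng[1] + 1
    br <- seq(rng[1], rng[2], length.out = bins + 1)
    ct <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins = bins)
    tibble::tibble(map = nm, bin_lo = br[-(bins + 1)], bin_hi = br[-1],
                   count = ct)
  })
  utils::write.table(dplyr::bind_rows(rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Compute local-dispersion maps over a collection
#'
#' For every detection folder with fitted maps, reads the five structural
#' maps from `Results/` and writes the 90 local-dispersion maps next to
#' them.
#'
#' @param root Collection root.
#' @param detection `"FSHG"`, `"BSHG"` or `"both"`.
#' @inheritParams dispersion_set
#' @return A tibble with one row per detection folder: `path`, `ok`,
#'   `error`.
#' @export
dispersion_collection <- function(root, detection = "both",
                                  windows = dispersion_windows(),
                                  entropy_bins = 256,
                                  min_valid_fraction = 0.5,
                                  circular_phi = FALSE) {
  folders <- .detection_folders(root, detection)
  if (!nrow(folders)) stop("no detection folders found under ", root)
  res <- lapply(folders$path, function(p) {
    tryCatch({
      maps <- read_parameter_maps(p)
      dm <- dispersion_set(maps, windows = windows,
                           entropy_bins = entropy_bins,
                           min_valid_fraction = min_valid_fraction,
                           circular_phi = circular_phi)
      write_dispersion_maps(dm, p)
      tibble::tibble(path = p, ok = TRUE, error = NA_character_)
    }, error = function(e)
      tibble::tibble(path = p, ok = FALSE, error = conditionMessage(e)))
  })
  dplyr::bind_rows(res)
}
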