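.tissues <- c("breast", "skin", "thyroid", "phantom")
.detections <- c("FSHG", "BSHG")

#' Parse a collection file name
#'
#' File names follow
#' `[tissue]_[HE]_[ROI number]_[detection]_[polarization angle]` for SHG
#' frames and `[tissue]_[HE]_[ROI number]_TPEF` for the fluorescence
#' context image; the `HE` token is present only for stained sections
#' (thyroid file names never carry it). Synthetic collections use the
#' tissue token `phantom`.
#'
#' @param name File name(s), with or without directory and `.tif` suffix.
#' @return A tibble with one row per name: `tissue`, `stained`, `roi`,
#'   `detection` (`"FSHG"`, `"BSHG"` or `"TPEF"`), `angle` (degrees, `NA`
#'   for TPEF) and `class_label` (the ROI class, see [roi_class()]).
#' @examples
#' parse_pshg_filename("breast_HE_19_FSHG_40.tif")
#' parse_pshg_filename("skin_7_TPEF")
#' @export
parse_pshg_filename <- function(name) {
  rows <- lapply(name, .parse_one_filename)
  dplyr::bind_rows(rows)
}

.parse_one_filename <- function(name) {
  base <- tools::file_path_sans_ext(basename(name))
  tok <- strsplit(base, "_", fixed = TRUE)[[1]]
  fail <- function(what, t) stop(sprintf("cannot parse '%s': %s token '%s'",
                                         base, what, t), call. = FALSE)
  if (length(tok) < 3) fail("too few tokens, last", tok[length(tok)])
  tissue <- tok[1]
  if (!tissue %in% .tissues) fail("unrecognized tissue", tissue)
  i <- 2
  stained <- FALSE
  if (tok[i] == "HE") { stained <- TRUE; i <- i + 1 }
  roi <- suppressWarnings(as.integer(tok[i]))
  if (is.na(roi) || roi < 1 || as.character(roi) != tok[i])
    fail("invalid ROI number", tok[i])
  i <- i + 1
  if (i > length(tok)) fail("missing detection", "")
  det <- tok[i]
  if (det == "TPEF") {
    if (i != length(tok)) fail("unexpected trailing", tok[i + 1])
    angle <- NA_real_
  } else {
    if (!det %in% .detections) fail("unrecognized detection", det)
    if (i + 1 != length(tok)) fail(
      if (i + 1 > length(tok)) "missing angle, last" else "unexpected trailing",
      tok[length(tok)])
    angle <- suppressWarnings(as.numeric(tok[i + 1]))
    if (is.na(angle) || !angle %in% seq(0, 180, by = 20))
      fail("invalid polarization angle", tok[i + 1])
  }
  tibble::tibble(tissue = tissue, stained = stained, roi = roi,
                 detection = det, angle = angle,
                 class_label = roi_class(tissue, stained, roi))
}

#' Format a collection file name
#'
#' Inverse of [parse_pshg_filename()] (without the `.tif` suffix).
#'
#' @param tissue Tissue token.
#' @param stained Logical: H&E-stained section (adds the `HE` token).
#' @param roi ROI number (positive integer).
#' @param detection `"FSHG"`, `"BSHG"` or `"TPEF"`.
#' @param angle Polarization angle in degrees (ignored for TPEF).
#' @return Character file name stem.
#' @export
format_pshg_filename <- function(tissue, stained, roi, detection, angle = NA) {
  stopifnot(tissue %in% .tissues, detection %in% c(.detections, "TPEF"))
  he <- if (stained) "HE" else NULL
  if (detection == "TPEF")
    paste(c(tissue, he, roi, "TPEF"), collapse = "_")
  else
    paste(c(tissue, he, roi, detection, angle), collapse = "_")
}

#' ROI class label
#'
#' Maps `(tissue, stained, roi)` to the histological class of the region
#' of interest: breast ROIs are normal terminal ductal-lobular units
#' (1-18), ductal carcinoma in situ (19-30) or invasive carcinoma (31-48
#' unstained, 31-47 stained); skin ROIs are papillary dermis (1-10),
#' reticular dermis (11-32) or subcutaneous tissue (33-53); thyroid ROIs
#' are papillary thyroid carcinoma (1-20) or follicular adenoma (21-40).
#'
#' @param tissue,stained,roi Vectors as in [parse_pshg_filename()].
#' @return Character vector of class labels (`NA` for phantom or
#'   out-of-range ROIs).
#' @export
roi_class <- function(tissue, stained, roi) {
  mapply(function(t, s, r) {
    switch(t,
      breast = {
        hi <- if (s) 47L else 48L
        if (r <= 18) "normal TDLU"
        else if (r <= 30) "ductal carcinoma in situ"
        else if (r <= hi) "invasive carcinoma"
        else NA_character_
      },
      skin = {
        if (r <= 10) "papillary dermis"
        else if (r <= 32) "reticular dermis"
        else if (r <= 53) "subcutaneous tissue"
        else NA_character_
      },
      thyroid = {
        if (r <= 20) "papillary thyroid carcinoma"
        else if (r <= 40) "follicular adenoma"
        else NA_character_
      },
      NA_character_)
  }, tissue, stained, roi, USE.NAMES = FALSE)
}

#' Expected image counts of a collection
#'
#' Derives the deterministic inventory from the per-group ROI totals:
#' every ROI yields two detection stacks (FSHG, BSHG) of 10 SHG frames,
#' one TPEF image, 8 fitted parameter maps per stack and 90 local
#' dispersion maps per stack.
#'
#' @param roi_totals Numeric vector of ROI counts per tissue/staining
#'   group (any grouping; only the sum matters).
#' @return A one-row tibble: `rois`, `stacks`, `shg_images`,
#'   `tpef_images`, `ffpshg_maps`, `dispersion_maps`, `total_images`.
#' @examples
#' expected_counts(c(48, 47, 53, 53, 40))
#' @export
expected_counts <- function(roi_totals) {
  stopifnot(is.numeric(roi_totals))
  if (any(roi_totals < 0)) stop("ROI totals must be non-negative")
  rois <- sum(roi_totals)
  stacks <- rois * 2
  tibble::tibble(
    rois = rois,
    stacks = stacks,
    shg_images = stacks * 10,
    tpef_images = rois,
    ffpshg_maps = stacks * 8,
    dispersion_maps = stacks * 90,
    total_images = stacks * 10 + rois + stacks * 8 + stacks * 90
  )
}

#' Read a polarization stack from a detection folder
#'
#' Reads the ten 8-bit SHG frames of one detection geometry, ordered by
#' parsed polarization angle.
#'
#' @param folder Path to a detection folder (`FSHG` or `BSHG`).
#' @param detection Detection token; defaults to the folder's base name.
#' @return A `height x width x 10` array of class `pshg_stack` (integer
#'   counts 0..255), with attributes `angles` and `files`.
#' @export
read_stack <- function(folder, detection = NULL) {
  if (!dir.exists(folder)) stop("no such folder: ", folder)
  if (is.null(detection)) detection <- basename(folder)
  if (!detection %in% .detections)
    stop("detection must be FSHG or BSHG, got: ", detection)
  files <- list.files(folder, pattern = "\\.tif$", full.names = TRUE)
  if (!length(files)) stop("no .tif files in ", folder)
  info <- parse_pshg_filename(files)
  keep <- info$detection == detection
  files <- files[keep]; info <- info[keep, ]
  want <- pshg_angles()
  missing <- setdiff(want, info$angle)
  if (length(missing))
    stop("missing polarization angle(s): ", paste(missing, collapse = ", "),
         " in ", folder)
  dup <- unique(info$angle[duplicated(info$angle)])
  if (length(dup))
    stop("duplicate polarization angle(s): ", paste(dup, collapse = ", "),
         " in files ", paste(basename(files[info$angle %in% dup]),
                             collapse = ", "))
  ord <- order(info$angle)
  files <- files[ord]
  frames <- lapply(files, function(f) {
    m <- tiff::readTIFF(f, as.is = TRUE)
    if (length(dim(m)) == 3) m <- m[, , 1]  # tolerate grayscale-as-RGB
    m
  })
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("frame shape mismatch in files: ",
         paste(basename(files), collapse = ", "))
  stack <- array(unlist(frames), dim = c(dims[1, 1], dims[2, 1], 10))
  structure(stack, angles = want, files = files, class = "pshg_stack")
}

#' Write an 8-bit grayscale TIFF frame
#'
#' @param img Matrix of counts in 0..255.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frame_tiff <- function(img, path) {
  stopifnot(is.matrix(img), max(img) <= 255, min(img) >= 0)
  tiff::writeTIFF(img / 255, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}

#' Write fitted parameter maps into a Results subfolder
#'
#' Writes the eight maps as 32-bit float TIFFs named `CHI3115.tif`,
#' `CHI3315.tif`, `CHI3331.tif`, `FI.tif`, `THETA.tif`, `R2.tif`,
#' `SNR.tif`, `ERR.tif` inside `Results/` under the detection folder.
#'
#' @param maps A `pshg_maps` object (or named list of the eight matrices).
#' @param folder Detection folder.
#' @return The `Results` path, invisibly.
#' @export
write_parameter_maps <- function(maps, folder) {
  if (inherits(maps, "pshg_maps")) maps <- maps$maps
  stopifnot(all(pshg_map_names() %in% names(maps)))
  res <- file.path(folder, "Results")
  dir.create(res, showWarnings = FALSE, recursive = TRUE)
  for (nm in pshg_map_names())
    write_float_tiff(maps[[nm]], file.path(res, paste0(nm, ".tif")))
  invisible(res)
}

#' Read the parameter maps of a Results folder
#'
#' @param folder Detection folder (containing `Results/`).
#' @return A `pshg_maps` object.
#' @export
read_parameter_maps <- function(folder) {
  res <- file.path(folder, "Results")
  maps <- lapply(pshg_map_names(), function(nm) {
    f <- file.path(res, paste0(nm, ".tif"))
    if (!file.exists(f)) stop("missing parameter map: ", f)
    read_float_tiff(f)
  })
  names(maps) <- pshg_map_names()
  structure(list(maps = maps, dim = dim(maps[[1]])), class = "pshg_maps")
}

#' Write local-dispersion maps into the Results subfolder
#'
#' @param dmaps Named list of matrices, as from [dispersion_set()].
#' @param folder Detection folder.
#' @return The `Results` path, invisibly.
#' @export
write_dispersion_maps <- function(dmaps, folder) {
  res <- file.path(folder, "Results")
  dir.create(res, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(dmaps))
    write_float_tiff(dmaps[[nm]], file.path(res, paste0(nm, ".tif")))
  invisible(res)
}

# expected file stems inside one detection folder's Results/
.expected_result_names <- function() {
  disp <- dispersion_windows()
  disp_names <- unlist(lapply(structural_map_names(), function(par)
    unlist(lapply(c("ENT", "SD", "MAD"), function(est)
      paste(par, est, disp$shape, disp$size, sep = "_")))))
  c(pshg_map_names(), disp_names)
}

#' Validate a collection tree against the expected inventory
#'
#' Walks a collection root laid out as
#' `root/[tissue]_[HE]_[roi]/[FSHG|BSHG]/...` and checks, per ROI: the 10
#' SHG frames of each detection geometry, the TPEF image, and (when
#' `check_results = TRUE`) the 8 fitted maps and 90 dispersion maps in
#' each `Results` subfolder. Extra files matching the SHG nomenclature and
#' unexpected `.tif` files in `Results` are reported too.
#'
#' @param root Collection root directory.
#' @param check_results Also require the computed maps (default `TRUE`).
#' @param expect_tpef Require one TPEF image per ROI (default `TRUE`).
#' @return A list of class `collection_report`: `ok` (logical), `summary`
#'   (tibble of expected vs observed counts) and `issues` (tibble with
#'   `roi`, `path`, `issue`).
#' @export
validate_collection <- function(root, check_results = TRUE,
                                expect_tpef = TRUE) {
  if (!dir.exists(root)) stop("unreadable root: ", root)
  roi_dirs <- list.dirs(root, recursive = FALSE)
  roi_dirs <- roi_dirs[grepl("^(breast|skin|thyroid|phantom)(_HE)?_[0-9]+$",
                             basename(roi_dirs))]
  issues <- list()
  note <- function(roi, path, issue)
    issues[[length(issues) + 1]] <<- tibble::tibble(
      roi = roi, path = path, issue = issue)
  n_shg <- 0L; n_tpef <- 0L; n_maps <- 0L; n_disp <- 0L; n_stacks <- 0L

  for (rd in roi_dirs) {
    roi <- basename(rd)
    # TPEF
    tpef <- file.path(rd, paste0(roi, "_TPEF.tif"))
    if (file.exists(tpef)) n_tpef <- n_tpef + 1L
    else if (expect_tpef) note(roi, tpef, "missing TPEF image")
    for (det in .detections) {
      dd <- file.path(rd, det)
      if (!dir.exists(dd)) { note(roi, dd, "missing detection folder"); next }
      frames <- list.files(dd, pattern = "\\.tif$")
      expect <- paste0(roi, "_", det, "_", pshg_angles(), ".tif")
      found <- intersect(expect, frames)
      n_shg <- n_shg + length(found)
      if (length(found) == 10L) n_stacks <- n_stacks + 1L
      for (f in setdiff(expect, frames))
        note(roi, file.path(dd, f), "missing SHG frame")
      for (f in setdiff(frames, expect))
        note(roi, file.path(dd, f), "unexpected file")
      if (check_results) {
        res <- file.path(dd, "Results")
        rfiles <- if (dir.exists(res))
          list.files(res, pattern = "\\.tif$") else character()
        rexpect <- paste0(.expected_result_names(), ".tif")
        rfound <- intersect(rexpect, rfiles)
        n_maps <- n_maps + sum(rfound %in% paste0(pshg_map_names(), ".tif"))
        n_disp <- n_disp + sum(!rfound %in% paste0(pshg_map_names(), ".tif"))
        for (f in setdiff(rexpect, rfiles))
          note(roi, file.path(res, f), "missing result map")
        for (f in setdiff(rfiles, c(rexpect, "R2_MASK.tif")))
          note(roi, file.path(res, f), "unexpected result file")
      }
    }
  }
  exp <- expected_counts(length(roi_dirs))
  observed <- tibble::tibble(
    rois = length(roi_dirs), stacks = n_stacks, shg_images = n_shg,
    tpef_images = n_tpef, ffpshg_maps = n_maps, dispersion_maps = n_disp,
    total_images = n_shg + n_tpef + n_maps + n_disp)
  issues <- if (length(issues)) dplyr::bind_rows(issues)
    else tibble::tibble(roi = character(), path = character(),
                        issue = character())
  summary <- dplyr::bind_rows(expected = exp, observed = observed,
                              .id = "which")
  structure(list(ok = nrow(issues) == 0, summary = summary, issues = issues),
            class = "collection_report")
}

#' @export
print.collection_report <- function(x, ...) {
  cat("<collection_report> ", if (x$ok) "OK" else
    sprintf("%d issue(s)", nrow(x$issues)), "\n", sep = "")
  print(x$summary)
  if (!x$ok) print(x$issues, n = 20)
  invisible(x)
}

#' Write a collection report as delimited text
#'
#' @param report A `collection_report`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "collection_report"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("ok\t%s", report$ok), con)
  utils::write.table(report$summary, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (nrow(report$issues))
    utils::write.table(report$issues, con, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  invisible(path)
}
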