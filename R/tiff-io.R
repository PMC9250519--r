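# Minimal IEEE 32-bit float TIFF reader/writer.
#
# The computationally generated maps are 32-bit floating-point grayscale
# TIFFs (SampleFormat = IEEEFP), a layout the CRAN tiff package cannot
# produce (it scales numeric data to integer samples). Files are written
# uncompressed, little-endian, single strip, one sample per pixel; the
# reader handles exactly that layout (which is also what ImageJ writes for
# uncompressed 32-bit images, modulo byte order).

.tiff_tags <- c(ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
                Compression = 259L, Photometric = 262L, StripOffsets = 273L,
                SamplesPerPixel = 277L, RowsPerStrip = 278L,
                StripByteCounts = 279L, SampleFormat = 339L)

#' Write a matrix as a 32-bit float TIFF
#'
#' Values (including `NaN`) are stored exactly up to single precision;
#' pixel order is row-major top-left origin, matching how the 8-bit frames
#' are read.
#'
#' @param img Numeric matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_float_tiff <- function(img, path) {
  stopifnot(is.matrix(img), is.numeric(img))
  h <- nrow(img); w <- ncol(img)
  data_offset <- 8L
  nbytes <- 4L * h * w
  ifd_offset <- data_offset + nbytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, nchars = 2, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd_offset, con, size = 4, endian = "little")
  # pixel data, row-major
  writeBin(as.numeric(t(img)), con, size = 4, endian = "little")
  # IFD
  entry <- function(tag, type, value) {
    writeBin(tag, con, size = 2, endian = "little")
    writeBin(type, con, size = 2, endian = "little")   # 3 = SHORT, 4 = LONG
    writeBin(1L, con, size = 4, endian = "little")
    if (type == 3L) {
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  tg <- .tiff_tags
  writeBin(10L, con, size = 2, endian = "little")  # entry count
  entry(tg[["ImageWidth"]], 4L, w)
  entry(tg[["ImageLength"]], 4L, h)
  entry(tg[["BitsPerSample"]], 3L, 32L)
  entry(tg[["Compression"]], 3L, 1L)
  entry(tg[["Photometric"]], 3L, 1L)     # black is zero
  entry(tg[["StripOffsets"]], 4L, data_offset)
  entry(tg[["SamplesPerPixel"]], 3L, 1L)
  entry(tg[["RowsPerStrip"]], 4L, h)
  entry(tg[["StripByteCounts"]], 4L, nbytes)
  entry(tg[["SampleFormat"]], 3L, 3L)    # IEEE float
  writeBin(0L, con, size = 4, endian = "little")  # no next IFD
  invisible(path)
}

#' Read a 32-bit float TIFF written by this package
#'
#' @param path File path.
#' @return Numeric matrix.
#' @export
read_float_tiff <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2, useBytes = TRUE)
  endian <- switch(magic, II = "little", MM = "big",
                   stop("not a TIFF file: ", path))
  if (readBin(con, "integer", size = 2, endian = endian) != 42L)
    stop("not a TIFF file: ", path)
  ifd <- readBin(con, "integer", size = 4, endian = endian)
  seek(con, ifd)
  n_entries <- readBin(con, "integer", size = 2, endian = endian)
  tags <- list()
  for (i in seq_len(n_entries)) {
    tag <- readBin(con, "integer", size = 2, endian = endian, signed = FALSE)
    type <- readBin(con, "integer", size = 2, endian = endian)
    count <- readBin(con, "integer", size = 4, endian = endian)
    value <- if (type == 3L) {
      v <- readBin(con, "integer", size = 2, endian = endian, signed = FALSE)
      readBin(con, "integer", size = 2, endian = endian)
      v
    } else {
      readBin(con, "integer", size = 4, endian = endian)
    }
    tags[[as.character(tag)]] <- c(value = value, count = count)
  }
  gettag <- function(id, default = NULL) {
    v <- tags[[as.character(id)]]
    if (is.null(v)) {
      if (is.null(default)) stop("missing TIFF tag ", id, " in ", path)
      default
    } else unname(v["value"])
  }
  tg <- .tiff_tags
  w <- gettag(tg[["ImageWidth"]]); h <- gettag(tg[["ImageLength"]])
  if (gettag(tg[["BitsPerSample"]]) != 32L ||
      gettag(tg[["SampleFormat"]], 1L) != 3L)
    stop(path, " is not a 32-bit float TIFF")
  if (gettag(tg[["Compression"]], 1L) != 1L)
    stop(path, ": compressed float TIFFs are not supported")
  offset <- gettag(tg[["StripOffsets"]])
  seek(con, offset)
  vals <- readBin(con, "numeric", n = h * w, size = 4, endian = endian)
  matrix(vals, h, w, byrow = TRUE)
}
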