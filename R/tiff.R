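# Minimal baseline TIFF codec for unsigned 16-bit images, 1 or 3 samples
# per pixel, uncompressed, chunky layout, little-endian. This is the only
# on-disk image format the pipeline needs; no TIFF library is assumed.

TIFF_TAGS <- c(
  ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
  Compression = 259L, Photometric = 262L, StripOffsets = 273L,
  SamplesPerPixel = 277L, RowsPerStrip = 278L, StripByteCounts = 279L,
  PlanarConfig = 284L, SampleFormat = 339L
)

#' Write an unsigned 16-bit TIFF
#'
#' Writes a single-image, uncompressed, little-endian baseline TIFF with one
#' (grayscale) or three (RGB) 16-bit samples per pixel, chunky planar layout,
#' one strip.
#'
#' @param x For one channel, an integer/numeric matrix (rows = image rows);
#'   for three channels, a list of three equally sized matrices in R, G, B
#'   order. Values must be in `[0, 65535]`; they are rounded to integers.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_tiff16()]
#' @export
write_tiff16 <- function(x, path) {
  chans <- if (is.matrix(x)) list(x) else x
  if (!is.list(chans) || !(length(chans) %in% c(1L, 3L)))
    stop("'x' must be a matrix or a list of 1 or 3 matrices")
  dims <- lapply(chans, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("all channels must share identical dimensions")
  h <- nrow(chans[[1L]]); w <- ncol(chans[[1L]]); spp <- length(chans)
  vals <- lapply(chans, function(m) {
    v <- matrix(round(as.numeric(m)), nrow(m), ncol(m))
    if (any(v < 0 | v > 65535)) stop("pixel values outside [0, 65535]")
    v
  })
  # sample-interleaved, row-major pixel stream
  px <- matrix(0, nrow = spp, ncol = h * w)
  for (s in seq_len(spp)) px[s, ] <- as.vector(t(vals[[s]]))
  stream <- as.integer(px)

  n_entries <- if (spp == 3L) 11L else 9L
  data_off <- 8L
  n_bytes <- length(stream) * 2L
  ifd_off <- data_off + n_bytes
  # external arrays (BitsPerSample, SampleFormat for spp == 3) follow the IFD
  ext_off <- ifd_off + 2L + n_entries * 12L + 4L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, nchars = 2, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd_off, con, size = 4, endian = "little")
  writeBin(stream, con, size = 2, endian = "little")

  entry <- function(tag, type, count, value, value_is_offset = FALSE) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L && !value_is_offset) { # SHORT packed into 4-byte slot
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }

  writeBin(n_entries, con, size = 2, endian = "little")
  entry(TIFF_TAGS[["ImageWidth"]], 4L, 1L, w)
  entry(TIFF_TAGS[["ImageLength"]], 4L, 1L, h)
  if (spp == 3L) {
    entry(TIFF_TAGS[["BitsPerSample"]], 3L, 3L, ext_off, value_is_offset = TRUE)
  } else {
    entry(TIFF_TAGS[["BitsPerSample"]], 3L, 1L, 16L)
  }
  entry(TIFF_TAGS[["Compression"]], 3L, 1L, 1L)
  entry(TIFF_TAGS[["Photometric"]], 3L, 1L, if (spp == 3L) 2L else 1L)
  entry(TIFF_TAGS[["StripOffsets"]], 4L, 1L, data_off)
  entry(TIFF_TAGS[["SamplesPerPixel"]], 3L, 1L, spp)
  entry(TIFF_TAGS[["RowsPerStrip"]], 4L, 1L, h)
  entry(TIFF_TAGS[["StripByteCounts"]], 4L, 1L, n_bytes)
  entry(TIFF_TAGS[["PlanarConfig"]], 3L, 1L, 1L)
  if (spp == 3L)
    entry(TIFF_TAGS[["SampleFormat"]], 3L, 3L, ext_off + 6L, value_is_offset = TRUE)
  writeBin(0L, con, size = 4, endian = "little") # next-IFD pointer
  if (spp == 3L) {
    writeBin(rep(16L, 3L), con, size = 2, endian = "little")
    writeBin(rep(1L, 3L), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an unsigned 16-bit TIFF
#'
#' Reads single-image uncompressed TIFFs with 16 bits per sample, 1 or 3
#' samples per pixel, chunky layout (as written by [write_tiff16()] or any
#' standard TIFF writer using those settings). Both byte orders are handled.
#'
#' @param path File path.
#' @return A matrix (one sample per pixel) or a list of three matrices in
#'   sample order (R, G, B).
#' @export
read_tiff16 <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  order_tag <- rawToChar(raw[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stop("not a TIFF file: ", path))
  rd <- function(off, size, n = 1L, signed = TRUE)
    readBin(raw[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            signed = signed, endian = endian)
  if (rd(2L, 2L, signed = FALSE) != 42L) stop("not a TIFF file: ", path)
  ifd <- rd(4L, 4L)
  n_entries <- rd(ifd, 2L, signed = FALSE)
  tags <- list()
  for (e in seq_len(n_entries)) {
    off <- ifd + 2L + (e - 1L) * 12L
    tag <- rd(off, 2L, signed = FALSE)
    type <- rd(off + 2L, 2L, signed = FALSE)
    count <- rd(off + 4L, 4L)
    val <- if (type == 3L) {
      if (count <= 2L) rd(off + 8L, 2L, n = count, signed = FALSE)
      else rd(rd(off + 8L, 4L), 2L, n = count, signed = FALSE)
    } else if (type == 4L) {
      if (count <= 1L) rd(off + 8L, 4L)
      else rd(rd(off + 8L, 4L), 4L, n = count)
    } else NULL
    if (!is.null(val)) tags[[as.character(tag)]] <- val
  }
  g <- function(tag, default = NULL) {
    v <- tags[[as.character(TIFF_TAGS[[tag]])]]
    if (is.null(v)) default else v
  }
  w <- g("ImageWidth"); h <- g("ImageLength")
  if (is.null(w) || is.null(h)) stop("TIFF missing dimensions")
  bps <- g("BitsPerSample", 1L)
  if (any(bps != 16L)) stop("only 16-bit samples are supported")
  if (g("Compression", 1L) != 1L) stop("only uncompressed TIFF is supported")
  spp <- g("SamplesPerPixel", 1L)
  if (!(spp %in% c(1L, 3L))) stop("only 1 or 3 samples per pixel supported")
  if (spp == 3L && g("PlanarConfig", 1L) != 1L)
    stop("only chunky planar layout is supported")
  offs <- g("StripOffsets"); counts <- g("StripByteCounts")
  stream <- integer(0)
  for (s in seq_along(offs)) {
    nvals <- counts[s] %/% 2L
    stream <- c(stream, rd(offs[s], 2L, n = nvals, signed = FALSE))
  }
  if (length(stream) != h * w * spp) stop("TIFF pixel data truncated")
  px <- matrix(stream, nrow = spp)
  chans <- lapply(seq_len(spp), function(s)
    matrix(px[s, ], nrow = h, ncol = w, byrow = TRUE))
  if (spp == 1L) chans[[1L]] else chans
}
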