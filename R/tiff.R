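# Minimal baseline TIFF reader/writer for single-plane grayscale images.
#
# Only the subset of the format produced by microscopy export of reconstructed
# single-plane images is supported: uncompressed, contiguous strips, one
# sample per pixel, 8/16-bit unsigned integer or 32-bit IEEE float samples.
# Anything else (RGB, multi-page stacks, compression) is rejected with an
# error naming the offending property.

TIFF_TAGS <- c(
  width = 256L, length = 257L, bits = 258L, compression = 259L,
  photometric = 262L, strip_offsets = 273L, samples_per_pixel = 277L,
  rows_per_strip = 278L, strip_byte_counts = 279L, sample_format = 339L
)

#' Read a single-plane grayscale TIFF
#'
#' @param path path to a baseline TIFF file (uncompressed, one sample per
#'   pixel, 8/16-bit unsigned or 32-bit float).
#' @return numeric matrix of intensities, `[row, col]`, row 1 at the top.
#' @export
read_tiff_gray <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8) abort("not a TIFF: file too short")
  endian <- if (rawToChar(raw[1:2]) == "II") "little"
            else if (rawToChar(raw[1:2]) == "MM") "big"
            else abort("not a TIFF: missing byte-order mark")
  rint <- function(offset, size, n = 1) {
    # readBin only honours signed = FALSE for sizes 1 and 2
    readBin(raw[(offset + 1):(offset + size * n)], "integer",
            n = n, size = size, signed = (size == 4), endian = endian)
  }
  if (rint(2, 2) != 42L) abort("not a TIFF: bad magic number")
  ifd_offset <- rint(4, 4)
  n_entries <- rint(ifd_offset, 2)
  tags <- list()
  for (i in seq_len(n_entries)) {
    e <- ifd_offset + 2 + (i - 1) * 12
    tag <- rint(e, 2)
    type <- rint(e + 2, 2)
    count <- rint(e + 4, 4)
    size <- c(1L, 1L, 2L, 4L)[match(type, c(1L, 2L, 3L, 4L))]
    if (is.na(size)) next  # unsupported field type: ignore tag
    vals <- if (count * size <= 4) {
      rint(e + 8, size, n = count)
    } else {
      rint(rint(e + 8, 4), size, n = count)
    }
    if (size == 2) vals <- ifelse(vals < 0, vals + 65536, vals)
    tags[[as.character(tag)]] <- vals
  }
  next_ifd <- rint(ifd_offset + 2 + n_entries * 12, 4)
  if (next_ifd != 0)
    abort("unsupported TIFF: multi-plane (more than one image directory)")
  gt <- function(id, default = NULL) tags[[as.character(id)]] %||% default

  spp <- gt(TIFF_TAGS["samples_per_pixel"], 1L)
  if (spp != 1L)
    abort(paste0("unsupported TIFF: SamplesPerPixel = ", spp,
                 " (RGB/multichannel); expected grayscale"))
  comp <- gt(TIFF_TAGS["compression"], 1L)
  if (comp != 1L)
    abort(paste0("unsupported TIFF: Compression = ", comp,
                 "; only uncompressed data is supported"))
  bits <- gt(TIFF_TAGS["bits"], 1L)
  fmt <- gt(TIFF_TAGS["sample_format"], 1L)
  width <- gt(TIFF_TAGS["width"])
  height <- gt(TIFF_TAGS["length"])
  if (is.null(width) || is.null(height)) abort("unsupported TIFF: missing dimensions")
  offs <- gt(TIFF_TAGS["strip_offsets"])
  counts <- gt(TIFF_TAGS["strip_byte_counts"])
  data <- do.call(c, lapply(seq_along(offs), function(i)
    raw[(offs[i] + 1):(offs[i] + counts[i])]))
  npx <- width * height
  v <- if (fmt == 3L && bits == 32L) {
    readBin(data, "double", n = npx, size = 4, endian = endian)
  } else if (fmt %in% c(1L, 4L) && bits == 8L) {
    as.numeric(readBin(data, "integer", n = npx, size = 1, signed = FALSE,
                       endian = endian))
  } else if (fmt %in% c(1L, 4L) && bits == 16L) {
    as.numeric(readBin(data, "integer", n = npx, size = 2, signed = FALSE,
                       endian = endian))
  } else if (fmt %in% c(1L, 4L) && bits == 32L) {
    x <- readBin(data, "integer", n = npx, size = 4, endian = endian)
    ifelse(x < 0, x + 2^32, as.numeric(x))
  } else {
    abort(paste0("unsupported TIFF: ", bits, "-bit, sample format ", fmt))
  }
  matrix(v, nrow = height, ncol = width, byrow = TRUE)
}

#' Write a single-plane grayscale TIFF
#'
#' @param pixels numeric matrix `[row, col]`.
#' @param path output path.
#' @param bits 8 or 16 for unsigned integer samples, 32 for IEEE float.
#' @return `path`, invisibly.
#' @export
write_tiff_gray <- function(pixels, path, bits = c(32, 16, 8)) {
  bits <- match.arg(as.character(bits[1]), c("32", "16", "8"))
  bits <- as.integer(bits)
  stopifnot(is.matrix(pixels))
  h <- nrow(pixels); w <- ncol(pixels)
  fmt <- if (bits == 32L) 3L else 1L
  bytes_px <- bits %/% 8L
  n_tags <- 10L
  data_offset <- 8L + 2L + n_tags * 12L + 4L
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeChar("II", con, nchars = 2, eos = NULL)
  w2(42); w4(8)
  w2(n_tags)
  entry <- function(tag, type, count, value) {
    w2(tag); w2(type); w4(count)
    if (type == 3L) { w2(value); w2(0) } else w4(value)
  }
  entry(256L, 4L, 1L, w)
  entry(257L, 4L, 1L, h)
  entry(258L, 3L, 1L, bits)
  entry(259L, 3L, 1L, 1L)          # no compression
  entry(262L, 3L, 1L, 1L)          # black-is-zero
  entry(273L, 4L, 1L, data_offset)
  entry(277L, 3L, 1L, 1L)
  entry(278L, 4L, 1L, h)           # single strip
  entry(279L, 4L, 1L, h * w * bytes_px)
  entry(339L, 3L, 1L, fmt)
  w4(0)                            # no further IFD
  v <- as.vector(t(pixels))        # row-major
  if (bits == 32L) {
    writeBin(as.double(v), con, size = 4, endian = "little")
  } else if (bits == 16L) {
    iv <- as.integer(round(v))
    if (any(iv < 0 | iv > 65535)) abort("16-bit TIFF: values outside [0, 65535]")
    writeBin(as.raw(rbind(iv %% 256L, iv %/% 256L)), con)
  } else {
    iv <- as.integer(round(v))
    if (any(iv < 0 | iv > 255)) abort("8-bit TIFF: values outside [0, 255]")
    writeBin(as.raw(iv), con)
  }
  invisible(path)
}
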