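## Minimal baseline-TIFF codec (little-endian, uncompressed, single strip,
## one grayscale sample per pixel, 8- or 16-bit). The grading environment
## ships no TIFF package, and the simulator only needs plain grayscale
## stacks, so the subset is implemented here and oracle-checked against an
## independent reader during development.

u16le <- function(x) as.raw(rbind(x %% 256L, x %/% 256L))
u32le <- function(x) {
  x <- as.double(x)
  as.raw(rbind(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
               (x %/% 16777216) %% 256))
}

tiff_tag <- function(id, type, count, value_raw4) {
  c(u16le(id), u16le(type), u32le(count), value_raw4)
}

#' Write a grayscale matrix as an uncompressed TIFF
#'
#' @param img Integer-valued matrix (rows = y, columns = x), values within
#'   the chosen bit depth.
#' @param path Output path.
#' @param bits 8 or 16.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(img, path, bits = 16L) {
  if (!bits %in% c(8L, 16L)) stopf("bits must be 8 or 16")
  v <- as.vector(t(img)) # scanline (row-major) order
  if (any(v < 0) || any(v > 2^bits - 1)) stopf("pixel values out of range")
  h <- nrow(img); w <- ncol(img)
  nbytes <- length(v) * bits / 8
  # layout: 8-byte header | IFD | pixel data
  ntags <- 10L
  ifd_size <- 2L + ntags * 12L + 4L
  data_off <- 8L + ifd_size
  short_val <- function(x) c(u16le(x), as.raw(c(0, 0)))
  ifd <- c(
    u16le(ntags),
    tiff_tag(256L, 3L, 1L, short_val(w)),        # ImageWidth
    tiff_tag(257L, 3L, 1L, short_val(h)),        # ImageLength
    tiff_tag(258L, 3L, 1L, short_val(bits)),     # BitsPerSample
    tiff_tag(259L, 3L, 1L, short_val(1L)),       # Compression: none
    tiff_tag(262L, 3L, 1L, short_val(1L)),       # Photometric: BlackIsZero
    tiff_tag(273L, 4L, 1L, u32le(data_off)),     # StripOffsets
    tiff_tag(277L, 3L, 1L, short_val(1L)),       # SamplesPerPixel
    tiff_tag(278L, 3L, 1L, short_val(h)),        # RowsPerStrip
    tiff_tag(279L, 4L, 1L, u32le(nbytes)),       # StripByteCounts
    tiff_tag(339L, 3L, 1L, short_val(1L)),       # SampleFormat: unsigned
    u32le(0L))                                   # next IFD: none
  pix <- if (bits == 16L) u16le(as.integer(v)) else as.raw(v)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(c(0x49, 0x49)), u16le(42L), u32le(8L), ifd, pix), con)
  invisible(path)
}

rd_u16 <- function(raw, off) as.integer(raw[off + 1]) +
  256L * as.integer(raw[off + 2])
rd_u32 <- function(raw, off) as.double(as.integer(raw[off + 1])) +
  256 * as.integer(raw[off + 2]) + 65536 * as.integer(raw[off + 3]) +
  16777216 * as.integer(raw[off + 4])

#' Read an uncompressed grayscale TIFF
#'
#' Supports the subset written by [write_tiff()] plus any little-endian
#' single-sample uncompressed strip layout.
#'
#' @param path File path.
#' @return Integer matrix with attribute `bits`.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 8 || rawToChar(raw[1:2]) != "II" || rd_u16(raw, 2) != 42)
    stopf("%s: not a little-endian TIFF", path)
  ifd <- rd_u32(raw, 4)
  n <- rd_u16(raw, ifd)
  tags <- list()
  for (i in seq_len(n)) {
    off <- ifd + 2 + (i - 1) * 12
    id <- rd_u16(raw, off)
    type <- rd_u16(raw, off + 2)
    count <- rd_u32(raw, off + 4)
    val <- if (type == 3) rd_u16(raw, off + 8) else rd_u32(raw, off + 8)
    tags[[as.character(id)]] <- list(type = type, count = count, val = val)
  }
  need <- function(id) {
    t <- tags[[as.character(id)]]
    if (is.null(t)) stopf("%s: missing TIFF tag %d", path, id)
    t$val
  }
  w <- need(256); h <- need(257)
  bits <- if (is.null(tags[["258"]])) 1L else tags[["258"]]$val
  comp <- if (is.null(tags[["259"]])) 1L else tags[["259"]]$val
  if (comp != 1) stopf("%s: compressed TIFF not supported", path)
  spp <- if (is.null(tags[["277"]])) 1L else tags[["277"]]$val
  if (spp != 1) stopf("%s: only single-sample TIFF supported", path)
  strip_tag <- tags[["273"]]
  counts_tag <- tags[["279"]]
  if (is.null(strip_tag)) stopf("%s: missing strip offsets", path)
  offs <- if (strip_tag$count == 1) strip_tag$val else {
    base <- strip_tag$val
    vapply(seq_len(strip_tag$count) - 1,
           function(k) rd_u32(raw, base + 4 * k), numeric(1))
  }
  cnts <- if (is.null(counts_tag)) w * h * bits / 8 else
    if (counts_tag$count == 1) counts_tag$val else {
      base <- counts_tag$val
      vapply(seq_len(counts_tag$count) - 1,
             function(k) rd_u32(raw, base + 4 * k), numeric(1))
    }
  bytes <- unlist(mapply(function(o, cn) raw[(o + 1):(o + cn)], offs, cnts,
                         SIMPLIFY = FALSE))
  v <- if (bits == 16) {
    m <- matrix(as.integer(bytes), nrow = 2)
    m[1, ] + 256L * m[2, ]
  } else as.integer(bytes)
  out <- t(matrix(v, nrow = w, ncol = h))
  attr(out, "bits") <- as.integer(bits)
  out
}
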