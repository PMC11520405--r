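# Minimal baseline TIFF I/O (uncompressed, grayscale, 8/16-bit, single- and
# multi-page, little-endian).  No CRAN TIFF reader is available in this
# stack, and the format subset needed for simulator round-trips is small
# enough to implement directly.  Images are float matrices in [0, 1] in
# memory; quantization to the integer sample depth is the only lossy step.

TIFF_TAGS <- c(
  width = 256L, length = 257L, bits = 258L, compression = 259L,
  photometric = 262L, strip_offsets = 273L, rows_per_strip = 278L,
  strip_byte_counts = 279L, sample_format = 339L
)

#' Write grayscale images as an uncompressed TIFF
#'
#' @param images A numeric matrix in `[0, 1]`, or a list of equally sized
#'   matrices (written as a multi-page stack).
#' @param path Output file path.
#' @param bits Sample depth, 8 or 16 (default 16).
#' @return `path`, invisibly.
#' @seealso [read_tiff()]
#' @export
write_tiff <- function(images, path, bits = 16L) {
  if (is.matrix(images)) images <- list(images)
  stopifnot(length(images) >= 1, bits %in% c(8L, 16L))
  for (im in images) check_image01(im)
  maxval <- 2^bits - 1
  con <- file(path, "wb")
  on.exit(close(con))
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  writeBin(charToRaw("II"), con)
  w2(42L)
  # layout per page: [pixel data][IFD]; first IFD offset written after header
  n <- length(images)
  offset_pos <- 4L
  w4(8L)  # first IFD offset placeholder (we compute exactly below)
  # We stream sequentially: header(8) then for each page data then IFD.
  # Compute offsets up front.
  H <- nrow(images[[1]]); W <- ncol(images[[1]])
  bytes_per_page <- H * W * (bits / 8)
  ifd_size <- 2 + 9 * 12 + 4
  data_off <- integer(n); ifd_off <- integer(n)
  pos <- 8
  for (i in seq_len(n)) {
    data_off[i] <- pos
    ifd_off[i] <- pos + bytes_per_page
    pos <- ifd_off[i] + ifd_size
  }
  # rewrite first IFD offset
  seek(con, offset_pos, rw = "write")
  w4(ifd_off[1])
  seek(con, 8, rw = "write")
  entry <- function(tag, type, count, value) {
    w2(tag); w2(type); w4(count); w4(value)
  }
  for (i in seq_len(n)) {
    im <- images[[i]]
    if (nrow(im) != H || ncol(im) != W) {
      stop("all pages must share one image size", call. = FALSE)
    }
    # TIFF stores rows (scanlines) contiguously: transpose column-major matrix
    px <- as.integer(round(t(im) * maxval))
    if (bits == 8L) {
      writeBin(as.raw(px), con)
    } else {
      writeBin(px, con, size = 2, endian = "little")
    }
    w2(9L)  # entry count
    entry(TIFF_TAGS[["width"]], 3L, 1L, W)
    entry(TIFF_TAGS[["length"]], 3L, 1L, H)
    entry(TIFF_TAGS[["bits"]], 3L, 1L, bits)
    entry(TIFF_TAGS[["compression"]], 3L, 1L, 1L)
    entry(TIFF_TAGS[["photometric"]], 3L, 1L, 1L)  # BlackIsZero
    entry(TIFF_TAGS[["strip_offsets"]], 4L, 1L, data_off[i])
    entry(TIFF_TAGS[["rows_per_strip"]], 3L, 1L, H)
    entry(TIFF_TAGS[["strip_byte_counts"]], 4L, 1L, bytes_per_page)
    entry(TIFF_TAGS[["sample_format"]], 3L, 1L, 1L)  # unsigned integer
    w4(if (i < n) ifd_off[i + 1] else 0L)
  }
  invisible(path)
}

#' Read an uncompressed grayscale TIFF
#'
#' Supports the subset written by [write_tiff()] plus single-strip or
#' multi-strip uncompressed grayscale files (8 or 16 bit, little-endian).
#'
#' @param path File path.
#' @return A list of numeric matrices in `[0, 1]`, one per page.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 8) stop("not a TIFF file: ", path, call. = FALSE)
  if (!(raw[1] == as.raw(0x49) && raw[2] == as.raw(0x49))) {
    stop("only little-endian TIFF is supported", call. = FALSE)
  }
  u16 <- function(off) as.integer(raw[off + 1]) + 256L * as.integer(raw[off + 2])
  u32 <- function(off) {
    as.numeric(raw[off + 1]) + 256 * as.numeric(raw[off + 2]) +
      65536 * as.numeric(raw[off + 3]) + 16777216 * as.numeric(raw[off + 4])
  }
  if (u16(2) != 42L) stop("bad TIFF magic in ", path, call. = FALSE)
  ifd <- u32(4)
  pages <- list()
  while (ifd != 0) {
    nentries <- u16(ifd)
    tags <- list()
    for (e in seq_len(nentries)) {
      off <- ifd + 2 + (e - 1) * 12
      tag <- u16(off); type <- u16(off + 2); count <- u32(off + 4)
      value <- if (type == 3 && count == 1) u16(off + 8) else u32(off + 8)
      # multi-valued strip arrays stored out-of-line
      if (count > 1 && tag %in% c(273L, 279L)) {
        ptr <- u32(off + 8)
        sz <- if (type == 3) 2 else 4
        value <- vapply(seq_len(count), function(k) {
          if (sz == 2) u16(ptr + (k - 1) * 2) else u32(ptr + (k - 1) * 4)
        }, numeric(1))
      }
      tags[[as.character(tag)]] <- value
    }
    g <- function(tag, default = NULL) tags[[as.character(tag)]] %||% default
    W <- g(256L); H <- g(257L); bits <- g(258L, 1L)
    if (is.null(W) || is.null(H)) stop("TIFF page missing size tags", call. = FALSE)
    if (g(259L, 1L) != 1L) stop("compressed TIFF not supported", call. = FALSE)
    if (!bits %in% c(8, 16)) stop("only 8/16-bit grayscale supported", call. = FALSE)
    offs <- g(273L); counts <- g(279L, H * W * bits / 8)
    px <- integer(0)
    for (s in seq_along(offs)) {
      nb <- counts[min(s, length(counts))]
      chunk <- raw[(offs[s] + 1):(offs[s] + nb)]
      px <- c(px, if (bits == 8) {
        as.integer(chunk)
      } else {
        readBin(chunk, "integer", n = nb / 2, size = 2, signed = FALSE,
                endian = "little")
      })
    }
    im <- matrix(px / (2^bits - 1), nrow = H, ncol = W, byrow = TRUE)
    pages[[length(pages) + 1]] <- im
    ifd <- u32(ifd + 2 + nentries * 12)
  }
  pages
}

#' Read a grayscale image (TIFF or PNG)
#'
#' PNG support requires the optional \pkg{png} package; RGB input is
#' converted to grayscale by channel averaging.
#'
#' @param path File path ending in `.tif`, `.tiff` or `.png`.
#' @return A numeric matrix in `[0, 1]` (first page for TIFF stacks).
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) return(read_tiff(path)[[1]])
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("reading PNG requires the 'png' package", call. = FALSE)
    }
    im <- png::readPNG(path)
    if (length(dim(im)) == 3) im <- apply(im[, , 1:min(3, dim(im)[3])], c(1, 2), mean)
    return(im)
  }
  stop("unsupported image format: ", path, call. = FALSE)
}
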