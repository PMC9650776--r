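# Minimal baseline TIFF support (little-endian, uncompressed, single-sample,
# one strip per page, 32-bit float or 8/16-bit unsigned integer). No TIFF
# package is assumed; this covers exactly the stacks the simulator writes
# plus plain camera exports. The sample-plane pixel size is carried in the
# ImageDescription tag as "pixel_size_nm=<value>".

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, description = 270L, strip_offsets = 273L,
               samples_per_px = 277L, rows_per_strip = 278L,
               strip_bytes = 279L, sample_format = 339L)

#' Write a frame stack as a multi-page TIFF
#'
#' Uncompressed little-endian baseline TIFF, 32-bit float samples, one page
#' per frame. The pixel size (nm) is embedded in each page's
#' ImageDescription tag so that [read_frames()] round-trips it.
#'
#' @param stack A [frame_stack()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_frames <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2,
                              endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4,
                              endian = "little")
  dims <- dim(stack$pixels)
  ny <- dims[1]; nx <- dims[2]; nf <- dims[3]
  desc <- sprintf("pixel_size_nm=%.6g", stack$pixel_size_nm)
  desc_raw <- c(charToRaw(desc), as.raw(0))
  n_entries <- 11L
  ifd_size <- 2 + n_entries * 12 + 4
  data_bytes <- nx * ny * 4

  writeBin(charToRaw("II"), con); w16(42L); w32(8L)  # header -> first IFD at 8
  offset <- 8
  for (f in seq_len(nf)) {
    ifd_off <- offset
    data_off <- ifd_off + ifd_size
    desc_off <- data_off + data_bytes
    next_off <- desc_off + length(desc_raw)
    entry <- function(tag, type, count, value) {
      w16(tag); w16(type); w32(count)
      if (type == 3L) { w16(value); w16(0L) } else w32(value)
    }
    w16(n_entries)
    entry(TIFF_TAGS["width"], 4L, 1L, nx)
    entry(TIFF_TAGS["length"], 4L, 1L, ny)
    entry(TIFF_TAGS["bits"], 3L, 1L, 32L)
    entry(TIFF_TAGS["compression"], 3L, 1L, 1L)
    entry(TIFF_TAGS["photometric"], 3L, 1L, 1L)
    entry(TIFF_TAGS["description"], 2L, length(desc_raw), desc_off)
    entry(TIFF_TAGS["strip_offsets"], 4L, 1L, data_off)
    entry(TIFF_TAGS["samples_per_px"], 3L, 1L, 1L)
    entry(TIFF_TAGS["rows_per_strip"], 4L, 1L, ny)
    entry(TIFF_TAGS["strip_bytes"], 4L, 1L, data_bytes)
    entry(TIFF_TAGS["sample_format"], 3L, 1L, 3L)
    w32(if (f < nf) next_off else 0L)
    writeBin(as.numeric(t(stack$pixels[, , f])), con, size = 4,
             endian = "little")
    writeBin(desc_raw, con)
    offset <- next_off
  }
  invisible(path)
}

#' Read a multi-page TIFF into a frame stack
#'
#' Supports the uncompressed baseline subset written by [write_frames()]
#' (little-endian, single sample per pixel, float32 or uint8/uint16).
#' Malformed or unsupported pages raise an error naming the page. If no
#' pixel-size tag is present, `fallback_pixel_size_nm` is used with a
#' warning.
#'
#' @param path TIFF file path.
#' @param fallback_pixel_size_nm Pixel size to assume when the file carries
#'   none.
#' @return A [frame_stack()].
#' @export
read_frames <- function(path, fallback_pixel_size_nm = 126.4) {
  if (!file.exists(path)) stop("TIFF file not found: ", path)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8 || rawToChar(raw[1:2]) != "II")
    stop("not a little-endian TIFF file: ", path)
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.integer(raw[off + 1:4]) * 256^(0:3))
  if (u16(2) != 42) stop("bad TIFF magic number in ", path)
  ifd <- u32(4)
  frames <- list()
  pixel_size <- NA_real_
  page <- 0L
  while (ifd != 0) {
    page <- page + 1L
    n <- u16(ifd)
    tags <- list()
    for (e in seq_len(n)) {
      base <- ifd + 2 + (e - 1) * 12
      tag <- u16(base); type <- u16(base + 2); count <- u32(base + 4)
      val <- if (type == 3L) u16(base + 8) else u32(base + 8)
      tags[[as.character(tag)]] <- list(type = type, count = count,
                                        value = val)
    }
    need <- function(tag, default = NULL) {
      t_ <- tags[[as.character(TIFF_TAGS[tag])]]
      if (is.null(t_)) {
        if (is.null(default))
          stop("TIFF page ", page, " lacks required tag ", tag)
        return(default)
      }
      t_$value
    }
    nx <- need("width"); ny <- need("length")
    if (need("compression", 1L) != 1L)
      stop("TIFF page ", page, " is compressed; only baseline uncompressed is supported")
    bits <- need("bits", 32L)
    fmt <- need("sample_format", 1L)
    strip_off <- need("strip_offsets")
    n_strips <- tags[[as.character(TIFF_TAGS["strip_offsets"])]]$count
    if (n_strips != 1L) {
      # multiple strips: offsets stored out-of-line as LONGs
      offs <- vapply(seq_len(n_strips) - 1L,
                     function(k) u32(strip_off + 4 * k), numeric(1))
    } else offs <- strip_off
    dtag <- tags[[as.character(TIFF_TAGS["description"])]]
    if (!is.null(dtag) && is.na(pixel_size)) {
      dr <- raw[dtag$value + seq_len(dtag$count)]
      txt <- rawToChar(dr[dr != as.raw(0)])
      m <- regmatches(txt, regexec("pixel_size_nm=([0-9.eE+-]+)", txt))[[1]]
      if (length(m) == 2) pixel_size <- as.numeric(m[2])
    }
    bytes_px <- bits / 8
    total <- nx * ny
    rows_per_strip <- need("rows_per_strip", ny)
    vals <- numeric(0)
    for (s in seq_along(offs)) {
      n_rows <- min(rows_per_strip, ny - (s - 1) * rows_per_strip)
      n_px <- n_rows * nx
      chunk <- raw[offs[s] + seq_len(n_px * bytes_px)]
      v <- if (fmt == 3L && bits == 32L) {
        readBin(chunk, "numeric", n = n_px, size = 4, endian = "little")
      } else if (fmt <= 1L && bits %in% c(8L, 16L)) {
        readBin(chunk, "integer", n = n_px, size = bytes_px, signed = FALSE,
                endian = "little")
      } else {
        stop("TIFF page ", page, ": unsupported sample layout (", bits,
             " bits, format ", fmt, ")")
      }
      vals <- c(vals, v)
    }
    if (length(vals) != total)
      stop("TIFF page ", page, " is truncated")
    frames[[page]] <- t(matrix(vals, nrow = nx, ncol = ny))  # rows stored x-fastest
    ifd <- u32(ifd + 2 + n * 12)
  }
  if (length(frames) == 0) stop("TIFF file has no pages: ", path)
  if (is.na(pixel_size)) {
    warning("no pixel-size tag found; assuming ", fallback_pixel_size_nm,
            " nm/px")
    pixel_size <- fallback_pixel_size_nm
  }
  pixels <- array(0, c(nrow(frames[[1]]), ncol(frames[[1]]), length(frames)))
  for (f in seq_along(frames)) pixels[, , f] <- frames[[f]]
  frame_stack(pixels, pixel_size)
}
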