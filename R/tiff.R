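# Minimal uncompressed little-endian TIFF dialect for image stacks:
# 64-bit float samples (bit-exact round trips), one strip per page, pages in
# TZYX order, axis metadata as JSON in the first page's ImageDescription.
# No TIFF library exists in this R environment, so the subset is implemented
# directly; files are readable by standard tools (e.g. Python's tifffile).

TIFF_TYPE_ASCII <- 2L; TIFF_TYPE_SHORT <- 3L; TIFF_TYPE_LONG <- 4L

#' Write an image stack as OME-style TIFF
#'
#' Pages are the T x Z planes in TZYX order; the first page's
#' ImageDescription carries JSON metadata (`axes`, `T`, `Z`, timestamps,
#' modality), which [read_stack()] uses to reassemble the stack. Samples are
#' 64-bit floats, so write-then-read round trips are bit-exact.
#'
#' @param stack an [image_stack()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  Tn <- d[1]; Zn <- d[2]; H <- d[3]; W <- d[4]
  desc <- as.character(jsonlite::toJSON(list(
    axes = "TZYX", T = Tn, Z = Zn,
    timestamps_s = stack$timestamps_s, modality = stack$modality,
    position = stack$position), auto_unbox = TRUE, digits = NA))
  desc_raw <- c(charToRaw(desc), as.raw(0))
  if (length(desc_raw) %% 2L == 1L) desc_raw <- c(desc_raw, as.raw(0))

  n_pages <- Tn * Zn
  page_bytes <- H * W * 8L
  n_entries <- c(10L, rep(9L, max(n_pages - 1L, 0L)))  # page 1 adds the description
  ifd_bytes <- 2L + n_entries * 12L + 4L

  desc_off <- 8L
  data_off <- desc_off + length(desc_raw)
  data_offs <- data_off + (seq_len(n_pages) - 1L) * page_bytes
  ifd0 <- data_off + n_pages * page_bytes
  ifd_offs <- ifd0 + cumsum(c(0L, head(ifd_bytes, -1L)))

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(as.integer(ifd_offs[1]), con, size = 4, endian = "little")
  writeBin(desc_raw, con)
  for (p in seq_len(n_pages)) {
    ti <- ((p - 1L) %/% Zn) + 1L
    zi <- ((p - 1L) %% Zn) + 1L
    plane <- stack$data[ti, zi, , ]
    writeBin(as.numeric(t(plane)), con, size = 8, endian = "little")
  }
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == TIFF_TYPE_SHORT && count == 1L) {
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  for (p in seq_len(n_pages)) {
    writeBin(n_entries[p], con, size = 2, endian = "little")
    entry(256, TIFF_TYPE_LONG, 1, W)              # ImageWidth
    entry(257, TIFF_TYPE_LONG, 1, H)              # ImageLength
    entry(258, TIFF_TYPE_SHORT, 1, 64)            # BitsPerSample
    entry(259, TIFF_TYPE_SHORT, 1, 1)             # Compression: none
    entry(262, TIFF_TYPE_SHORT, 1, 1)             # Photometric: BlackIsZero
    if (p == 1L)
      entry(270, TIFF_TYPE_ASCII, length(desc_raw), desc_off)
    entry(273, TIFF_TYPE_LONG, 1, data_offs[p])   # StripOffsets
    entry(278, TIFF_TYPE_LONG, 1, H)              # RowsPerStrip
    entry(279, TIFF_TYPE_LONG, 1, page_bytes)     # StripByteCounts
    entry(339, TIFF_TYPE_SHORT, 1, 3)             # SampleFormat: IEEE float
    nxt <- if (p < n_pages) ifd_offs[p + 1L] else 0L
    writeBin(as.integer(nxt), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read an image stack written by [write_stack()]
#'
#' Multi-page files must carry the JSON axis metadata in the first page's
#' ImageDescription; a plain single-page 2D TIFF is promoted to T = 1,
#' Z = 1 with a warning.
#'
#' @param path file path.
#' @return an [image_stack()].
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("read_stack: no such file: ", path)
  raw <- readBin(path, "raw", file.info(path)$size)
  fail <- function(why) stop(sprintf("read_stack: %s in '%s'", why, path),
                             call. = FALSE)
  if (length(raw) < 8) fail("truncated header")
  if (rawToChar(raw[1:2]) != "II") fail("not a little-endian TIFF")
  u16 <- function(off) as.integer(raw[off + 1L]) +
    256L * as.integer(raw[off + 2L])
  u32 <- function(off) u16(off) + 65536 * u16(off + 2L)
  if (u16(2L) != 42L) fail("bad TIFF magic")

  ifd_off <- u32(4L)
  pages <- list(); desc <- NULL
  while (ifd_off != 0) {
    if (ifd_off + 2 > length(raw)) fail("IFD offset out of range")
    n <- u16(ifd_off)
    tags <- list()
    for (k in seq_len(n)) {
      e <- ifd_off + 2L + (k - 1L) * 12L
      tag <- u16(e); type <- u16(e + 2L); count <- u32(e + 4L)
      val <- if (type == TIFF_TYPE_SHORT && count == 1L) u16(e + 8L)
             else u32(e + 8L)
      tags[[as.character(tag)]] <- list(type = type, count = count,
                                        value = val)
    }
    pages[[length(pages) + 1L]] <- tags
    if (is.null(desc) && !is.null(tags[["270"]])) {
      dt <- tags[["270"]]
      bytes <- raw[dt$value + seq_len(dt$count)]
      bytes <- bytes[bytes != as.raw(0)]
      desc <- rawToChar(bytes)
    }
    ifd_off <- u32(ifd_off + 2L + n * 12L)
    if (length(pages) > 100000L) fail("IFD loop")
  }
  if (length(pages) == 0) fail("no IFDs")

  read_page <- function(tags) {
    need <- c("256", "257", "273", "279")
    if (!all(need %in% names(tags))) fail("missing required tags")
    W <- tags[["256"]]$value; H <- tags[["257"]]$value
    off <- tags[["273"]]$value; nbytes <- tags[["279"]]$value
    bits <- if (!is.null(tags[["258"]])) tags[["258"]]$value else 64L
    fmt <- if (!is.null(tags[["339"]])) tags[["339"]]$value else 3L
    if (!is.null(tags[["259"]]) && tags[["259"]]$value != 1L)
      fail("compressed TIFF not supported")
    if (off + nbytes > length(raw)) fail("strip data out of range")
    bytes <- raw[off + seq_len(nbytes)]
    vals <- if (fmt == 3L && bits == 64L) {
      readBin(bytes, "double", n = H * W, size = 8, endian = "little")
    } else if (fmt == 3L && bits == 32L) {
      readBin(bytes, "double", n = H * W, size = 4, endian = "little")
    } else if (bits == 16L) {
      readBin(bytes, "integer", n = H * W, size = 2, signed = FALSE,
              endian = "little")
    } else if (bits == 8L) {
      as.integer(bytes)
    } else fail(sprintf("unsupported sample format (%d bits)", bits))
    t(matrix(as.numeric(vals), nrow = W, ncol = H))  # scanlines are rows
  }
  planes <- lapply(pages, read_page)

  meta <- if (!is.null(desc))
    tryCatch(jsonlite::fromJSON(desc), error = function(e) NULL) else NULL
  if (is.null(meta) || is.null(meta$axes)) {
    if (length(planes) == 1L) {
      warning("no axis metadata; promoting 2D TIFF to T=1, Z=1")
      return(image_stack(planes[[1]]))
    }
    fail("multi-page TIFF without axis metadata")
  }
  if (!identical(meta$axes, "TZYX")) fail("unsupported axis order")
  Tn <- as.integer(meta$T); Zn <- as.integer(meta$Z)
  if (Tn * Zn != length(planes)) fail("page count disagrees with metadata")
  H <- nrow(planes[[1]]); W <- ncol(planes[[1]])
  data <- array(0, dim = c(Tn, Zn, H, W))
  for (p in seq_along(planes)) {
    ti <- ((p - 1L) %/% Zn) + 1L
    zi <- ((p - 1L) %% Zn) + 1L
    data[ti, zi, , ] <- planes[[p]]
  }
  image_stack(data,
              timestamps_s = if (!is.null(meta$timestamps_s))
                as.numeric(meta$timestamps_s) else seq_len(Tn) - 1,
              modality = if (!is.null(meta$modality)) meta$modality
                         else "FLUOR",
              position = if (!is.null(meta$position)) meta$position
                         else NA_integer_)
}
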