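# Minimal multi-page TIFF I/O (uncompressed 16-bit grayscale, little-endian).
# No TIFF package is available in the target environment, so the baseline
# subset needed for synthetic image stacks is implemented here and verified
# by round-trip tests.

#' Write / read a multi-page 16-bit grayscale TIFF
#'
#' `write_tiff_stack` stores a `rows x cols x frames` array (or matrix) as an
#' uncompressed little-endian baseline TIFF, one page per frame, rounding and
#' clamping values to the 16-bit unsigned range. `read_tiff_stack` reads
#' files written this way (single-sample grayscale, uncompressed).
#'
#' @param arr Numeric array `rows x cols x frames` or a single matrix.
#' @param path Output file.
#' @return `write_tiff_stack`: `path`, invisibly. `read_tiff_stack`: a
#'   `rows x cols x frames` numeric array.
#' @export
write_tiff_stack <- function(arr, path) {
  if (is.matrix(arr)) arr <- array(arr, c(dim(arr), 1))
  stopifnot(length(dim(arr)) == 3)
  nr <- dim(arr)[1]; nc <- dim(arr)[2]; nt <- dim(arr)[3]
  vals <- pmin(pmax(round(arr), 0), 65535)
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeChar("II", con, eos = NULL)
  w2(42)
  page_bytes <- nr * nc * 2
  ifd_bytes <- 2 + 9 * 12 + 4
  # layout per page: [pixel data][IFD]; header is 8 bytes
  data_off <- function(p) 8 + (p - 1) * (page_bytes + ifd_bytes)
  ifd_off <- function(p) data_off(p) + page_bytes
  w4(ifd_off(1))
  entry <- function(tag, type, count, value) {
    w2(tag); w2(type); w4(count)
    if (type == 3) { w2(value); w2(0) } else w4(value)
  }
  for (p in seq_len(nt)) {
    # TIFF strips are row-major
    w2(as.vector(t(vals[, , p])))
    w2(9)  # entry count
    entry(256, 3, 1, nc)            # ImageWidth
    entry(257, 3, 1, nr)            # ImageLength
    entry(258, 3, 1, 16)            # BitsPerSample
    entry(259, 3, 1, 1)             # Compression: none
    entry(262, 3, 1, 1)             # Photometric: BlackIsZero
    entry(273, 4, 1, data_off(p))   # StripOffsets
    entry(277, 3, 1, 1)             # SamplesPerPixel
    entry(278, 3, 1, nr)            # RowsPerStrip
    entry(279, 4, 1, page_bytes)    # StripByteCounts
    w4(if (p < nt) ifd_off(p + 1) else 0)
  }
  invisible(path)
}

#' @rdname write_tiff_stack
#' @export
read_tiff_stack <- function(path) {
  raw_all <- readBin(path, "raw", file.info(path)$size)
  u2 <- function(off) as.integer(raw_all[off + 1]) + 256L * as.integer(raw_all[off + 2])
  u4 <- function(off) u2(off) + 65536 * u2(off + 2)
  if (rawToChar(raw_all[1:2]) != "II" || u2(2) != 42) {
    stop_invalid("not a little-endian TIFF file")
  }
  pages <- list()
  off <- u4(4)
  while (off != 0) {
    n_ent <- u2(off)
    tags <- list()
    for (i in seq_len(n_ent)) {
      e <- off + 2 + (i - 1) * 12
      tag <- u2(e); type <- u2(e + 2)
      val <- if (type == 3) u2(e + 8) else u4(e + 8)
      tags[[as.character(tag)]] <- val
    }
    if ((tags[["259"]] %||% 1) != 1) stop_invalid("compressed TIFF not supported")
    if ((tags[["258"]] %||% 16) != 16) stop_invalid("only 16-bit TIFF supported")
    nc <- tags[["256"]]; nr <- tags[["257"]]
    doff <- tags[["273"]]
    npx <- nr * nc
    bytes <- raw_all[(doff + 1):(doff + 2 * npx)]
    v <- readBin(bytes, "integer", n = npx, size = 2, endian = "little",
                 signed = FALSE)
    pages[[length(pages) + 1]] <- t(matrix(v, nrow = nc, ncol = nr))
    off <- u4(off + 2 + n_ent * 12)
  }
  array(unlist(pages), c(dim(pages[[1]]), length(pages)))
}

#' Write an image stack to a pair of TIFF files plus metadata
#'
#' One multi-page TIFF per channel (`<prefix>_donor.tif`,
#' `<prefix>_acceptor.tif`) and a JSON sidecar with `frame_dt`, spot
#' positions and channel transform.
#'
#' @param stack An `image_stack`.
#' @param prefix Output path prefix.
#' @param transform Donor-to-acceptor translation `(drow, dcol)` recorded in
#'   the metadata (the synthetic channels are co-registered, so `c(0, 0)`).
#' @return Named character vector of the files written, invisibly.
#' @export
write_image_stack <- function(stack, prefix, transform = c(0, 0)) {
  fd <- paste0(prefix, "_donor.tif")
  fa <- paste0(prefix, "_acceptor.tif")
  fm <- paste0(prefix, "_meta.json")
  write_tiff_stack(stack$donor, fd)
  write_tiff_stack(stack$acceptor, fa)
  jsonlite::write_json(
    list(frame_dt = stack$frame_dt, transform = transform,
         psf_sigma = stack$psf_sigma, positions = stack$positions,
         background = stack$background),
    fm, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(c(donor = fd, acceptor = fa, meta = fm))
}
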