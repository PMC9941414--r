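# Single-image float32 TIFF writer (uncompressed, little-endian, one
# strip) with an ImageDescription tag carrying the JSON-serialized
# metadata. Written by hand because the reconstruction pipeline stores
# unbounded float sample values, which the available TIFF writer clamps
# to [0,1]; tiff::readTIFF reads these files back verbatim and serves as
# the independent format check in the tests.

TIFF_SHORT <- 3L; TIFF_LONG <- 4L; TIFF_ASCII <- 2L

tiff_entry <- function(tag, type, count, value_bytes) {
  stopifnot(length(value_bytes) <= 4L)
  c(writeBin(as.integer(tag), raw(), size = 2L, endian = "little"),
    writeBin(as.integer(type), raw(), size = 2L, endian = "little"),
    writeBin(as.integer(count), raw(), size = 4L, endian = "little"),
    value_bytes, rep(as.raw(0), 4L - length(value_bytes)))
}

short_val <- function(v) writeBin(as.integer(v), raw(), size = 2L,
                                  endian = "little")
long_val <- function(v) writeBin(as.integer(v), raw(), size = 4L,
                                 endian = "little")

write_float_tiff <- function(path, image, description = "") {
  stopifnot(is.matrix(image))
  H <- nrow(image); W <- ncol(image)
  desc <- charToRaw(enc2utf8(description))
  if (length(desc) %% 2L == 0L) desc <- c(desc, charToRaw(" "))  # word alignment
  desc <- c(desc, as.raw(0))                       # NUL-terminated ASCII

  n_tags <- 11L
  ifd_offset <- 8L
  ifd_size <- 2L + n_tags * 12L + 4L
  desc_offset <- ifd_offset + ifd_size
  data_offset <- desc_offset + length(desc)
  nbytes <- H * W * 4L

  entries <- c(
    tiff_entry(256L, TIFF_LONG, 1L, long_val(W)),          # ImageWidth
    tiff_entry(257L, TIFF_LONG, 1L, long_val(H)),          # ImageLength
    tiff_entry(258L, TIFF_SHORT, 1L, short_val(32L)),      # BitsPerSample
    tiff_entry(259L, TIFF_SHORT, 1L, short_val(1L)),       # Compression: none
    tiff_entry(262L, TIFF_SHORT, 1L, short_val(1L)),       # BlackIsZero
    tiff_entry(270L, TIFF_ASCII, length(desc), long_val(desc_offset)),
    tiff_entry(273L, TIFF_LONG, 1L, long_val(data_offset)),# StripOffsets
    tiff_entry(277L, TIFF_SHORT, 1L, short_val(1L)),       # SamplesPerPixel
    tiff_entry(278L, TIFF_LONG, 1L, long_val(H)),          # RowsPerStrip
    tiff_entry(279L, TIFF_LONG, 1L, long_val(nbytes)),     # StripByteCounts
    tiff_entry(339L, TIFF_SHORT, 1L, short_val(3L)))       # SampleFormat: IEEE float

  tmp <- paste0(path, ".tmp-", Sys.getpid())
  con <- file(tmp, open = "wb")
  ok <- FALSE
  on.exit({
    close(con)
    if (!ok) unlink(tmp)
  })
  writeBin(charToRaw("II"), con)
  writeBin(as.integer(42L), con, size = 2L, endian = "little")
  writeBin(as.integer(ifd_offset), con, size = 4L, endian = "little")
  writeBin(as.integer(n_tags), con, size = 2L, endian = "little")
  writeBin(entries, con)
  writeBin(as.integer(0L), con, size = 4L, endian = "little")  # no next IFD
  writeBin(desc, con)
  writeBin(as.double(frame_to_c_order(image)), con, size = 4L,
           endian = "little")
  close(con)
  on.exit(NULL)
  if (!file.rename(tmp, path)) {
    unlink(tmp)
    stop("could not move TIFF into place: ", path, call. = FALSE)
  }
  ok <- TRUE
  invisible(path)
}

# Read a reconstruction TIFF back: image (float matrix) + parsed
# ImageDescription JSON (NULL when absent/unparseable).
read_float_tiff <- function(path) {
  img <- tiff::readTIFF(path, info = TRUE)
  desc <- attr(img, "description")
  meta <- NULL
  if (!is.null(desc) && nzchar(desc))
    meta <- tryCatch(jsonlite::fromJSON(desc, simplifyVector = TRUE),
                     error = function(e) NULL)
  attributes(img) <- list(dim = dim(img))
  list(image = img, meta = meta)
}
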