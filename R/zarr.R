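# Minimal Zarr v2 directory store, sufficient for the raw-stack and
# reconstructed-image interchange used throughout the pipeline:
# uncompressed chunks, C (row-major) order, little-endian "<u2" (camera
# counts) or "<f4" (reconstructions), JSON attributes in .zattrs.
# Raw stacks are chunked one-frame-per-chunk so that a shared-filesystem
# reader can fetch frames independently while the writer is still active
# elsewhere in the store.

zarr_dtypes <- list(
  "<u2" = list(size = 2L, what = "integer"),
  "<f4" = list(size = 4L, what = "double"))

# R matrices are column-major; Zarr C-order wants row-major bytes.
frame_to_c_order <- function(m) as.vector(t(m))
c_order_to_frame <- function(v, H, W) t(matrix(v, nrow = W, ncol = H))

write_chunk <- function(path, values, dtype) {
  dt <- zarr_dtypes[[dtype]]
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (dtype == "<u2") {
    v <- as.integer(round(values))
    if (any(v < 0L | v > 65535L))
      stop("uint16 overflow while writing chunk", call. = FALSE)
    v <- ifelse(v > 32767L, v - 65536L, v)  # two's complement for writeBin
    writeBin(v, con, size = 2L, endian = "little")
  } else {
    writeBin(as.double(values), con, size = 4L, endian = "little")
  }
  invisible(path)
}

read_chunk <- function(path, n, dtype) {
  dt <- zarr_dtypes[[dtype]]
  con <- file(path, open = "rb")
  on.exit(close(con))
  if (dtype == "<u2") {
    readBin(con, "integer", n = n, size = 2L, signed = FALSE,
            endian = "little")
  } else {
    readBin(con, "double", n = n, size = 4L, endian = "little")
  }
}

zarr_array_meta <- function(shape, chunks, dtype) {
  list(zarr_format = 2L, shape = as.integer(shape),
       chunks = as.integer(chunks), dtype = dtype,
       compressor = NULL, fill_value = 0L, order = "C", filters = NULL)
}

write_json_file <- function(x, path) {
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, null = "null",
                              digits = NA), path)
}

# Write a stack (H x W x n array, or H x W matrix treated as one 2D array)
# as a Zarr v2 array at `path` (a directory). attrs land in .zattrs.
zarr_write <- function(path, data, dtype = "<u2", attrs = NULL,
                       frame_chunks = TRUE) {
  tmp <- paste0(path, ".tmp-", Sys.getpid())
  if (dir.exists(tmp)) unlink(tmp, recursive = TRUE)
  dir.create(tmp, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(tmp, recursive = TRUE))
  if (is.matrix(data)) {
    H <- nrow(data); W <- ncol(data)
    write_json_file(zarr_array_meta(c(H, W), c(H, W), dtype),
                    file.path(tmp, ".zarray"))
    write_chunk(file.path(tmp, "0.0"), frame_to_c_order(data), dtype)
  } else {
    stopifnot(length(dim(data)) == 3L)
    H <- dim(data)[1]; W <- dim(data)[2]; n <- dim(data)[3]
    chunks <- if (frame_chunks) c(1L, H, W) else c(n, H, W)
    write_json_file(zarr_array_meta(c(n, H, W), chunks,  dtype),
                    file.path(tmp, ".zarray"))
    if (frame_chunks) {
      for (k in seq_len(n))
        write_chunk(file.path(tmp, sprintf("%d.0.0", k - 1L)),
                    frame_to_c_order(data[, , k]), dtype)
    } else {
      buf <- unlist(lapply(seq_len(n), function(k)
        frame_to_c_order(data[, , k])), use.names = FALSE)
      write_chunk(file.path(tmp, "0.0.0"), buf, dtype)
    }
  }
  if (!is.null(attrs)) write_json_file(attrs, file.path(tmp, ".zattrs"))
  if (dir.exists(path)) unlink(path, recursive = TRUE)
  if (!file.rename(tmp, path))
    stop("could not move Zarr store into place: ", path, call. = FALSE)
  ok <- TRUE
  invisible(path)
}

# Read a Zarr v2 array directory written by zarr_write (or a compatible
# uncompressed C-order store). Returns list(data, attrs).
zarr_read <- function(path) {
  meta_path <- file.path(path, ".zarray")
  if (!file.exists(meta_path))
    stop("not a Zarr array (missing .zarray): ", path, call. = FALSE)
  meta <- jsonlite::fromJSON(meta_path)
  if (!is.null(meta$compressor))
    stop("unsupported Zarr compressor (only uncompressed stores are read)",
         call. = FALSE)
  if (!identical(meta$order, "C"))
    stop("unsupported Zarr order: ", meta$order, call. = FALSE)
  if (!meta$dtype %in% names(zarr_dtypes))
    stop("unsupported Zarr dtype: ", meta$dtype, call. = FALSE)
  shape <- as.integer(meta$shape)
  chunks <- as.integer(meta$chunks)
  attrs_path <- file.path(path, ".zattrs")
  attrs <- if (file.exists(attrs_path)) jsonlite::fromJSON(attrs_path,
                                                           simplifyVector = TRUE)
           else NULL
  if (length(shape) == 2L) {
    stopifnot(identical(chunks, shape))
    v <- read_chunk(file.path(path, "0.0"), prod(shape), meta$dtype)
    data <- c_order_to_frame(v, shape[1], shape[2])
  } else if (length(shape) == 3L) {
    n <- shape[1]; H <- shape[2]; W <- shape[3]
    data <- array(0, dim = c(H, W, n))
    if (chunks[1] == 1L) {
      for (k in seq_len(n)) {
        v <- read_chunk(file.path(path, sprintf("%d.0.0", k - 1L)),
                        H * W, meta$dtype)
        data[, , k] <- c_order_to_frame(v, H, W)
      }
    } else if (chunks[1] == n) {
      v <- read_chunk(file.path(path, "0.0.0"), n * H * W, meta$dtype)
      for (k in seq_len(n))
        data[, , k] <- c_order_to_frame(v[((k - 1) * H * W + 1):(k * H * W)],
                                        H, W)
    } else stop("unsupported chunking along frame axis", call. = FALSE)
  } else stop("unsupported Zarr rank: ", length(shape), call. = FALSE)
  list(data = data, attrs = attrs, meta = meta)
}

# OME-Zarr (NGFF 0.4) single-scale writer: a Zarr group whose .zattrs
# carries multiscales metadata and whose dataset "0" is the image.
omezarr_write <- function(path, image, pixel_size_um, extra_attrs = NULL) {
  stopifnot(is.matrix(image))
  tmp <- paste0(path, ".tmp-", Sys.getpid())
  if (dir.exists(tmp)) unlink(tmp, recursive = TRUE)
  dir.create(tmp, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(tmp, recursive = TRUE))
  write_json_file(list(zarr_format = 2L), file.path(tmp, ".zgroup"))
  multiscales <- list(list(
    version = "0.4",
    name = basename(path),
    axes = list(list(name = "y", type = "space", unit = "micrometer"),
                list(name = "x", type = "space", unit = "micrometer")),
    datasets = list(list(
      path = "0",
      coordinateTransformations = list(list(
        type = "scale", scale = c(pixel_size_um, pixel_size_um)))))))
  attrs <- c(list(multiscales = multiscales), extra_attrs)
  write_json_file(attrs, file.path(tmp, ".zattrs"))
  H <- nrow(image); W <- ncol(image)
  dir.create(file.path(tmp, "0"))
  write_json_file(zarr_array_meta(c(H, W), c(H, W), "<f4"),
                  file.path(tmp, "0", ".zarray"))
  write_chunk(file.path(tmp, "0", "0.0"), frame_to_c_order(image), "<f4")
  if (dir.exists(path)) unlink(path, recursive = TRUE)
  if (!file.rename(tmp, path))
    stop("could not move OME-Zarr store into place: ", path, call. = FALSE)
  ok <- TRUE
  invisible(path)
}

omezarr_read <- function(path) {
  attrs_path <- file.path(path, ".zattrs")
  attrs <- if (file.exists(attrs_path)) jsonlite::fromJSON(attrs_path,
                                                           simplifyVector = TRUE)
           else NULL
  arr <- zarr_read(file.path(path, "0"))
  list(image = arr$data, attrs = attrs)
}
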