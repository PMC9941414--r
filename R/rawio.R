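#' Acquisition metadata
#'
#' The experimental details stored alongside every raw stack, serialized
#' as a single JSON text attribute named `ImSwitchData` in both storage
#' formats, so that any downstream reader can reproduce the acquisition
#' conditions from the file alone.
#'
#' @param stage_position_um Numeric length-3 `(x, y, z)` stage position.
#' @param scan A [scan_config()].
#' @param detector_shape_px Integer length-2 `(H, W)` frame shape.
#' @param pixel_size_um Pixel size in micrometers (> 0).
#' @param tile_index Integer length-2 0-based `(i, j)` tile index, or `NULL`.
#' @param lapse_index Integer timelapse index (0-based), or `NULL`.
#' @param laser_settings Named list of laser powers, possibly empty.
#' @param acquired_at Acquisition timestamp (ISO-8601 string or POSIXct).
#' @return An `acq_metadata` object.
#' @export
acq_metadata <- function(stage_position_um, scan, detector_shape_px,
                         pixel_size_um, tile_index = NULL,
                         lapse_index = NULL, laser_settings = list(),
                         acquired_at = Sys.time()) {
  stopifnot(length(stage_position_um) == 3L, inherits(scan, "scan_config"),
            length(detector_shape_px) == 2L)
  stopifnot_scalar_num(pixel_size_um, "pixel_size_um", 0, strict = TRUE)
  if (inherits(acquired_at, "POSIXct")) acquired_at <- iso_ts(acquired_at)
  structure(
    list(stage_position_um = as.numeric(stage_position_um),
         tile_index = if (!is.null(tile_index)) as.integer(tile_index),
         lapse_index = if (!is.null(lapse_index)) as.integer(lapse_index),
         scan = scan,
         detector_shape_px = as.integer(detector_shape_px),
         pixel_size_um = pixel_size_um,
         laser_settings = laser_settings,
         acquired_at = acquired_at,
         writer_version = as.character(utils::packageVersion("scopeflow"))),
    class = "acq_metadata")
}

IMSWITCH_ATTR <- "ImSwitchData"

meta_to_json <- function(meta) {
  stopifnot(inherits(meta, "acq_metadata"))
  x <- unclass(meta)
  x$scan <- unclass(x$scan)
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE,
                                null = "null", digits = NA))
}

meta_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  sc <- x$scan
  scan <- scan_config(steps_per_axis = sc$steps_per_axis,
                      foci_pitch_px = sc$foci_pitch_px,
                      frame_period_ms = sc$frame_period_ms,
                      amplitude = sc$amplitude, background = sc$background,
                      noise = sc$noise,
                      blur_sigma_px = sc$blur_sigma_px %||% 0)
  acq_metadata(stage_position_um = x$stage_position_um, scan = scan,
               detector_shape_px = x$detector_shape_px,
               pixel_size_um = x$pixel_size_um,
               tile_index = x$tile_index, lapse_index = x$lapse_index,
               laser_settings = as.list(x$laser_settings),
               acquired_at = x$acquired_at)
}

#' Save a raw stack to Zarr or HDF5
#'
#' Stores the frames as an `n_frames x H x W` unsigned 16-bit array with
#' the metadata serialized under the `ImSwitchData` attribute. The Zarr
#' store (a directory tree) is chunked one frame per chunk so that a
#' shared-filesystem consumer pays only for the frames it touches; the
#' HDF5 file holds a single dataset `data`. Writes are atomic: content is
#' staged under a temporary name and renamed into place, so a concurrent
#' watcher never ingests a half-written file.
#'
#' @param stack A [raw_stack()].
#' @param meta An [acq_metadata()] whose `detector_shape_px` matches the
#'   stack frames.
#' @param folder Destination folder.
#' @param format `"zarr"` or `"hdf5"`.
#' @param name File stem (default `"stack"`); the extension (`.zarr` /
#'   `.h5`) is appended.
#' @return The path written.
#' @seealso [load_raw()]
#' @export
save_raw <- function(stack, meta, folder, format = c("zarr", "hdf5"),
                     name = "stack") {
  stopifnot(inherits(stack, "raw_stack"), inherits(meta, "acq_metadata"))
  if (!is.character(format) || !all(format %in% c("zarr", "hdf5")))
    stop("unsupported raw format: ", paste(format, collapse = ", "),
         call. = FALSE)
  format <- match.arg(format)
  d <- dim(stack$frames)
  if (d[3] < 1L) stop("refusing to write a 0-frame stack", call. = FALSE)
  if (!identical(as.integer(d[1:2]), meta$detector_shape_px))
    stop("metadata detector_shape_px does not match stack frames",
         call. = FALSE)
  if (!dir.exists(folder)) dir.create(folder, recursive = TRUE)
  json <- meta_to_json(meta)
  if (format == "zarr") {
    path <- file.path(folder, paste0(name, ".zarr"))
    attrs <- list()
    attrs[[IMSWITCH_ATTR]] <- json
    zarr_write(path, stack$frames, dtype = "<u2", attrs = attrs)
  } else {
    path <- file.path(folder, paste0(name, ".h5"))
    tmp <- paste0(path, ".tmp-", Sys.getpid())
    flat <- as.integer(unlist(lapply(seq_len(d[3]), function(k)
      frame_to_c_order(stack$frames[, , k])), use.names = FALSE))
    .Call(C_h5_write_stack, tmp, flat, as.integer(c(d[3], d[1], d[2])),
          IMSWITCH_ATTR, json)
    if (!file.rename(tmp, path)) {
      unlink(tmp)
      stop("could not move HDF5 file into place: ", path, call. = FALSE)
    }
  }
  path
}

#' Load a raw stack written by [save_raw()]
#'
#' Format-agnostic ingest: dispatches on the `.zarr` / `.h5` suffix and
#' returns the identical frames and metadata regardless of which format
#' they were stored in. A file without the `ImSwitchData` attribute is
#' rejected as foreign.
#'
#' @param path Path to a `.zarr` store or `.h5` file.
#' @return A list with elements `stack` ([raw_stack()]) and `meta`
#'   ([acq_metadata()]).
#' @export
load_raw <- function(path) {
  low <- tolower(path)
  if (endsWith(low, ".zarr")) {
    z <- zarr_read(path)
    json <- z$attrs[[IMSWITCH_ATTR]]
    if (is.null(json))
      stop("missing ", IMSWITCH_ATTR, " attribute: ", path, call. = FALSE)
    meta <- meta_from_json(json)
    frames <- z$data
    storage.mode(frames) <- "integer"
  } else if (endsWith(low, ".h5") || endsWith(low, ".hdf5")) {
    h <- .Call(C_h5_read_stack, path, IMSWITCH_ATTR)
    if (is.null(h$attr))
      stop("missing ", IMSWITCH_ATTR, " attribute: ", path, call. = FALSE)
    meta <- meta_from_json(h$attr)
    n <- h$dims[1]; H <- h$dims[2]; W <- h$dims[3]
    frames <- array(0L, dim = c(H, W, n))
    per <- H * W
    for (k in seq_len(n))
      frames[, , k] <- c_order_to_frame(h$data[((k - 1) * per + 1):(k * per)],
                                        H, W)
  } else {
    stop("unrecognized raw file extension: ", path, call. = FALSE)
  }
  list(stack = raw_stack(frames, meta$scan), meta = meta)
}
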