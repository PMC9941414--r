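#' Reconstruction parameters
#'
#' Settings for the n-frames-to-one-image stage. The default algorithm,
#' focus reassignment, places at every focus position the (optionally
#' background-subtracted) signal summed over a `(2w+1)^2` pixel window
#' around that focus in the frame where the focus visited it. The stage
#' is pluggable via `algorithm_id` (see [register_recon_algorithm()]) so
#' a different grid-scan reconstruction can be swapped in without
#' touching the unit's watch/queue/output contract.
#'
#' @param window_halfwidth_px Integer `w >= 0`; must satisfy
#'   `2w + 1 <= foci_pitch` of the stack being reconstructed, otherwise
#'   the window would overlap a neighboring focus.
#' @param background_mode `"none"` or `"global_min"` (subtract the
#'   stack-wide minimum from every frame before reassignment).
#' @param algorithm_id Registered algorithm name; default
#'   `"focus_reassignment"`.
#' @return A `recon_params` object.
#' @export
recon_params <- function(window_halfwidth_px = 0L,
                         background_mode = c("none", "global_min"),
                         algorithm_id = "focus_reassignment") {
  background_mode <- match.arg(background_mode)
  w <- as.integer(window_halfwidth_px)
  if (is.na(w) || w < 0L)
    stop("window_halfwidth_px must be an integer >= 0", call. = FALSE)
  structure(list(window_halfwidth_px = w, background_mode = background_mode,
                 algorithm_id = algorithm_id),
            class = "recon_params")
}

# Algorithm registry: algorithm_id -> function(stack, params) -> matrix.
the_recon_registry <- new.env(parent = emptyenv())

.onLoad <- function(libname, pkgname) {
  register_recon_algorithm("focus_reassignment", recon_focus_reassignment)
}

#' Register a reconstruction algorithm
#'
#' @param id Algorithm name used in [recon_params()].
#' @param fn Function `(stack, params) -> H x W numeric matrix`.
#' @export
register_recon_algorithm <- function(id, fn) {
  stopifnot(is.character(id), length(id) == 1L, is.function(fn))
  assign(id, fn, envir = the_recon_registry)
  invisible(id)
}

recon_focus_reassignment <- function(stack, params) {
  s <- stack$scan$steps_per_axis
  p <- stack$scan$foci_pitch_px
  w <- params$window_halfwidth_px
  if (2L * w + 1L > p)
    stop("window_halfwidth_px ", w, " overlaps neighboring foci (pitch ",
         p, ")", call. = FALSE)
  d <- dim(stack$frames)
  H <- d[1]; W <- d[2]
  b <- if (params$background_mode == "global_min") min(stack$frames) else 0
  R <- matrix(0, H, W)
  for (k0 in 0:(stack$scan$n_frames - 1L)) {
    kx <- k0 %% s; ky <- k0 %/% s
    rows <- foci_rows(H, p, ky); cols <- foci_cols(W, p, kx)
    if (!length(rows) || !length(cols)) next
    Fk <- stack$frames[, , k0 + 1L] - b
    if (w == 0L) {
      R[rows, cols] <- Fk[rows, cols]
    } else {
      # windowed sum via summed-area table; windows are clipped at the
      # frame border
      ii <- rbind(0, cbind(0, apply(apply(Fk, 2, cumsum), 1, cumsum)))
      # note: ii is now (W+1) x (H+1) because apply transposes; index as
      # ii[c + 1, r + 1] for the inclusive prefix sum over rows 1..r,
      # cols 1..c
      win_sum <- function(r, c) {
        r1 <- max(1L, r - w); r2 <- min(H, r + w)
        c1 <- max(1L, c - w); c2 <- min(W, c + w)
        ii[c2 + 1, r2 + 1] - ii[c1, r2 + 1] - ii[c2 + 1, r1] + ii[c1, r1]
      }
      for (r in rows) for (c in cols) R[r, c] <- win_sum(r, c)
    }
  }
  R
}

#' Reconstruct one grid-scan stack into an image
#'
#' Dispatches to the algorithm named in `params$algorithm_id`. The
#' reference focus-reassignment algorithm is the exact inverse of the
#' simulator's forward model on noiseless stacks when the foci pitch
#' equals the step count, `w = 0` and no background is subtracted.
#' Pixels that are a focus in no frame (sparser pitch than steps) stay 0.
#'
#' @param stack A [raw_stack()].
#' @param params A [recon_params()].
#' @return `H x W` numeric matrix.
#' @export
reconstruct_stack <- function(stack, params = recon_params()) {
  stopifnot(inherits(stack, "raw_stack"), inherits(params, "recon_params"))
  fn <- get0(params$algorithm_id, envir = the_recon_registry,
             inherits = FALSE)
  if (is.null(fn))
    stop("unknown reconstruction algorithm: ", params$algorithm_id,
         call. = FALSE)
  fn(stack, params)
}

#' Reconstruct a raw file and write TIFF + OME-Zarr outputs
#'
#' Loads a raw stack (either storage format), triggers reconstruction
#' through the unit's internal `"reconstruct"` event, and writes
#' `<stem>_rec.tiff` (float32, metadata in the ImageDescription JSON) and
#' `<stem>_rec.zarr` (single-scale OME-Zarr, NGFF 0.4) under `rec_root`.
#' Both outputs carry the acquisition metadata and the reconstruction
#' parameters. Outputs are staged under temporary names and renamed only
#' on success, so a failed reconstruction leaves no partial files behind;
#' an `"execution_finished"` event is emitted on completion.
#'
#' @param path Raw file written by [save_raw()].
#' @param params A [recon_params()].
#' @param rec_root Output folder (created if missing).
#' @param bus Optional [event_bus()] for the unit's events.
#' @return Named character vector `c(tiff = ..., zarr = ...)`.
#' @export
process_raw_file <- function(path, params = recon_params(),
                             rec_root = file.path(dirname(path), "rec"),
                             bus = NULL) {
  raw <- load_raw(path)
  holder <- new.env(parent = emptyenv())
  if (is.null(bus)) bus <- event_bus()
  # reconstruction runs via the unit's reconstruct event, not a direct call
  subscribe(bus, "reconstruct", function(stack, p)
    holder$image <- reconstruct_stack(stack, p))
  emit(bus, "reconstruct", raw$stack, params)
  img <- holder$image

  if (!dir.exists(rec_root)) dir.create(rec_root, recursive = TRUE)
  stem <- sub("\\.(zarr|h5|hdf5)$", "", basename(path), ignore.case = TRUE)
  tiff_path <- file.path(rec_root, paste0(stem, "_rec.tiff"))
  zarr_path <- file.path(rec_root, paste0(stem, "_rec.zarr"))
  desc <- as.character(jsonlite::toJSON(
    list(ImSwitchData = meta_to_json(raw$meta),
         recon = unclass(params), source_raw = basename(path)),
    auto_unbox = TRUE, null = "null", digits = NA))
  write_float_tiff(tiff_path, img, description = desc)
  extra <- list(recon = unclass(params), source_raw = basename(path))
  extra[[IMSWITCH_ATTR]] <- meta_to_json(raw$meta)
  omezarr_write(zarr_path, img, pixel_size_um = raw$meta$pixel_size_um,
                extra_attrs = extra)
  emit(bus, "execution_finished", path, c(tiff = tiff_path,
                                          zarr = zarr_path))
  c(tiff = tiff_path, zarr = zarr_path)
}

#' Run the reconstruction unit
#'
#' Composes the file watcher with [process_raw_file()]: every raw file
#' appearing in the watched data folder is reconstructed FIFO and its
#' TIFF + OME-Zarr outputs land in the `rec` subfolder of the data
#' folder, which is excluded from the watch so outputs are never
#' re-ingested. On stop the unit writes its experiment log into the data
#' folder.
#'
#' @param watch A [watch_config()] on the acquisition data folder whose
#'   extensions include the raw formats (e.g. `c(".zarr", ".h5")`).
#' @param params A [recon_params()].
#' @param rec_root Output folder; default `<data folder>/rec`.
#' @param stop_when,max_polls,sleep Passed to [run_watcher()].
#' @param bus Optional [event_bus()].
#' @param write_log_on_stop Write the session log into the data folder.
#' @return The session's `experiment_log`, invisibly.
#' @export
run_reconstruction_unit <- function(watch, params = recon_params(),
                                    rec_root = file.path(watch$folder, "rec"),
                                    stop_when = NULL, max_polls = Inf,
                                    sleep = TRUE, bus = NULL,
                                    write_log_on_stop = TRUE) {
  session <- reconstruction_session(watch, params, rec_root, bus)
  n <- 0
  repeat {
    poll_session(session)
    n <- n + 1
    if (!is.null(stop_when) && isTRUE(stop_when())) break
    if (n >= max_polls) break
    if (sleep) Sys.sleep(watch$poll_interval_s)
  }
  if (write_log_on_stop) write_log(session$log, watch$folder)
  invisible(session$log)
}

# Steppable reconstruction session (used by run_reconstruction_unit and
# the single-process demo scheduler).
reconstruction_session <- function(watch, params = recon_params(),
                                   rec_root = file.path(watch$folder, "rec"),
                                   bus = NULL) {
  rec_norm <- normalizePath(rec_root, mustWork = FALSE)
  handler <- function(path) {
    if (startsWith(normalizePath(path, mustWork = FALSE), rec_norm))
      return(invisible(NULL))   # never re-ingest own outputs
    process_raw_file(path, params, rec_root, bus = bus)
  }
  watch_session(watch, handler, role = "reconstruction")
}
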