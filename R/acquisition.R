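#' Create a simulated acquisition backend
#'
#' The device layer behind the control API: a virtual stage, the virtual
#' grid-scan camera, the recording folder and format, and a virtual
#' experiment clock. Every scan acquires one raw stack from the attached
#' [make_sample()] specimen at the current stage position and writes it
#' with [save_raw()]; the clock advances by the stack duration plus any
#' configured settle time, modelling the real instrument's timing
#' without sleeping (wall-clock pacing can be enabled with
#' `realtime = TRUE`).
#'
#' @param sample A [make_sample()] specimen.
#' @param folder Recording folder for raw files.
#' @param format `"zarr"` or `"hdf5"`.
#' @param scan Default [scan_config()].
#' @param fov_px Detector shape `(H, W)` in pixels.
#' @param bus Optional [event_bus()]; scans emit `"scan_saved"`.
#' @param noise_seed Base seed for the per-scan noise draw (each scan k
#'   uses `noise_seed + k`), making whole experiments reproducible.
#' @param realtime If `TRUE`, `run_scan` also sleeps for the simulated
#'   acquisition duration.
#' @return An `acq_backend` environment.
#' @export
acq_backend <- function(sample, folder, format = "zarr",
                        scan = scan_config(), fov_px = c(64L, 64L),
                        bus = NULL, noise_seed = NULL, realtime = FALSE) {
  stopifnot(inherits(sample, "virtual_sample"))
  b <- new.env(parent = emptyenv())
  b$sample <- sample
  b$folder <- folder
  b$format <- format
  b$scan <- scan
  b$fov_px <- fov_px
  b$stage <- c(x = 0, y = 0, z = 0)
  b$params <- list(settle_s = 0)
  b$bus <- bus %||% event_bus()
  b$noise_seed <- noise_seed
  b$scan_count <- 0L
  b$scanning <- FALSE
  b$vclock_s <- 0          # virtual experiment time
  b$realtime <- isTRUE(realtime)
  b$messages <- character(0)
  class(b) <- c("acq_backend", class(b))
  b
}

backend_run_scan <- function(backend, tag = "scan") {
  if (backend$scanning)
    stop("scan backend busy: overlapping run_scan calls", call. = FALSE)
  backend$scanning <- TRUE
  on.exit(backend$scanning <- FALSE)
  if (is.null(backend$folder))
    stop("recording folder not set", call. = FALSE)
  seed <- if (!is.null(backend$noise_seed))
    backend$noise_seed + backend$scan_count
  stack <- acquire_stack(backend$sample,
                         stage_xy_um = backend$stage[c("x", "y")],
                         scan = backend$scan, fov_px = backend$fov_px,
                         seed = seed)
  ti <- backend$params$tile_index
  li <- backend$params$lapse_index
  meta <- acq_metadata(
    stage_position_um = unname(backend$stage),
    scan = backend$scan,
    detector_shape_px = dim(stack$frames)[1:2],
    pixel_size_um = backend$sample$pixel_size_um,
    tile_index = ti, lapse_index = li,
    laser_settings = backend$params$lasers %||% list())
  name <- sprintf("%s_t%d_x%d_y%d_%s", tag,
                  (li %||% 0L), (ti %||% c(0L, 0L))[1],
                  (ti %||% c(0L, 0L))[2], fs_ts())
  # suffix-index on collision so repeated tags never overwrite
  k <- 0L
  ext <- if (backend$format == "zarr") ".zarr" else ".h5"
  final <- name
  while (file.exists(file.path(backend$folder, paste0(final, ext)))) {
    k <- k + 1L
    final <- sprintf("%s_%03d", name, k)
  }
  path <- save_raw(stack, meta, backend$folder, backend$format, name = final)
  backend$scan_count <- backend$scan_count + 1L
  dur <- stack_duration_s(backend$scan)
  backend$vclock_s <- backend$vclock_s + dur
  if (backend$realtime) Sys.sleep(dur)
  emit(backend$bus, "scan_saved", path)
  path
}

#' Build the control API exported to experiment scripts
#'
#' Scripts see exactly one object, `api`, whose `imcontrol` namespace
#' exposes the microscope operations: `move_stage`, `get_stage_position`,
#' `run_scan`, `wait_for_scan_end`, `set_recording_folder`,
#' `set_save_format`, `set_param`/`get_param`, `load_plan` and
#' `log_message`. Every call is synchronous: `run_scan` returns only
#' after the raw file is fully written, so scripts need no polling of
#' their own.
#'
#' @param backend An [acq_backend()].
#' @return A list with element `imcontrol`.
#' @export
control_api <- function(backend) {
  stopifnot(inherits(backend, "acq_backend"))
  imcontrol <- list(
    move_stage = function(x = NULL, y = NULL, z = NULL) {
      if (!is.null(x)) backend$stage[["x"]] <- x
      if (!is.null(y)) backend$stage[["y"]] <- y
      if (!is.null(z)) backend$stage[["z"]] <- z
      settle <- backend$params$settle_s %||% 0
      backend$vclock_s <- backend$vclock_s + settle
      if (backend$realtime && settle > 0) Sys.sleep(settle)
      invisible(unname(backend$stage))
    },
    get_stage_position = function() backend$stage,
    run_scan = function(tag = "scan") backend_run_scan(backend, tag),
    wait_for_scan_end = function() invisible(TRUE),  # scans are synchronous
    set_recording_folder = function(path) {
      if (!dir.exists(path)) dir.create(path, recursive = TRUE)
      backend$folder <- path
      invisible(path)
    },
    set_save_format = function(format) {
      if (!format %in% c("zarr", "hdf5"))
        stop("unsupported format: ", format, call. = FALSE)
      backend$format <- format
      invisible(format)
    },
    set_param = function(name, value) {
      backend$params[[name]] <- value
      invisible(value)
    },
    get_param = function(name, default = NULL) {
      backend$params[[name]] %||% default
    },
    load_plan = function(path = NULL) {
      path <- path %||% backend$params$plan_path
      if (is.null(path)) stop("no plan_path configured", call. = FALSE)
      plan_visits(read_plan(path))
    },
    log_message = function(msg) {
      backend$messages <- c(backend$messages, msg)
      invisible(msg)
    })
  list(imcontrol = imcontrol)
}

#' Execute one experiment script
#'
#' Interprets the script (an R program) in a restricted environment in
#' which only the `api` object is bound beyond the base language — no
#' package namespaces, filesystem helpers or network primitives are
#' injected, which keeps scripts auditable. On completion (either way) a
#' `"script_finished"` event is emitted on the backend's bus with the
#' script path and status; an exception inside the script yields status
#' `"failed"` with the condition message logged, and never blocks
#' subsequent scripts.
#'
#' @param script_path Path to the script file.
#' @param api A [control_api()] list.
#' @param bus Optional bus for the `"script_finished"` event (defaults to
#'   the backend bus embedded in `api`).
#' @return `"ok"` or `"failed"`.
#' @export
run_script <- function(script_path, api, bus = NULL) {
  bus <- bus %||% environment(api$imcontrol$run_scan)$backend$bus
  sandbox <- new.env(parent = baseenv())
  sandbox$api <- api
  status <- tryCatch({
    exprs <- parse(file = script_path)
    for (e in exprs) eval(e, envir = sandbox)
    "ok"
  }, error = function(err) {
    warning("script failed [", basename(script_path), "]: ",
            conditionMessage(err), call. = FALSE)
    "failed"
  })
  if (!is.null(bus)) emit(bus, "script_finished", script_path, status)
  status
}

#' Run the acquisition unit
#'
#' Composes the file watcher with [run_script()]: experiment scripts
#' dropped into the watched scripts folder are executed FIFO, one at a
#' time, against the backend's control API. On stop the unit writes its
#' experiment log into the scripts folder.
#'
#' @param watch A [watch_config()] on the scripts folder (extensions
#'   typically `".R"`).
#' @param backend An [acq_backend()].
#' @param stop_when,max_polls,sleep Passed to the watch loop.
#' @param write_log_on_stop Write the session log on exit.
#' @return The session's `experiment_log`, invisibly.
#' @export
run_acquisition_unit <- function(watch, backend, stop_when = NULL,
                                 max_polls = Inf, sleep = TRUE,
                                 write_log_on_stop = TRUE) {
  session <- acquisition_session(watch, backend)
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

acquisition_session <- function(watch, backend) {
  api <- control_api(backend)
  handler <- function(path) {
    status <- run_script(path, api, bus = backend$bus)
    if (status == "failed")
      stop("script execution failed: ", basename(path), call. = FALSE)
    invisible(status)
  }
  watch_session(watch, handler, role = "acquisition")
}
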