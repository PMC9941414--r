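#' Configure a folder watch
#'
#' A watch is the synchronization primitive between units: each unit
#' periodically lists a folder, detects files that are new *and* fully
#' written, and hands them to a processing function as ordered batches.
#' Nothing else connects the units, so any shared filesystem (local disk,
#' network share) is enough to couple them.
#'
#' A file is judged fully written ("stable") when its size and modification
#' time are unchanged across two consecutive polls. Directory datasets (Zarr
#' stores, i.e. paths ending in `.zarr`) are judged stable when their
#' recursive file count and total byte size are unchanged. This needs no
#' cooperation from the writer, which may be a different program on a
#' different machine.
#'
#' @param folder Directory to monitor. Must exist when a session starts.
#' @param extensions Character vector of file suffixes to deliver
#'   (e.g. `c(".zarr", ".h5")`). Matching is case-insensitive.
#' @param poll_interval_s Seconds between polls; must be > 0. Default 1.
#' @param process_preexisting If `FALSE` (default), files already present
#'   when the session starts are marked as seen without being delivered:
#'   the watch observes the folder from "now" on. Set `TRUE` to reprocess
#'   an existing folder.
#' @return A `watch_config` object.
#' @export
watch_config <- function(folder, extensions, poll_interval_s = 1,
                         process_preexisting = FALSE) {
  stopifnot_scalar_num(poll_interval_s, "poll_interval_s", 0, strict = TRUE)
  if (length(extensions) == 0L || !is.character(extensions))
    stop("extensions must be a non-empty character vector", call. = FALSE)
  extensions <- ifelse(startsWith(extensions, "."), extensions,
                       paste0(".", extensions))
  structure(
    list(folder = normalizePath(folder, mustWork = FALSE),
         extensions = tolower(extensions),
         poll_interval_s = poll_interval_s,
         process_preexisting = isTRUE(process_preexisting)),
    class = "watch_config")
}

# Mutable per-session state: the set of already-delivered paths and the
# size/mtime snapshot of not-yet-stable candidates. Kept in an environment
# so scan_folder can update it in place.
new_watch_state <- function() {
  st <- new.env(parent = emptyenv())
  st$seen <- character(0)
  st$pending <- list()   # path -> c(size, mtime, nfiles)
  st
}

matches_ext <- function(path, extensions) {
  low <- tolower(basename(path))
  vapply(low, function(p) any(endsWith(p, extensions)), logical(1),
         USE.NAMES = FALSE)
}

# Size/mtime signature of one candidate. Zarr directory stores are sized
# recursively; a still-growing store changes its file count or total bytes.
path_signature <- function(path) {
  if (dir.exists(path)) {
    fls <- list.files(path, recursive = TRUE, full.names = TRUE,
                      all.files = TRUE, no.. = TRUE)
    fi <- suppressWarnings(file.info(fls))
    c(size = sum(fi$size, na.rm = TRUE), mtime = 0, n = length(fls))
  } else {
    fi <- suppressWarnings(file.info(path))
    if (is.na(fi$size)) return(NULL)
    c(size = fi$size, mtime = as.numeric(fi$mtime), n = 1)
  }
}

#' Poll a folder once for new stable files
#'
#' One poll of the watch loop: lists the folder, filters by suffix, drops
#' paths already delivered this session, and delivers the candidates whose
#' size and mtime are unchanged since the previous poll. First-time
#' candidates only enter the pending snapshot, so every file waits at least
#' one poll interval before delivery — the price of writer-independent
#' completeness detection.
#'
#' @param state Session state from `new_watch_state()` (updated in place).
#' @param config A [watch_config()].
#' @return A `file_batch`: list with `paths` (absolute, sorted
#'   lexicographically by filename, mtime tie-break) and `detected_at`.
#' @export
scan_folder <- function(state, config) {
  if (!dir.exists(config$folder))
    stop("watch folder does not exist: ", config$folder, call. = FALSE)
  entries <- list.files(config$folder, full.names = TRUE, no.. = TRUE)
  entries <- entries[matches_ext(entries, config$extensions)]
  entries <- setdiff(normalizePath(entries, mustWork = FALSE), state$seen)

  ready <- character(0)
  mtimes <- numeric(0)
  new_pending <- list()
  for (p in entries) {
    sig <- tryCatch(path_signature(p), error = function(e) {
      warning("skipping unreadable entry: ", p, call. = FALSE)
      NULL
    })
    if (is.null(sig)) next
    prev <- state$pending[[p]]
    if (!is.null(prev) && identical(unname(prev), unname(sig))) {
      ready <- c(ready, p)
      mtimes <- c(mtimes, sig[["mtime"]])
    } else {
      new_pending[[p]] <- sig
    }
  }
  state$pending <- new_pending
  if (length(ready)) {
    ord <- order(basename(ready), mtimes)
    ready <- ready[ord]
    state$seen <- c(state$seen, ready)
  }
  structure(list(paths = ready, detected_at = Sys.time()),
            class = "file_batch")
}

#' Run a watch session
#'
#' Polls `config$folder` every `poll_interval_s` seconds and passes each
#' non-empty batch to `handler`. Handler errors are caught, recorded as
#' failed execution records, and never kill the session; the per-item
#' arrival-to-finish latency of every handled path is appended to the
#' session's experiment log.
#'
#' The loop stops when `stop_when()` returns `TRUE` (checked after each
#' poll) or after `max_polls` polls. `run_watcher` is synchronous; units
#' that must run "simultaneously" in one process are interleaved by
#' stepping their sessions round-robin (see [cmd_demo()]).
#'
#' @param config A [watch_config()].
#' @param handler Function taking one delivered path (called once per path,
#'   in batch order).
#' @param stop_when Optional function of no arguments returning `TRUE` to
#'   end the session.
#' @param max_polls Maximum number of polls (default `Inf`).
#' @param sleep If `FALSE`, do not sleep between polls (deterministic
#'   stepping for tests and demos).
#' @param role Unit role recorded in the session log: `"acquisition"`,
#'   `"reconstruction"` or `"orchestrator"`.
#' @return Invisibly, the session's `experiment_log`.
#' @export
run_watcher <- function(config, handler, stop_when = NULL, max_polls = Inf,
                        sleep = TRUE, role = "acquisition") {
  session <- watch_session(config, handler, role = role)
  n <- 0
  repeat {
    poll_session(session)
    n <- n + 1
    if (!is.null(stop_when) && isTRUE(stop_when())) break
    if (n >= max_polls) break
    if (sleep) Sys.sleep(config$poll_interval_s)
  }
  invisible(session$log)
}

#' Create a steppable watch session
#'
#' Lower-level interface behind [run_watcher()]: returns a session handle
#' whose polls are driven explicitly with [poll_session()], which lets
#' several units share one process deterministically.
#'
#' @inheritParams run_watcher
#' @return A `watch_session` environment with fields `config`, `state`,
#'   `log`, and `handled` (count of items processed).
#' @export
watch_session <- function(config, handler, role = "acquisition") {
  stopifnot(inherits(config, "watch_config"))
  if (!dir.exists(config$folder))
    stop("watch folder does not exist: ", config$folder, call. = FALSE)
  s <- new.env(parent = emptyenv())
  s$config <- config
  s$state <- new_watch_state()
  s$handler <- handler
  s$log <- experiment_log(role = role)
  s$handled <- 0L
  if (!config$process_preexisting) {
    pre <- list.files(config$folder, full.names = TRUE, no.. = TRUE)
    pre <- pre[matches_ext(pre, config$extensions)]
    s$state$seen <- normalizePath(pre, mustWork = FALSE)
  }
  class(s) <- c("watch_session", class(s))
  s
}

#' Advance a watch session by one poll
#'
#' @param session A [watch_session()].
#' @return The number of paths handled this poll, invisibly.
#' @export
poll_session <- function(session) {
  batch <- scan_folder(session$state, session$config)
  for (p in batch$paths) {
    arrival <- Sys.time()
    status <- tryCatch({
      session$handler(p)
      "ok"
    }, error = function(e) {
      warning("handler failed for ", p, ": ", conditionMessage(e),
              call. = FALSE)
      "failed"
    })
    session$log <- log_append(session$log, p, arrival, Sys.time(), status)
    session$handled <- session$handled + 1L
  }
  invisible(length(batch$paths))
}
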