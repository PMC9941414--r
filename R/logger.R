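#' Create an experiment log
#'
#' Each unit keeps a per-session log of every item it handled: arrival
#' time, finish time, the derived latency, and whether the handler
#' succeeded. The log is written to the watched folder when the session
#' ends, so the performance of each computer in the pipeline can be
#' evaluated offline from files alone.
#'
#' @param role One of `"acquisition"`, `"reconstruction"`, `"orchestrator"`.
#' @param host_name Computer name; defaults to the system node name.
#' @param started_at Session start time.
#' @return An `experiment_log` object: header fields plus a `records`
#'   data.frame with columns `item_path`, `arrival_time`, `finish_time`,
#'   `latency_s`, `status`.
#' @export
experiment_log <- function(role = c("acquisition", "reconstruction",
                                    "orchestrator"),
                           host_name = Sys.info()[["nodename"]],
                           started_at = Sys.time()) {
  role <- match.arg(role)
  structure(
    list(host_name = host_name, started_at = started_at, unit_role = role,
         records = data.frame(
           item_path = character(0),
           arrival_time = as.POSIXct(character(0), tz = "UTC"),
           finish_time = as.POSIXct(character(0), tz = "UTC"),
           latency_s = numeric(0),
           status = character(0),
           stringsAsFactors = FALSE)),
    class = "experiment_log")
}

log_append <- function(log, item_path, arrival_time, finish_time, status) {
  stopifnot(inherits(log, "experiment_log"), status %in% c("ok", "failed"))
  if (finish_time < arrival_time)
    stop("finish_time earlier than arrival_time", call. = FALSE)
  rec <- data.frame(
    item_path = item_path,
    arrival_time = arrival_time,
    finish_time = finish_time,
    latency_s = as.numeric(difftime(finish_time, arrival_time,
                                    units = "secs")),
    status = status,
    stringsAsFactors = FALSE)
  log$records <- rbind(log$records, rec)
  log$records <- log$records[order(log$records$arrival_time), , drop = FALSE]
  rownames(log$records) <- NULL
  log
}

#' @export
print.experiment_log <- function(x, ...) {
  cat(sprintf("<experiment_log> role=%s host=%s started=%s records=%d\n",
              x$unit_role, x$host_name, iso_ts(x$started_at),
              nrow(x$records)))
  invisible(x)
}

#' Write an experiment log file
#'
#' Serializes the log as UTF-8 text: three header lines (`host:`, `role:`,
#' `started:`) followed by one tab-separated line per record with the item
#' path, arrival and finish timestamps (ISO-8601, millisecond precision),
#' the latency in seconds (`%.3f`), and `ok`/`failed`. The filename is
#' `<role>_<host>_<start timestamp>.log`; an existing file of that name is
#' never overwritten — a numeric suffix is appended instead.
#'
#' @param log An [experiment_log()].
#' @param folder Destination folder (must be writable).
#' @return The path of the file written.
#' @export
write_log <- function(log, folder) {
  stopifnot(inherits(log, "experiment_log"))
  if (!dir.exists(folder))
    stop("log folder does not exist: ", folder, call. = FALSE)
  base <- sprintf("%s_%s_%s", log$unit_role, log$host_name,
                  fs_ts(log$started_at))
  path <- file.path(folder, paste0(base, ".log"))
  k <- 1L
  while (file.exists(path)) {
    path <- file.path(folder, sprintf("%s_%03d.log", base, k))
    k <- k + 1L
  }
  hdr <- c(paste0("host: ", log$host_name),
           paste0("role: ", log$unit_role),
           paste0("started: ", iso_ts(log$started_at)))
  lines <- hdr
  if (nrow(log$records)) {
    r <- log$records
    lines <- c(lines, sprintf("%s\t%s\t%s\t%.3f\t%s",
                              r$item_path, iso_ts(r$arrival_time),
                              iso_ts(r$finish_time), r$latency_s, r$status))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  path
}

#' Parse an experiment log file
#'
#' Inverse of [write_log()]: `parse_log(write_log(L))` reproduces `L`
#' field-for-field with timestamps at millisecond precision. Each record
#' line is validated — a latency field inconsistent with its own
#' timestamps (beyond 2 ms) or a malformed line raises an error naming the
#' line number.
#'
#' @param path Path to a logger file produced by [write_log()].
#' @return An [experiment_log()].
#' @export
parse_log <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 3L)
    stop("malformed log file (missing header): ", path, call. = FALSE)
  get_hdr <- function(i, key) {
    if (!startsWith(lines[i], paste0(key, ": ")))
      stop(sprintf("malformed log header at line %d: expected '%s:'", i, key),
           call. = FALSE)
    sub(paste0("^", key, ": "), "", lines[i])
  }
  host <- get_hdr(1L, "host")
  role <- get_hdr(2L, "role")
  started <- parse_iso_ts(get_hdr(3L, "started"))
  log <- experiment_log(role = role, host_name = host, started_at = started)
  body <- lines[-(1:3)]
  body_idx <- which(nzchar(body))
  for (i in body_idx) {
    fields <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    lineno <- i + 3L
    if (length(fields) != 5L)
      stop(sprintf("malformed record at line %d: expected 5 tab-separated fields, got %d",
                   lineno, length(fields)), call. = FALSE)
    arrival <- tryCatch(parse_iso_ts(fields[2]), error = function(e)
      stop(sprintf("malformed record at line %d: bad arrival timestamp", lineno),
           call. = FALSE))
    finish <- tryCatch(parse_iso_ts(fields[3]), error = function(e)
      stop(sprintf("malformed record at line %d: bad finish timestamp", lineno),
           call. = FALSE))
    lat <- suppressWarnings(as.numeric(fields[4]))
    if (is.na(lat) || lat < 0)
      stop(sprintf("malformed record at line %d: bad latency field", lineno),
           call. = FALSE)
    implied <- as.numeric(difftime(finish, arrival, units = "secs"))
    if (abs(implied - lat) > 2e-3)
      stop(sprintf(
        "invalid record at line %d: latency %.3f inconsistent with timestamps (%.3f)",
        lineno, lat, implied), call. = FALSE)
    if (!fields[5] %in% c("ok", "failed"))
      stop(sprintf("malformed record at line %d: bad status '%s'", lineno,
                   fields[5]), call. = FALSE)
    log$records <- rbind(log$records, data.frame(
      item_path = fields[1], arrival_time = arrival, finish_time = finish,
      latency_s = lat, status = fields[5], stringsAsFactors = FALSE))
  }
  rownames(log$records) <- NULL
  log
}

#' Summarize per-item latencies of a log
#'
#' Summary statistics over the arrival-to-finish latencies of the
#' successfully handled (`ok`) records; failures are counted separately
#' and excluded from the statistics.
#'
#' @param log An [experiment_log()].
#' @return A list with `n` (ok records), `n_failed`, `min_s`, `max_s`,
#'   `mean_s`. With no ok records, `n` is 0 and the statistics are `NA`.
#' @export
latency_summary <- function(log) {
  stopifnot(inherits(log, "experiment_log"))
  lat <- log$records$latency_s[log$records$status == "ok"]
  n_failed <- sum(log$records$status == "failed")
  if (length(lat) == 0L)
    return(list(n = 0L, n_failed = n_failed, min_s = NA_real_,
                max_s = NA_real_, mean_s = NA_real_))
  list(n = length(lat), n_failed = n_failed, min_s = min(lat),
       max_s = max(lat), mean_s = mean(lat))
}
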