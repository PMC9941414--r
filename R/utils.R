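#' @useDynLib scopeflow, .registration = TRUE
#' @keywords internal
"_PACKAGE"

# ISO-8601 timestamps with millisecond precision, always UTC, are the wire
# format for logger files and file names.
iso_ts <- function(t = Sys.time()) {
  format(t, "%Y-%m-%dT%H:%M:%OS3", tz = "UTC")
}

parse_iso_ts <- function(s) {
  t <- as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  if (any(is.na(t))) stop("unparseable ISO-8601 timestamp: ", s[is.na(t)][1], call. = FALSE)
  t
}

# File-system-safe variant (':' is illegal on some filesystems).
fs_ts <- function(t = Sys.time()) {
  format(t, "%Y%m%dT%H%M%OS3", tz = "UTC")
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_num <- function(x, name, min = -Inf, strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > min else x >= min)
  if (!ok) stop(name, " must be a finite scalar ", if (strict) "> " else ">= ",
                min, call. = FALSE)
  invisible(x)
}
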