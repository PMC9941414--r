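# Shared fixtures: everything is generated in code at test time.

tmp_dir <- function() {
  d <- tempfile("sf-")
  dir.create(d)
  d
}

tiny_scan <- function(s = 4L, p = s, ...) {
  scan_config(steps_per_axis = s, foci_pitch_px = p, ...)
}

# A raw stack with independently random uint16 frames (not produced by the
# simulator), for oracle comparisons.
random_stack <- function(s = 8L, H = 16L, W = 16L, seed = 1L, p = s) {
  sc <- tiny_scan(s, p)
  frames <- scopeflow:::with_seed(seed, {
    array(sample.int(65535L, H * W * sc$n_frames, replace = TRUE) - 1L,
          dim = c(H, W, sc$n_frames))
  })
  raw_stack(frames, sc)
}

# Independent reconstruction oracle: naive triple loop over frames and
# focus positions, summing the (2w+1)^2 clipped window directly.
recon_oracle <- function(stack, w = 0L, background = c("none", "global_min")) {
  background <- match.arg(background)
  s <- stack$scan$steps_per_axis
  p <- stack$scan$foci_pitch_px
  d <- dim(stack$frames)
  H <- d[1]; W <- d[2]
  b <- if (background == "global_min") min(stack$frames) else 0
  R <- matrix(0, H, W)
  for (k0 in 0:(stack$scan$n_frames - 1L)) {
    kx <- k0 %% s
    ky <- k0 %/% s
    Fk <- stack$frames[, , k0 + 1L]
    for (r in seq_len(H)) {
      for (c in seq_len(W)) {
        if ((r - 1L) %% p != ky || (c - 1L) %% p != kx) next
        acc <- 0
        for (dr in -w:w) for (dc in -w:w) {
          rr <- r + dr; cc <- c + dc
          if (rr >= 1 && rr <= H && cc >= 1 && cc <= W)
            acc <- acc + (Fk[rr, cc] - b)
        }
        R[r, c] <- acc
      }
    }
  }
  R
}

# Scripted file dropper: writes `n` files one at a time, each followed by
# enough polls for the stability check, collecting delivered paths.
drop_and_poll <- function(session, folder, n, ext = ".h5",
                          polls_per_drop = 3L) {
  for (i in seq_len(n)) {
    writeLines(sprintf("payload %d", i),
               file.path(folder, sprintf("file%02d%s", i, ext)))
    for (k in seq_len(polls_per_drop)) poll_session(session)
  }
  invisible(session)
}

# Synthetic experiment-script writer for acquisition tests.
write_script <- function(folder, name, lines) {
  path <- file.path(folder, name)
  writeLines(lines, path)
  path
}
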