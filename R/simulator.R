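#' Grid-scan configuration
#'
#' Geometry and timing of one parallelized grid-scan acquisition. The
#' illumination is a periodic grid of foci with pitch `foci_pitch_px`
#' pixels that is stepped `steps_per_axis` times along each axis, one
#' camera frame per step, so a stack holds `steps_per_axis^2` frames.
#' With the defaults (18 steps, 8 ms per frame) a stack has 324 frames
#' and takes 2.592 s to acquire.
#'
#' When `foci_pitch_px == steps_per_axis` the scan steps tile the pitch
#' exactly: every detector pixel is a focus pixel in exactly one frame,
#' and reconstruction is exactly invertible. A larger pitch (sparser
#' foci) is allowed and leaves unvisited pixels at background.
#'
#' @param steps_per_axis Scan steps per axis `s` (integer >= 1).
#' @param foci_pitch_px Focus grid pitch `p` in pixels (integer >= `s`).
#' @param frame_period_ms Camera frame period in ms (> 0). Default 8.
#' @param amplitude Forward-model gain applied to the sample intensity.
#' @param background Constant background level (camera counts).
#' @param noise `"none"` or `"poisson"` (per-pixel shot noise).
#' @param blur_sigma_px Optional Gaussian optics blur of the sample crop,
#'   in pixels; 0 (default) disables it.
#' @return A `scan_config` object; `n_frames` is derived as `s^2`.
#' @export
scan_config <- function(steps_per_axis = 18L, foci_pitch_px = steps_per_axis,
                        frame_period_ms = 8, amplitude = 1, background = 0,
                        noise = c("none", "poisson"), blur_sigma_px = 0) {
  noise <- match.arg(noise)
  s <- as.integer(steps_per_axis)
  p <- as.integer(foci_pitch_px)
  if (is.na(s) || s < 1L) stop("steps_per_axis must be >= 1", call. = FALSE)
  if (is.na(p) || p < s) stop("foci_pitch_px must be >= steps_per_axis",
                              call. = FALSE)
  stopifnot_scalar_num(frame_period_ms, "frame_period_ms", 0, strict = TRUE)
  stopifnot_scalar_num(background, "background", 0)
  structure(list(steps_per_axis = s, foci_pitch_px = p,
                 frame_period_ms = frame_period_ms, amplitude = amplitude,
                 background = background, noise = noise,
                 blur_sigma_px = blur_sigma_px, n_frames = s * s),
            class = "scan_config")
}

#' Acquisition time of one stack
#'
#' `steps_per_axis^2 * frame_period_ms / 1000` seconds: 2.592 s for the
#' default 18-step, 8 ms scan.
#'
#' @param scan A [scan_config()].
#' @return Seconds.
#' @export
stack_duration_s <- function(scan) {
  stopifnot(inherits(scan, "scan_config"))
  scan$n_frames * scan$frame_period_ms / 1000
}

#' Raw camera stack
#'
#' @param frames `H x W x n_frames` array of non-negative camera counts.
#' @param scan The [scan_config()] that produced it; `n_frames` must equal
#'   `scan$steps_per_axis^2`.
#' @return A `raw_stack` object.
#' @export
raw_stack <- function(frames, scan) {
  stopifnot(inherits(scan, "scan_config"), length(dim(frames)) == 3L)
  if (dim(frames)[3] != scan$n_frames)
    stop("frame count ", dim(frames)[3], " != steps_per_axis^2 = ",
         scan$n_frames, call. = FALSE)
  structure(list(frames = frames, scan = scan), class = "raw_stack")
}

#' @export
print.raw_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<raw_stack> %d frames of %dx%d px (s=%d, p=%d px)\n",
              d[3], d[1], d[2], x$scan$steps_per_axis,
              x$scan$foci_pitch_px))
  invisible(x)
}

#' Generate a virtual sample
#'
#' A deterministic synthetic specimen on a micrometer pixel grid, used by
#' the virtual microscope in place of a biological sample. `"constant"`
#' gives a uniform field (the simplest invertibility check), `"spots"`
#' scatters Gaussian puncta (mitochondria-like), and `"filaments"` draws
#' random-walk curves (actin-like).
#'
#' @param kind `"constant"`, `"spots"` or `"filaments"`.
#' @param size_px Image size in pixels: scalar or `(H, W)`; >= 16 per axis.
#' @param seed Integer seed; identical seeds give identical samples.
#' @param value Intensity of the `"constant"` sample (default 100).
#' @param pixel_size_um Pixel size in micrometers (default 1).
#' @return A `virtual_sample`: list with `image` (non-negative matrix),
#'   `pixel_size_um`, `seed`, `kind`.
#' @export
make_sample <- function(kind = c("constant", "spots", "filaments"),
                        size_px = 128L, seed = 1L, value = 100,
                        pixel_size_um = 1) {
  kind <- match.arg(kind)
  if (length(size_px) == 1L) size_px <- c(size_px, size_px)
  size_px <- as.integer(size_px)
  if (any(size_px < 16L)) stop("size_px must be >= 16 per axis",
                               call. = FALSE)
  H <- size_px[1]; W <- size_px[2]
  img <- with_seed(seed, {
    switch(kind,
      constant = matrix(value, H, W),
      spots = {
        img <- matrix(0, H, W)
        n <- max(5L, round(H * W / 400))
        cy <- stats::runif(n, 1, H); cx <- stats::runif(n, 1, W)
        amp <- stats::runif(n, 2000, 8000)
        sg <- stats::runif(n, 1.0, 2.5)
        yy <- matrix(seq_len(H), H, W)
        xx <- matrix(seq_len(W), H, W, byrow = TRUE)
        for (i in seq_len(n))
          img <- img + amp[i] *
            exp(-((yy - cy[i])^2 + (xx - cx[i])^2) / (2 * sg[i]^2))
        img
      },
      filaments = {
        img <- matrix(0, H, W)
        n_fil <- max(3L, round((H + W) / 40))
        for (f in seq_len(n_fil)) {
          y <- stats::runif(1, 1, H); x <- stats::runif(1, 1, W)
          theta <- stats::runif(1, 0, 2 * pi)
          len <- round(1.5 * (H + W))
          inten <- stats::runif(1, 1500, 4000)
          for (step in seq_len(len)) {
            theta <- theta + stats::rnorm(1, 0, 0.15)
            y <- y + sin(theta); x <- x + cos(theta)
            if (y < 1 || y > H || x < 1 || x > W) break
            img[round(y), round(x)] <- img[round(y), round(x)] + inten
          }
        }
        img
      })
  })
  structure(list(image = img, pixel_size_um = pixel_size_um, seed = seed,
                 kind = kind), class = "virtual_sample")
}

# 0-based foci row/col indices (1-based R positions) for scan step k0.
foci_rows <- function(H, p, ky) which((seq_len(H) - 1L) %% p == ky)
foci_cols <- function(W, p, kx) which((seq_len(W) - 1L) %% p == kx)

gaussian_blur <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  # separable convolution with edge replication
  pad_idx <- function(n) c(rep(1L, r), seq_len(n), rep(n, r))
  mp <- m[pad_idx(nrow(m)), pad_idx(ncol(m))]
  out <- apply(mp, 2, function(col) stats::filter(col, k, sides = 2))
  out <- t(apply(out, 1, function(row) stats::filter(row, k, sides = 2)))
  out[(r + 1):(r + nrow(m)), (r + 1):(r + ncol(m))]
}

#' Acquire one raw stack from the virtual microscope
#'
#' Forward model of the grid-scan camera: the field of view is the
#' `fov_px` window of the sample at the commanded stage position (stage x
#' maps to image columns, y to rows; continuous micrometer positions snap
#' to the nearest pixel). Frame `k` (0-based, row-major over scan steps:
#' `k = ky * s + kx`) records
#' `background + amplitude * S` at the pixels whose 0-based coordinates
#' satisfy `col %% p == kx` and `row %% p == ky`, and `background`
#' everywhere else. Optional per-pixel Poisson noise is applied, and
#' values are rounded and clipped into the unsigned 16-bit camera range.
#'
#' @param sample A [make_sample()] result.
#' @param stage_xy_um Stage position `(x, y)` in micrometers.
#' @param scan A [scan_config()].
#' @param fov_px Detector shape `(H, W)` in pixels (default 64 x 64).
#' @param seed Optional seed for the noise draw (stacks are bit-identical
#'   given identical seeds and configs).
#' @return A [raw_stack()].
#' @export
acquire_stack <- function(sample, stage_xy_um = c(0, 0), scan = scan_config(),
                          fov_px = c(64L, 64L), seed = NULL) {
  stopifnot(inherits(sample, "virtual_sample"), inherits(scan, "scan_config"))
  if (length(fov_px) == 1L) fov_px <- c(fov_px, fov_px)
  H <- as.integer(fov_px[1]); W <- as.integer(fov_px[2])
  ps <- sample$pixel_size_um
  col0 <- round(stage_xy_um[1] / ps)   # 0-based offsets into the sample
  row0 <- round(stage_xy_um[2] / ps)
  Hs <- nrow(sample$image); Ws <- ncol(sample$image)
  if (row0 < 0 || col0 < 0 || row0 + H > Hs || col0 + W > Ws)
    stop(sprintf(
      "FOV outside sample: stage (%.2f, %.2f) um needs pixels [%d,%d]-[%d,%d] in a %dx%d sample",
      stage_xy_um[1], stage_xy_um[2], row0, col0, row0 + H - 1, col0 + W - 1,
      Hs, Ws), call. = FALSE)
  S <- sample$image[(row0 + 1):(row0 + H), (col0 + 1):(col0 + W),
                    drop = FALSE]
  if (scan$blur_sigma_px > 0) S <- gaussian_blur(S, scan$blur_sigma_px)

  s <- scan$steps_per_axis; p <- scan$foci_pitch_px
  frames <- with_seed(seed, {
    out <- array(0L, dim = c(H, W, scan$n_frames))
    for (k0 in 0:(scan$n_frames - 1L)) {
      kx <- k0 %% s; ky <- k0 %/% s
      fr <- matrix(scan$background, H, W)
      rows <- foci_rows(H, p, ky); cols <- foci_cols(W, p, kx)
      if (length(rows) && length(cols))
        fr[rows, cols] <- scan$background +
          scan$amplitude * S[rows, cols, drop = FALSE]
      if (scan$noise == "poisson")
        fr <- matrix(stats::rpois(length(fr), lambda = pmax(fr, 0)), H, W)
      fr <- round(fr)
      fr[fr < 0] <- 0; fr[fr > 65535] <- 65535
      out[, , k0 + 1L] <- as.integer(fr)
    }
    out
  })
  raw_stack(frames, scan)
}
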