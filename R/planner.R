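#' Plan a tile grid
#'
#' Computes the stage-target grid for a tiling experiment: `nx * ny`
#' tiles of `fov_um` micrometers with fractional overlap `overlap_frac`
#' between neighbors, so the stage step is `fov_um * (1 - overlap_frac)`.
#' The overlap exists so reconstructed tiles can be aligned in
#' post-processing, relaxing the stage's (x, y) precision requirement.
#' Tile indices `(i, j)` are 0-based with `i` along x (image columns,
#' rightward) and `j` along y (image rows, downward); the visit order is
#' row-major (all `i` within a row `j`, then the next row).
#'
#' @param nx,ny Grid size (integers >= 1).
#' @param fov_um Tile field of view in micrometers (> 0).
#' @param overlap_frac Overlap fraction `0 <= o < 1`.
#' @param origin_um Stage position `(x0, y0)` of tile (0, 0).
#' @param z_map Optional `function(i, j) -> z_um` for per-tile focus
#'   (e.g. a measured sample tilt); default 0 everywhere.
#' @return A `tile_plan`: grid parameters, the derived `step_um`, and a
#'   `targets` data.frame with columns `i, j, x_um, y_um, z_um, skip`.
#' @examples
#' plan <- plan_grid(5, 5, fov_um = 38, overlap_frac = 0.14)
#' plan$step_um          # 32.68
#' nrow(plan$targets)    # 25
#' @export
plan_grid <- function(nx, ny, fov_um, overlap_frac = 0,
                      origin_um = c(0, 0), z_map = NULL) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (is.na(nx) || is.na(ny) || nx < 1L || ny < 1L)
    stop("nx and ny must be integers >= 1", call. = FALSE)
  stopifnot_scalar_num(fov_um, "fov_um", 0, strict = TRUE)
  if (!is.numeric(overlap_frac) || overlap_frac < 0 || overlap_frac >= 1)
    stop("overlap_frac must satisfy 0 <= o < 1", call. = FALSE)
  step <- fov_um * (1 - overlap_frac)
  grid <- expand.grid(i = 0:(nx - 1L), j = 0:(ny - 1L))  # i fastest: row-major
  z <- if (is.null(z_map)) rep(0, nrow(grid))
       else mapply(z_map, grid$i, grid$j)
  targets <- data.frame(
    i = grid$i, j = grid$j,
    x_um = origin_um[1] + grid$i * step,
    y_um = origin_um[2] + grid$j * step,
    z_um = as.numeric(z),
    skip = FALSE)
  structure(list(nx = nx, ny = ny, fov_um = fov_um,
                 overlap_frac = overlap_frac, origin_um = origin_um,
                 step_um = step, targets = targets),
            class = "tile_plan")
}

#' @export
print.tile_plan <- function(x, ...) {
  cat(sprintf(
    "<tile_plan> %dx%d tiles of %g um, overlap %.0f%% (step %.4g um), %d skipped\n",
    x$nx, x$ny, x$fov_um, 100 * x$overlap_frac, x$step_um,
    sum(x$targets$skip)))
  invisible(x)
}

#' Mosaic extent along one axis
#'
#' Distance from the start of the first tile to the end of the last:
#' `n * fov - (n - 1) * overlap_frac * fov`. Five 38-micrometer tiles at
#' 14 % overlap give 168.72 um.
#'
#' @param n Number of tiles along the axis (>= 1).
#' @param fov_um Tile field of view (um).
#' @param overlap_frac Overlap fraction `0 <= o < 1`.
#' @return Extent in micrometers.
#' @export
mosaic_extent_um <- function(n, fov_um, overlap_frac = 0) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1", call. = FALSE)
  n * fov_um - (n - 1) * overlap_frac * fov_um
}

#' Apply focus registration and tile skips to a plan
#'
#' Headless stand-in for the interactive widefield registration step: a
#' table of per-tile focus positions and skip annotations (tiles without
#' content are skipped, adapting the acquisition to the sample). Tiles
#' not listed keep their current values.
#'
#' @param plan A [plan_grid()] result.
#' @param registrations data.frame with columns `i`, `j` and optionally
#'   `z_um`, `skip`.
#' @return The updated `tile_plan`.
#' @export
apply_registration <- function(plan, registrations) {
  stopifnot(inherits(plan, "tile_plan"))
  if (is.null(registrations) || nrow(registrations) == 0L) return(plan)
  stopifnot(all(c("i", "j") %in% names(registrations)))
  key <- paste(plan$targets$i, plan$targets$j)
  for (r in seq_len(nrow(registrations))) {
    idx <- match(paste(registrations$i[r], registrations$j[r]), key)
    if (is.na(idx))
      stop("unknown tile_index (", registrations$i[r], ", ",
           registrations$j[r], ")", call. = FALSE)
    if (!is.null(registrations$z_um) && !is.na(registrations$z_um[r]))
      plan$targets$z_um[idx] <- registrations$z_um[r]
    if (!is.null(registrations$skip) && !is.na(registrations$skip[r]))
      plan$targets$skip[idx] <- registrations$skip[r]
  }
  plan
}

#' Plan a cyclic timelapse over a tile grid
#'
#' The tile sequence (skipped tiles excluded) is visited `n_lapses`
#' times, imaging every tile once per lapse; `settle_s` seconds of
#' settling are budgeted after every stage move to let drift die down.
#'
#' @param tiles A [plan_grid()] result (skips already applied).
#' @param n_lapses Number of lapses `N >= 1`.
#' @param settle_s Post-move settle time in seconds (>= 0); default 1.
#' @return A `timelapse_plan` with a `visits` data.frame (tile columns
#'   plus `lapse`, 0-based) of length `N x` number of unskipped tiles.
#' @export
plan_timelapse <- function(tiles, n_lapses, settle_s = 1) {
  stopifnot(inherits(tiles, "tile_plan"))
  n_lapses <- as.integer(n_lapses)
  if (is.na(n_lapses) || n_lapses < 1L)
    stop("n_lapses must be >= 1", call. = FALSE)
  stopifnot_scalar_num(settle_s, "settle_s", 0)
  active <- tiles$targets[!tiles$targets$skip, , drop = FALSE]
  visits <- do.call(rbind, lapply(0:(n_lapses - 1L), function(t) {
    v <- active
    v$lapse <- t
    v
  }))
  rownames(visits) <- NULL
  structure(list(n_lapses = n_lapses, tiles = tiles, settle_s = settle_s,
                 visits = visits),
            class = "timelapse_plan")
}

#' @export
print.timelapse_plan <- function(x, ...) {
  cat(sprintf("<timelapse_plan> N=%d lapses x %d tiles = %d visits, settle %g s\n",
              x$n_lapses, nrow(x$visits) / x$n_lapses, nrow(x$visits),
              x$settle_s))
  invisible(x)
}

# Visit table of either plan type: one row per stage target in execution
# order, with a lapse column (0 for a plain tiling pass).
plan_visits <- function(plan) {
  if (inherits(plan, "timelapse_plan")) {
    v <- plan$visits
    v$settle_s <- plan$settle_s
    v
  } else if (inherits(plan, "tile_plan")) {
    v <- plan$targets[!plan$targets$skip, , drop = FALSE]
    v$lapse <- 0L
    v$settle_s <- 0
    rownames(v) <- NULL
    v
  } else stop("not a plan", call. = FALSE)
}

#' Serialize a plan to JSON
#'
#' Writes the grid parameters and per-tile records (plus lapse schedule
#' for timelapse plans) as a JSON document that experiment scripts load
#' through the control API.
#'
#' @param plan A `tile_plan` or `timelapse_plan`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plan <- function(plan, path) {
  if (inherits(plan, "timelapse_plan")) {
    doc <- list(type = "timelapse", n_lapses = plan$n_lapses,
                settle_s = plan$settle_s,
                grid = plan$tiles[c("nx", "ny", "fov_um", "overlap_frac",
                                    "origin_um", "step_um")],
                targets = plan$tiles$targets,
                visits = plan_visits(plan))
  } else if (inherits(plan, "tile_plan")) {
    doc <- list(type = "tiling",
                grid = plan[c("nx", "ny", "fov_um", "overlap_frac",
                              "origin_um", "step_um")],
                targets = plan$targets,
                visits = plan_visits(plan))
  } else stop("not a plan", call. = FALSE)
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                              dataframe = "columns"), path)
  invisible(path)
}

#' Read a plan JSON document
#'
#' @param path Path written by [write_plan()].
#' @return A `tile_plan` or `timelapse_plan` equal to the one written.
#' @export
read_plan <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  g <- doc$grid
  plan <- plan_grid(g$nx, g$ny, g$fov_um, g$overlap_frac,
                    as.numeric(g$origin_um))
  t <- as.data.frame(doc$targets)
  plan$targets <- data.frame(i = as.integer(t$i), j = as.integer(t$j),
                             x_um = t$x_um, y_um = t$y_um, z_um = t$z_um,
                             skip = t$skip)
  if (identical(doc$type, "timelapse"))
    plan_timelapse(plan, doc$n_lapses, doc$settle_s)
  else plan
}
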