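#' Create a layer registry
#'
#' Headless stand-in for the viewer's layer list: an ordered, named
#' collection of reconstructed images with their metadata, filled by the
#' orchestrator's watch on the `rec` folder.
#'
#' @return A `layer_registry` environment.
#' @export
layer_registry <- function() {
  r <- new.env(parent = emptyenv())
  r$entries <- list()       # name -> list(image, metadata, source, added_at)
  r$paths <- character(0)   # normalized source paths, for idempotence
  class(r) <- c("layer_registry", class(r))
  r
}

#' @export
print.layer_registry <- function(x, ...) {
  cat(sprintf("<layer_registry> %d layers\n", length(x$entries)))
  for (nm in names(x$entries)) cat(" -", nm, "\n")
  invisible(x)
}

#' Register a reconstructed image as a layer
#'
#' Reads a reconstruction output (TIFF or OME-Zarr) and appends it to
#' the registry under its filename stem, preserving arrival order. The
#' image's metadata travels with the entry so the acquisition conditions
#' of every displayed tile remain inspectable. Re-adding an
#' already-registered path is ignored with a warning; an unreadable file
#' warns and leaves the registry unchanged.
#'
#' @param registry A [layer_registry()].
#' @param path `.tiff` or `.zarr` written by [process_raw_file()].
#' @param bus Optional [event_bus()]; emits `"layer_added"`.
#' @return The registry, invisibly.
#' @export
register_layer <- function(registry, path, bus = NULL) {
  stopifnot(inherits(registry, "layer_registry"))
  norm <- normalizePath(path, mustWork = FALSE)
  if (norm %in% registry$paths) {
    warning("layer already registered, ignoring: ", basename(path),
            call. = FALSE)
    return(invisible(registry))
  }
  loaded <- tryCatch({
    low <- tolower(path)
    if (endsWith(low, ".tiff") || endsWith(low, ".tif")) {
      x <- read_float_tiff(path)
      list(image = x$image, meta = x$meta)
    } else if (endsWith(low, ".zarr")) {
      x <- omezarr_read(path)
      list(image = x$image, meta = x$attrs)
    } else stop("unsupported layer format: ", path, call. = FALSE)
  }, error = function(e) {
    warning("could not read layer ", basename(path), ": ",
            conditionMessage(e), call. = FALSE)
    NULL
  })
  if (is.null(loaded)) return(invisible(registry))
  meta <- loaded$meta
  if (is.null(meta)) {
    warning("layer has no metadata block: ", basename(path), call. = FALSE)
    meta <- list()
  }
  name <- sub("\\.(tiff|tif|zarr)$", "", basename(path), ignore.case = TRUE)
  # same stem in both output formats: keep names unique, arrival order intact
  k <- 1L
  base_name <- name
  while (!is.null(registry$entries[[name]])) {
    k <- k + 1L
    name <- sprintf("%s [%d]", base_name, k)
  }
  registry$entries[[name]] <- list(image = loaded$image, metadata = meta,
                                   source = norm, added_at = Sys.time())
  registry$paths <- c(registry$paths, norm)
  if (!is.null(bus)) emit(bus, "layer_added", name)
  invisible(registry)
}

#' Dump a registry as JSON
#'
#' Names, sources, arrival times and metadata of every layer (images
#' excluded), for offline inspection of what the orchestrator saw.
#'
#' @param registry A [layer_registry()].
#' @param path Optional output path; when `NULL` the JSON is returned.
#' @export
registry_to_json <- function(registry, path = NULL) {
  doc <- lapply(names(registry$entries), function(nm) {
    e <- registry$entries[[nm]]
    list(name = nm, source = e$source, added_at = iso_ts(e$added_at),
         shape_px = dim(e$image), metadata = e$metadata)
  })
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}

# Pull (image, stage position, pixel size, tile index) out of a registry
# entry or recon-tile-like list, tolerating both metadata layouts (TIFF
# description vs OME-Zarr attrs).
tile_geometry <- function(tile) {
  meta <- tile$metadata %||% tile$meta
  im_json <- meta[["ImSwitchData"]] %||% meta$ImSwitchData
  acq <- if (is.character(im_json)) meta_from_json(im_json) else meta
  list(image = tile$image,
       stage_xy = acq$stage_position_um[1:2],
       pixel_size_um = acq$pixel_size_um,
       tile_index = acq$tile_index %||% c(NA_integer_, NA_integer_))
}

#' Compute nominal mosaic layout from stage coordinates
#'
#' Places every tile on a shared canvas at the pixel offset implied by
#' its recorded stage position: each tile's stage (x, y) is converted to
#' pixels with its (shared) pixel size and shifted so the smallest
#' offset is (0, 0). This replaces interactive stitching with the
#' stage's own geometry; [overlap_consistency()] quantifies when
#' correlation-based refinement would actually be needed.
#'
#' @param tiles List of registry entries or tiles: each needs `image`
#'   and metadata carrying stage position and pixel size. All tiles must
#'   share pixel size and shape.
#' @return A `mosaic_layout`: `offsets_px` data.frame (`row_px`,
#'   `col_px`, `i`, `j`), `canvas_shape_px`, `pixel_size_um`.
#' @export
compute_layout <- function(tiles) {
  stopifnot(length(tiles) >= 1L)
  geo <- lapply(tiles, tile_geometry)
  ps <- vapply(geo, function(g) g$pixel_size_um, numeric(1))
  if (max(ps) - min(ps) > 1e-9)
    stop("tiles have mixed pixel sizes", call. = FALSE)
  shp <- vapply(geo, function(g) dim(g$image), integer(2))
  if (any(shp != shp[, 1]))
    stop("tiles have mixed shapes", call. = FALSE)
  # same rounding as the simulator's crop, so nominal placement is exact
  rows <- vapply(geo, function(g) round(g$stage_xy[2] / ps[1]), numeric(1))
  cols <- vapply(geo, function(g) round(g$stage_xy[1] / ps[1]), numeric(1))
  rows <- rows - min(rows); cols <- cols - min(cols)
  H <- shp[1, 1]; W <- shp[2, 1]
  offsets <- data.frame(
    row_px = as.integer(rows), col_px = as.integer(cols),
    i = vapply(geo, function(g) as.integer(g$tile_index[1]), integer(1)),
    j = vapply(geo, function(g) as.integer(g$tile_index[2]), integer(1)))
  structure(list(offsets_px = offsets,
                 canvas_shape_px = c(as.integer(max(rows) + H),
                                     as.integer(max(cols) + W)),
                 pixel_size_um = ps[1], tile_shape_px = c(H, W)),
            class = "mosaic_layout")
}

#' Assemble tiles into a mosaic
#'
#' Composes the tiles onto the layout's canvas. `"average"` (default)
#' divides each pixel by its coverage count, so perfectly consistent
#' overlaps are conserved exactly; `"overwrite"` lets later tiles win;
#' `"feather"` weights each tile by its distance to its own border,
#' hiding seams when overlaps disagree slightly. Pixels covered by no
#' tile are 0.
#'
#' @param tiles As in [compute_layout()] (same order as the layout).
#' @param layout A [compute_layout()] result.
#' @param blend `"average"`, `"overwrite"` or `"feather"`.
#' @return Canvas matrix.
#' @export
assemble_mosaic <- function(tiles, layout,
                            blend = c("average", "overwrite", "feather")) {
  blend <- match.arg(blend)
  stopifnot(inherits(layout, "mosaic_layout"),
            length(tiles) == nrow(layout$offsets_px))
  Hc <- layout$canvas_shape_px[1]; Wc <- layout$canvas_shape_px[2]
  canvas <- matrix(0, Hc, Wc)
  weight <- matrix(0, Hc, Wc)
  for (t in seq_along(tiles)) {
    img <- (tile_geometry(tiles[[t]]))$image
    H <- nrow(img); W <- ncol(img)
    r0 <- layout$offsets_px$row_px[t]; c0 <- layout$offsets_px$col_px[t]
    if (r0 < 0 || c0 < 0 || r0 + H > Hc || c0 + W > Wc)
      stop("tile ", t, " falls outside the canvas", call. = FALSE)
    rr <- (r0 + 1):(r0 + H); cc <- (c0 + 1):(c0 + W)
    if (blend == "overwrite") {
      canvas[rr, cc] <- img
      weight[rr, cc] <- 1
    } else if (blend == "average") {
      canvas[rr, cc] <- canvas[rr, cc] + img
      weight[rr, cc] <- weight[rr, cc] + 1
    } else {
      dr <- pmin(seq_len(H), rev(seq_len(H)))
      dc <- pmin(seq_len(W), rev(seq_len(W)))
      wt <- outer(dr, dc, pmin)
      canvas[rr, cc] <- canvas[rr, cc] + img * wt
      weight[rr, cc] <- weight[rr, cc] + wt
    }
  }
  if (blend != "overwrite") {
    nz <- weight > 0
    canvas[nz] <- canvas[nz] / weight[nz]
  }
  canvas
}

#' Pairwise overlap consistency of a layout
#'
#' For every tile pair whose placements overlap, the RMS of the pixel
#' differences over the shared region — 0 for perfectly consistent
#' noiseless tiles, about `sigma * sqrt(2)` when each tile carries
#' independent noise of standard deviation `sigma`, and inflated by
#' misplacement, which is exactly the signal that correlation-based
#' stitching refinement would be needed.
#'
#' @param tiles As in [compute_layout()].
#' @param layout A [compute_layout()] result.
#' @return data.frame with columns `a`, `b` (tile indices into `tiles`),
#'   `n_px`, `rms`. Pairs without overlap are omitted.
#' @export
overlap_consistency <- function(tiles, layout) {
  stopifnot(inherits(layout, "mosaic_layout"))
  n <- length(tiles)
  off <- layout$offsets_px
  out <- data.frame(a = integer(0), b = integer(0), n_px = integer(0),
                    rms = numeric(0))
  imgs <- lapply(tiles, function(t) (tile_geometry(t))$image)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (b <= a) next
    Ha <- nrow(imgs[[a]]); Wa <- ncol(imgs[[a]])
    Hb <- nrow(imgs[[b]]); Wb <- ncol(imgs[[b]])
    r1 <- max(off$row_px[a], off$row_px[b])
    r2 <- min(off$row_px[a] + Ha, off$row_px[b] + Hb) - 1L
    c1 <- max(off$col_px[a], off$col_px[b])
    c2 <- min(off$col_px[a] + Wa, off$col_px[b] + Wb) - 1L
    if (r2 < r1 || c2 < c1) next
    pa <- imgs[[a]][(r1 - off$row_px[a] + 1):(r2 - off$row_px[a] + 1),
                    (c1 - off$col_px[a] + 1):(c2 - off$col_px[a] + 1)]
    pb <- imgs[[b]][(r1 - off$row_px[b] + 1):(r2 - off$row_px[b] + 1),
                    (c1 - off$col_px[b] + 1):(c2 - off$col_px[b] + 1)]
    out <- rbind(out, data.frame(
      a = a, b = b, n_px = length(pa),
      rms = sqrt(mean((pa - pb)^2))))
  }
  out
}

#' Run the orchestrator unit
#'
#' Watches the `rec` folder for reconstructed TIFFs and registers each
#' as a layer, FIFO, mirroring the viewer that displays incoming tiles.
#'
#' @param watch A [watch_config()] on the `rec` folder (extensions
#'   typically `".tiff"`).
#' @param registry A [layer_registry()] filled in place.
#' @param stop_when,max_polls,sleep Passed to the watch loop.
#' @param bus Optional [event_bus()].
#' @return The session's `experiment_log`, invisibly.
#' @export
run_orchestrator_unit <- function(watch, registry = layer_registry(),
                                  stop_when = NULL, max_polls = Inf,
                                  sleep = TRUE, bus = NULL) {
  session <- orchestrator_session(watch, registry, bus)
  n <- 0
  repeat {
    poll_session(session)
    n <- n + 1
    if (!is.null(stop_when) && isTRUE(stop_when())) break
    if (n >= max_polls) break
    if (sleep) Sys.sleep(watch$poll_interval_s)
  }
  invisible(session$log)
}

orchestrator_session <- function(watch, registry, bus = NULL) {
  handler <- function(path) register_layer(registry, path, bus = bus)
  s <- watch_session(watch, handler, role = "orchestrator")
  s$registry <- registry
  s
}
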