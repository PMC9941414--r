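test_that("reconstruct_stack matches the brute-force oracle on random stacks", {
  for (seed in 1:20) {
    st <- random_stack(s = 8L, H = 16L, W = 16L, seed = seed)
    expect_identical(reconstruct_stack(st, recon_params(0)),
                     recon_oracle(st, 0))
  }
  # windowed variant and background subtraction, smaller cases
  for (seed in 1:5) {
    st <- random_stack(s = 3L, H = 12L, W = 12L, seed = seed, p = 5L)
    expect_equal(reconstruct_stack(st, recon_params(1)),
                 recon_oracle(st, 1L), tolerance = 1e-12)
    expect_equal(
      reconstruct_stack(st, recon_params(2, background_mode = "global_min")),
      recon_oracle(st, 2L, "global_min"), tolerance = 1e-12)
  }
})

test_that("simulate then reconstruct is the identity on noiseless stacks", {
  # constant sample: uniform image at the constant
  cs <- make_sample("constant", 64, value = 211)
  stc <- acquire_stack(cs, c(0, 0), tiny_scan(4), fov_px = 24)
  expect_true(all(reconstruct_stack(stc) == 211))

  # arbitrary samples, any seed, p == s, w = 0
  for (seed in c(1, 7, 23)) {
    s <- make_sample("spots", 96, seed = seed)
    st <- acquire_stack(s, c(8, 16), tiny_scan(6), fov_px = c(30, 36))
    truth <- round(s$image[17:46, 9:44])
    expect_identical(reconstruct_stack(st), truth)
  }
})

test_that("an all-zero stack reconstructs to a zero image", {
  st <- raw_stack(array(0L, dim = c(8, 8, 16)), tiny_scan(4))
  expect_true(all(reconstruct_stack(st) == 0))
})

test_that("reconstruction conserves total focus-pixel signal at w = 0", {
  st <- random_stack(s = 4L, H = 12L, W = 12L, seed = 3)
  R <- reconstruct_stack(st)
  total <- 0
  for (k0 in 0:15) {
    rows <- scopeflow:::foci_rows(12, 4, k0 %/% 4)
    cols <- scopeflow:::foci_cols(12, 4, k0 %% 4)
    total <- total + sum(st$frames[rows, cols, k0 + 1])
  }
  expect_equal(sum(R), total, tolerance = 1e-9)
})

test_that("global_min background subtraction removes a constant offset", {
  s <- make_sample("spots", 64, seed = 4)
  clean <- acquire_stack(s, c(0, 0), tiny_scan(4), fov_px = 24)
  offset <- acquire_stack(s, c(0, 0), tiny_scan(4, background = 50),
                          fov_px = 24)
  R <- reconstruct_stack(offset, recon_params(background_mode = "global_min"))
  # min over the offset stack is the background (some dark pixels exist)
  expect_equal(R, reconstruct_stack(clean) * 1.0, tolerance = 1e-12)
})

test_that("reconstruction error shrinks as the signal level grows", {
  s <- make_sample("spots", 64, seed = 6)
  peak <- max(s$image)
  mae <- vapply(c(0.05, 0.5, 5), function(amp) {
    st <- acquire_stack(s, c(0, 0),
                        tiny_scan(4, amplitude = amp, noise = "poisson"),
                        fov_px = 24, seed = 123)
    R <- reconstruct_stack(st) / amp
    truth <- s$image[1:24, 1:24]
    mean(abs(R - truth)) / peak
  }, numeric(1))
  expect_true(all(diff(mae) < 0))
})

test_that("a window reaching a neighboring focus is a parameter error", {
  st <- random_stack(s = 4L, H = 12L, W = 12L, seed = 1)
  expect_error(reconstruct_stack(st, recon_params(2)), "overlap")
  expect_error(reconstruct_stack(st, recon_params(0, algorithm_id = "nope")),
               "unknown")
})

test_that("process_raw_file writes matching TIFF and OME-Zarr outputs", {
  fxs <- make_sample("spots", 48, seed = 12)
  st <- acquire_stack(fxs, c(0, 0), tiny_scan(4), fov_px = 16)
  meta <- acq_metadata(c(0, 0, 0), st$scan, c(16L, 16L), 1)
  d <- tmp_dir()
  pz <- save_raw(st, meta, d, "zarr", "t1")
  ph <- save_raw(st, meta, d, "hdf5", "t2")
  rec <- file.path(d, "rec")

  out_z <- process_raw_file(pz, recon_params(), rec)
  expect_true(file.exists(out_z["tiff"]) && dir.exists(out_z["zarr"]))
  tiff_img <- scopeflow:::read_float_tiff(out_z["tiff"])
  zarr_img <- scopeflow:::omezarr_read(out_z["zarr"])
  expect_identical(tiff_img$image, zarr_img$image)
  expect_identical(tiff_img$image, reconstruct_stack(st) * 1.0)
  # metadata travels in both outputs
  expect_identical(
    scopeflow:::meta_from_json(tiff_img$meta$ImSwitchData)$detector_shape_px,
    c(16L, 16L))
  expect_identical(zarr_img$attrs$multiscales$version, "0.4")

  # format-agnostic ingest: HDF5 input gives the same reconstruction
  out_h <- process_raw_file(ph, recon_params(), rec)
  expect_identical(scopeflow:::read_float_tiff(out_h["tiff"])$image,
                   tiff_img$image)
})

test_that("a corrupt raw file fails cleanly with no partial outputs", {
  d <- tmp_dir()
  rec <- file.path(d, "rec")
  writeLines("not hdf5", file.path(d, "broken.h5"))
  expect_error(suppressWarnings(
    process_raw_file(file.path(d, "broken.h5"), recon_params(), rec)))
  expect_identical(list.files(rec, recursive = TRUE), character(0))
})

test_that("the reconstruction unit processes dropped stacks FIFO and ignores rec/", {
  d <- tmp_dir()
  s <- make_sample("spots", 48, seed = 20)
  meta_scan <- tiny_scan(3)
  for (i in 1:4) {
    st <- acquire_stack(s, c(0, 0), meta_scan, fov_px = 16)
    meta <- acq_metadata(c(0, 0, 0), meta_scan, c(16L, 16L), 1)
    save_raw(st, meta, d, "zarr", sprintf("tile%02d", i))
  }
  watch <- watch_config(d, c(".zarr", ".h5"), poll_interval_s = 0.01,
                        process_preexisting = TRUE)
  session <- scopeflow:::reconstruction_session(watch, recon_params())
  for (k in 1:3) poll_session(session)
  tiffs <- list.files(file.path(d, "rec"), pattern = "_rec\\.tiff$")
  expect_identical(length(tiffs), 4L)
  expect_identical(nrow(session$log$records), 4L)
  expect_identical(basename(session$log$records$item_path),
                   sprintf("tile%02d.zarr", 1:4))
  # outputs in rec/ are never re-ingested: further polls of the same
  # session discover no new work
  for (k in 1:3) poll_session(session)
  expect_identical(session$handled, 4L)
  # the runner writes the session log next to the data
  log <- run_reconstruction_unit(watch, recon_params(), max_polls = 1,
                                 sleep = FALSE)
  expect_identical(length(list.files(d, pattern = "^reconstruction_.*\\.log$")),
                   1L)
})
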