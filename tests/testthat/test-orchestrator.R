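# Build reconstructed-tile-like entries directly (image + metadata), the
# same shape register_layer produces.
fake_tile <- function(image, x_um, y_um, pixel_size_um = 1, i = 0L, j = 0L) {
  sc <- tiny_scan(2)
  meta <- acq_metadata(c(x_um, y_um, 0), sc, dim(image),
                       pixel_size_um = pixel_size_um,
                       tile_index = c(i, j))
  list(image = image,
       metadata = list(ImSwitchData = scopeflow:::meta_to_json(meta)))
}

test_that("the registry preserves arrival order and ignores duplicates", {
  d <- tmp_dir()
  s <- make_sample("spots", 48, seed = 30)
  for (i in 1:3) {
    st <- acquire_stack(s, c(0, 0), tiny_scan(3), fov_px = 16)
    meta <- acq_metadata(c(0, 0, 0), st$scan, c(16L, 16L), 1)
    pz <- save_raw(st, meta, d, "zarr", sprintf("t%d", i))
    process_raw_file(pz, recon_params(), file.path(d, "rec"))
  }
  tiffs <- list.files(file.path(d, "rec"), pattern = "\\.tiff$",
                      full.names = TRUE)
  reg <- layer_registry()
  for (p in tiffs) register_layer(reg, p)
  expect_identical(names(reg$entries), sub("\\.tiff$", "", basename(tiffs)))

  expect_warning(register_layer(reg, tiffs[1]), "already registered")
  expect_identical(length(reg$entries), 3L)

  # OME-Zarr layers load too; the shared stem gets a disambiguated name
  zarrs <- list.files(file.path(d, "rec"), pattern = "\\.zarr$",
                      full.names = TRUE)
  register_layer(reg, zarrs[1])
  expect_identical(length(reg$entries), 4L)
  expect_identical(anyDuplicated(names(reg$entries)), 0L)

  # unreadable file: warning, registry unchanged
  bad <- file.path(d, "rec", "junk.tiff")
  writeLines("junk", bad)
  expect_warning(register_layer(reg, bad), "could not read")
  expect_identical(length(reg$entries), 4L)

  js <- jsonlite::fromJSON(registry_to_json(reg))
  expect_identical(nrow(js), 4L)
})

test_that("layout offsets follow stage coordinates on the shared canvas", {
  img <- matrix(0, 100, 100)
  single <- compute_layout(list(fake_tile(img, 0, 0)))
  expect_identical(single$offsets_px$row_px, 0L)
  expect_identical(single$canvas_shape_px, c(100L, 100L))

  # two tiles at 14 % overlap: step 86 um at 1 um/px
  two <- compute_layout(list(fake_tile(img, 0, 0),
                             fake_tile(img, 86, 0, i = 1L)))
  expect_identical(two$offsets_px$col_px, c(0L, 86L))
  expect_identical(two$canvas_shape_px, c(100L, 186L))

  # 5x5 grid: canvas 100 + 4*86 = 444 per axis
  tiles <- list()
  for (j in 0:4) for (i in 0:4)
    tiles <- c(tiles, list(fake_tile(img, 86 * i, 86 * j, i = i, j = j)))
  full <- compute_layout(tiles)
  expect_identical(full$canvas_shape_px, c(444L, 444L))

  # layout offsets recomputed from a plan match its step geometry
  plan <- plan_grid(5, 5, 100, 0.14)
  ptiles <- lapply(seq_len(25), function(r)
    fake_tile(img, plan$targets$x_um[r], plan$targets$y_um[r]))
  poff <- compute_layout(ptiles)$offsets_px
  expect_identical(sort(unique(poff$col_px)),
                   as.integer(round((0:4) * plan$step_um)))

  mixed <- list(fake_tile(img, 0, 0),
                fake_tile(img, 86, 0, pixel_size_um = 2))
  expect_error(compute_layout(mixed), "mixed pixel sizes")
})

test_that("noiseless simulate-reconstruct-stitch recovers the sample exactly", {
  s <- make_sample("filaments", c(150, 150), seed = 41)
  plan <- plan_grid(3, 3, fov_um = 50, overlap_frac = 0.2)  # step 40 px
  tiles <- lapply(seq_len(nrow(plan$targets)), function(r) {
    st <- acquire_stack(s, c(plan$targets$x_um[r], plan$targets$y_um[r]),
                        tiny_scan(5), fov_px = 50)
    fake_tile(reconstruct_stack(st), plan$targets$x_um[r],
              plan$targets$y_um[r], i = plan$targets$i[r],
              j = plan$targets$j[r])
  })
  layout <- compute_layout(tiles)
  mosaic <- assemble_mosaic(tiles, layout, blend = "average")
  truth <- round(s$image[1:130, 1:130])
  expect_equal(mosaic, truth, tolerance = 1e-12)

  # overlaps agree perfectly, so every pairwise RMS is 0
  cons <- overlap_consistency(tiles, layout)
  expect_gt(nrow(cons), 0)
  expect_true(all(cons$rms == 0))
})

test_that("blending conserves constant tiles with no seam", {
  img <- matrix(55, 60, 60)
  tiles <- list(fake_tile(img, 0, 0), fake_tile(img, 40, 0, i = 1L))
  layout <- compute_layout(tiles)
  for (blend in c("average", "overwrite", "feather")) {
    mosaic <- assemble_mosaic(tiles, layout, blend = blend)
    expect_true(all(mosaic == 55), info = blend)
  }
  expect_identical(assemble_mosaic(tiles[1], compute_layout(tiles[1])),
                   img)
})

test_that("overlap RMS tracks independent noise at sigma*sqrt(2)", {
  sigma <- 7
  base <- matrix(100, 120, 120)
  set.seed(202)
  t1 <- fake_tile(base + matrix(rnorm(120^2, 0, sigma), 120), 0, 0)
  t2 <- fake_tile(base + matrix(rnorm(120^2, 0, sigma), 120), 30, 0, i = 1L)
  layout <- compute_layout(list(t1, t2))
  cons <- overlap_consistency(list(t1, t2), layout)
  expect_gte(cons$n_px, 1e4)
  expect_equal(cons$rms, sigma * sqrt(2), tolerance = 0.1)
})

test_that("a misplaced tile inflates its pairwise RMS", {
  s <- make_sample("filaments", c(80, 140), seed = 55)
  img_a <- s$image[1:80, 1:80]
  img_b <- s$image[1:80, 41:120]
  t_a <- fake_tile(img_a, 0, 0)
  t_b <- fake_tile(img_b, 40, 0, i = 1L)
  layout <- compute_layout(list(t_a, t_b))
  baseline <- overlap_consistency(list(t_a, t_b), layout)$rms
  expect_equal(baseline, 0, tolerance = 1e-12)

  shifted <- fake_tile(s$image[1:80, 43:122], 40, 0, i = 1L)  # 2 px off
  worse <- overlap_consistency(list(t_a, shifted), layout)$rms
  expect_gt(worse, baseline)
})
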