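test_that("plan_grid reproduces the tiling geometry", {
  plan <- plan_grid(5, 5, fov_um = 38, overlap_frac = 0.14)
  expect_identical(nrow(plan$targets), 25L)
  expect_equal(plan$step_um, 32.68, tolerance = 1e-12)

  single <- plan_grid(1, 1, 38, 0.14)
  expect_identical(nrow(single$targets), 1L)
  expect_equal(unlist(single$targets[1, c("x_um", "y_um")]),
               c(x_um = 0, y_um = 0))

  p23 <- plan_grid(2, 3, 10, 0.5)
  expect_setequal(unique(p23$targets$x_um), c(0, 5))
  expect_setequal(unique(p23$targets$y_um), c(0, 5, 10))

  # row-major visit order: i varies fastest
  expect_identical(p23$targets$i[1:4], c(0L, 1L, 0L, 1L))
  expect_identical(p23$targets$j[1:4], c(0L, 0L, 1L, 1L))

  expect_error(plan_grid(0, 1, 38), ">= 1")
  expect_error(plan_grid(2, 2, 38, overlap_frac = 1), "overlap_frac")
})

test_that("mosaic extent follows the overlap formula and its invariants", {
  expect_equal(mosaic_extent_um(1, 38, 0.14), 38)
  expect_equal(mosaic_extent_um(5, 38, 0.14), 168.72, tolerance = 1e-12)
  expect_gte(mosaic_extent_um(5, 38, 0.14), 160)
  expect_equal(mosaic_extent_um(2, 10, 0), 20)

  # oracle: first-tile start to last-tile end, summing steps
  extent_oracle <- function(n, f, o) (n - 1) * f * (1 - o) + f
  for (n in 1:6) for (o in c(0, 0.14, 0.5))
    expect_equal(mosaic_extent_um(n, 38, o), extent_oracle(n, 38, o),
                 tolerance = 1e-12)

  # zero overlap is n*f; extent is non-increasing in overlap
  expect_equal(mosaic_extent_um(4, 25, 0), 100)
  ext <- vapply(c(0, 0.1, 0.2, 0.5), mosaic_extent_um, numeric(1),
                n = 5, fov_um = 38)
  expect_true(all(diff(ext) < 0))
})

test_that("adjacent tiles overlap by exactly the overlap fraction", {
  plan <- plan_grid(5, 5, 38, 0.14)
  t <- plan$targets
  for (j in 0:4) {
    xs <- sort(t$x_um[t$j == j])
    gaps <- diff(xs)
    # shared region per axis = fov - step = overlap_frac * fov
    expect_true(all(abs((38 - gaps) - 0.14 * 38) < 1e-9))
  }
})

test_that("registration updates focus and skips, rejecting unknown tiles", {
  plan <- plan_grid(5, 5, 38, 0.14)

  # tilt plane z = a*x + b*y registered for every tile
  a <- 0.01; b <- -0.02
  regs <- data.frame(i = plan$targets$i, j = plan$targets$j,
                     z_um = a * plan$targets$x_um + b * plan$targets$y_um,
                     skip = FALSE)
  reg_plan <- apply_registration(plan, regs)
  expect_equal(reg_plan$targets$z_um,
               a * plan$targets$x_um + b * plan$targets$y_um,
               tolerance = 1e-12)

  # skip 5 of 25 tiles: visit sequence shrinks to 20
  skips <- data.frame(i = 0:4, j = 2L, z_um = NA_real_, skip = TRUE)
  sk_plan <- apply_registration(plan, skips)
  expect_identical(nrow(scopeflow:::plan_visits(sk_plan)), 20L)

  expect_identical(apply_registration(plan, NULL), plan)
  expect_error(apply_registration(plan, data.frame(i = 9L, j = 0L)),
               "unknown tile_index")
})

test_that("timelapse plans repeat the tile order once per lapse", {
  grid <- plan_grid(2, 2, 38, 0.14)
  tl <- plan_timelapse(grid, n_lapses = 10, settle_s = 1)
  expect_identical(nrow(tl$visits), 40L)
  expect_identical(tl$visits$lapse, rep(0:9, each = 4L))
  # tile order preserved within every lapse
  for (t in 0:9)
    expect_identical(tl$visits$i[tl$visits$lapse == t], grid$targets$i)

  one <- plan_timelapse(plan_grid(1, 1, 38), 3)
  expect_identical(nrow(one$visits), 3L)
  expect_true(all(one$visits$x_um == 0))

  skipped <- apply_registration(grid, data.frame(i = 0L, j = 0L, skip = TRUE))
  expect_identical(nrow(plan_timelapse(skipped, 2)$visits), 6L)
  expect_error(plan_timelapse(grid, 0), ">= 1")
})

test_that("plans roundtrip through their JSON serialization", {
  plan <- apply_registration(
    plan_grid(3, 2, 38, 0.14),
    data.frame(i = c(0L, 2L), j = c(0L, 1L), z_um = c(1.5, -0.25),
               skip = c(FALSE, TRUE)))
  d <- tmp_dir()
  p <- file.path(d, "plan.json")
  write_plan(plan, p)
  back <- read_plan(p)
  expect_equal(back$targets, plan$targets, tolerance = 1e-12)
  expect_equal(back$step_um, plan$step_um, tolerance = 1e-12)

  tl <- plan_timelapse(plan, 4, settle_s = 1)
  write_plan(tl, p)
  back_tl <- read_plan(p)
  expect_identical(back_tl$n_lapses, 4L)
  expect_equal(back_tl$visits, tl$visits, tolerance = 1e-12)
})
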