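demo_backend <- function(d, s = 3L, fov = 16L, sample_seed = 1L,
                         format = "zarr") {
  sample <- make_sample("spots", 128, seed = sample_seed)
  acq_backend(sample, folder = d, format = format, scan = tiny_scan(s),
              fov_px = fov)
}

test_that("an empty script succeeds, emits the finished event, writes nothing", {
  d <- tmp_dir()
  backend <- demo_backend(d)
  api <- control_api(backend)
  finished <- list()
  subscribe(backend$bus, "script_finished",
            function(path, status) finished[[length(finished) + 1]] <<-
              c(path, status))
  sp <- write_script(d, "empty.R", "# nothing to do")
  expect_identical(run_script(sp, api), "ok")
  expect_identical(length(finished), 1L)
  expect_identical(finished[[1]][2], "ok")
  expect_identical(list.files(d, pattern = "\\.(zarr|h5)$"), character(0))
})

test_that("scripts run in a restricted namespace exposing only the api", {
  d <- tmp_dir()
  backend <- demo_backend(d)
  api <- control_api(backend)
  sp <- write_script(d, "bad.R", "api$imcontrol$fly_to_moon()")
  expect_warning(st <- run_script(sp, api), "script failed")
  expect_identical(st, "failed")
  # package functions are not visible inside the sandbox
  sp2 <- write_script(d, "leaky.R", "make_sample('spots', 32)")
  expect_warning(st2 <- run_script(sp2, api), "script failed")
  expect_identical(st2, "failed")
  # a failure never blocks the next script
  sp3 <- write_script(d, "next.R", "api$imcontrol$log_message('alive')")
  expect_identical(run_script(sp3, api), "ok")
  expect_identical(backend$messages, "alive")
})

test_that("each run_scan writes exactly one raw file with scan metadata", {
  d <- tmp_dir()
  backend <- demo_backend(d)
  api <- control_api(backend)
  sp <- write_script(d, "scans.R", c(
    "api$imcontrol$move_stage(x = 10, y = 20, z = -1)",
    "api$imcontrol$set_param('tile_index', c(1, 2))",
    "p1 <- api$imcontrol$run_scan('demo')",
    "api$imcontrol$wait_for_scan_end()",
    "p2 <- api$imcontrol$run_scan('demo')"))
  expect_identical(run_script(sp, api), "ok")
  files <- list.files(d, pattern = "\\.zarr$")
  expect_identical(length(files), 2L)              # one file per scan
  expect_identical(backend$scan_count, 2L)
  expect_false(files[1] == files[2])               # distinct, suffix-indexed
  loaded <- load_raw(file.path(d, files[1]))
  expect_equal(loaded$meta$stage_position_um, c(10, 20, -1))
  expect_identical(loaded$meta$tile_index, c(1L, 2L))
  expect_identical(dim(loaded$stack$frames)[3], tiny_scan(3)$n_frames)
  # simulated acquisition time advanced by n_frames x frame period
  expect_equal(backend$vclock_s, 2 * stack_duration_s(backend$scan),
               tolerance = 1e-9)
})

test_that("the acquisition unit executes queued scripts FIFO, serially", {
  root <- tmp_dir()
  scripts <- file.path(root, "scripts"); dir.create(scripts)
  data <- file.path(root, "data"); dir.create(data)
  backend <- demo_backend(data)
  order_seen <- character(0)
  subscribe(backend$bus, "script_finished",
            function(path, status) order_seen <<- c(order_seen,
                                                    basename(path)))
  session <- scopeflow:::acquisition_session(
    watch_config(scripts, ".R", poll_interval_s = 0.01), backend)
  for (nm in c("a_first.R", "b_second.R", "c_third.R"))
    write_script(scripts, nm,
                 sprintf("api$imcontrol$run_scan('%s')",
                         sub("\\.R$", "", nm)))
  for (k in 1:4) poll_session(session)
  expect_identical(order_seen, c("a_first.R", "b_second.R", "c_third.R"))
  expect_identical(session$log$records$status, rep("ok", 3))
  expect_identical(backend$scan_count, 3L)   # file count == scan count
})

test_that("the timelapse plan drives 2x2 x N visits through the script engine", {
  root <- tmp_dir()
  data <- file.path(root, "data"); dir.create(data)
  backend <- demo_backend(data, s = 2L, sample_seed = 3L)
  plan <- plan_timelapse(plan_grid(2, 2, 16, 0), n_lapses = 3, settle_s = 1)
  plan_path <- file.path(root, "plan.json")
  write_plan(plan, plan_path)
  backend$params$plan_path <- plan_path
  backend$params$settle_s <- plan$settle_s
  api <- control_api(backend)
  script <- system.file("scripts", "timelapse.R", package = "scopeflow")
  expect_identical(run_script(script, api), "ok")
  expect_identical(backend$scan_count, 12L)
  expect_identical(length(list.files(data, pattern = "\\.zarr$")), 12L)
  # virtual clock: 12 stacks + 12 moves x 1 s settle
  expect_equal(backend$vclock_s,
               12 * stack_duration_s(backend$scan) + 12 * 1,
               tolerance = 1e-9)
  # lapse/tile indices encoded in filenames for downstream units
  expect_identical(
    sum(grepl("_t2_x1_y1_", list.files(data, pattern = "\\.zarr$"))), 1L)
})

test_that("hdf5 recording format is honored end-to-end", {
  d <- tmp_dir()
  backend <- demo_backend(d, format = "hdf5")
  api <- control_api(backend)
  api$imcontrol$set_save_format("hdf5")
  sp <- write_script(d, "one.R", "api$imcontrol$run_scan('h5demo')")
  expect_identical(run_script(sp, api), "ok")
  f <- list.files(d, pattern = "\\.h5$", full.names = TRUE)
  expect_identical(length(f), 1L)
  expect_s3_class(load_raw(f)$stack, "raw_stack")
  expect_error(api$imcontrol$set_save_format("tiff"), "unsupported")
})
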