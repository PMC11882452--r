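write_config <- function(lines) {
  f <- tempfile(fileext = ".yaml")
  writeLines(lines, f)
  f
}

test_that("configs load with defaults and reject unknown or invalid keys", {
  f <- write_config(c("model:", "  epsilon: 8", "  p_open: 0.8"))
  cfg <- load_config(f)
  expect_s3_class(cfg, "run_config")
  expect_equal(cfg$model$epsilon, 8)
  expect_equal(cfg$model$sigma, 1)       # default applied
  expect_equal(cfg$model$delta, 0.038)
  expect_equal(cfg$n_sweeps, 5e5)
  # out-of-range value names the constraint
  f2 <- write_config(c("model:", "  theta_pw: 1.2"))
  expect_error(load_config(f2), "theta_pw")
  # unknown keys are named
  f3 <- write_config(c("model:", "  epsilonn: 3"))
  expect_error(load_config(f3), "epsilonn")
  f4 <- write_config(c("foo: 1"))
  expect_error(load_config(f4), "foo")
})

test_that("save/load round trip is the identity on resolved configs", {
  f <- write_config(c("model:", "  epsilon: 7", "  n_particles: 42",
                      "schedule:", "  max_translate: 0.25",
                      "n_sweeps: 1000", "record_every: 100", "seed: 5"))
  cfg <- load_config(f)
  f2 <- tempfile(fileext = ".yaml")
  save_config(cfg, f2)
  cfg2 <- load_config(f2)
  expect_equal(unclass(cfg2$model), unclass(cfg$model))
  expect_equal(unclass(cfg2$schedule), unclass(cfg$schedule))
  expect_equal(cfg2$n_sweeps, cfg$n_sweeps)
  expect_equal(cfg2$seed, cfg$seed)
})

test_that("the CLI dispatches, validates and reports usage errors", {
  expect_equal(as.integer(patchnet_cli(character(0))), 2L)
  expect_equal(as.integer(patchnet_cli("frobnicate")), 2L)
  # missing required option
  expect_equal(as.integer(suppressMessages(patchnet_cli(c("analyze")))), 1L)
})

test_that("CLI simulate twice with one seed gives byte-identical trajectories", {
  cfgf <- write_config(c("model:", "  epsilon: 6", "  n_particles: 20",
                         "n_sweeps: 500", "record_every: 100"))
  out1 <- tempfile(fileext = ".jsonl")
  out2 <- tempfile(fileext = ".jsonl")
  s1 <- suppressMessages(patchnet_cli(c("simulate", "--config", cfgf,
                                        "--seed", "7", "--out", out1)))
  s2 <- suppressMessages(patchnet_cli(c("simulate", "--config", cfgf,
                                        "--seed", "7", "--out", out2)))
  expect_equal(as.integer(s1), 0L)
  expect_equal(as.integer(s2), 0L)
  expect_identical(readBin(out1, "raw", file.size(out1)),
                   readBin(out2, "raw", file.size(out2)))
  # resolved config and observables land next to the trajectory
  expect_true(file.exists(paste0(out1, ".config.yaml")))
  expect_true(file.exists(paste0(tools::file_path_sans_ext(out1),
                                 "_observables.csv")))
})

test_that("CLI analyze round-trips a trajectory into morphology CSV", {
  p <- model_params(epsilon = 6, n_particles = 20)
  tr <- run_mc(p, n_sweeps = 500, record_every = 100, seed = 3)
  tf <- tempfile(fileext = ".jsonl")
  write_trajectory(tr, tf)
  out <- tempfile(fileext = ".csv")
  st <- suppressMessages(patchnet_cli(c("analyze", "--traj", tf,
                                        "--out", out)))
  expect_equal(as.integer(st), 0L)
  expect_true(nrow(read.csv(out)) >= 5)
  # an empty trajectory file fails with a non-zero status
  empty <- tempfile(fileext = ".jsonl")
  writeLines(character(0), empty)
  st2 <- suppressMessages(patchnet_cli(c("analyze", "--traj", empty,
                                         "--out", out)))
  expect_equal(as.integer(st2), 1L)
})

test_that("CLI sweep --dry-run prints the grid without running", {
  cfgf <- write_config(c(
    "model:", "  epsilon: 6", "  n_particles: 20",
    "sweep:",
    "  axis1: {name: p_open, values: [0.5, 0.7]}",
    "  axis2: {name: epsilon, values: [4, 8]}",
    "  replicates: 2"))
  out <- capture.output(
    st <- suppressMessages(patchnet_cli(c("sweep", "--config", cfgf,
                                          "--dry-run"))))
  expect_equal(as.integer(st), 0L)
  expect_true(any(grepl("8 runs", out)))
})

test_that("CLI synth writes centres, truth and images", {
  dir <- tempfile()
  st <- suppressMessages(patchnet_cli(c("synth", "--preset", "gas",
                                        "--seed", "3", "--out", dir)))
  expect_equal(as.integer(st), 0L)
  expect_true(file.exists(file.path(dir, "centres.csv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  expect_true(file.exists(file.path(dir, "field.tif")))
  truth <- jsonlite::fromJSON(file.path(dir, "truth.json"))
  expect_equal(truth$preset, "gas")
})
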