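test_that("state-flip acceptance follows the intrinsic-weight Metropolis rule", {
  p <- model_params(p_open = 0.8, epsilon = 8)
  # isolated patch, closed -> open: weight ratio 4 caps at 1
  expect_equal(state_flip_acceptance(1, 0, p), 1)
  # bonded patch, closed -> open: breaking one bond costs +epsilon
  expect_equal(state_flip_acceptance(1, 8, p), 4 * exp(-8))
  # open -> closed against the weight bias
  expect_equal(state_flip_acceptance(0, 0, p), 0.25)
  # forming a bond on closing
  expect_equal(state_flip_acceptance(0, -8, p), min(1, 0.25 * exp(8)))
  # degenerate weights never divide by zero
  p0 <- model_params(p_open = 0)
  expect_equal(state_flip_acceptance(1, 0, p0), 0)
  p1 <- model_params(p_open = 1)
  expect_equal(state_flip_acceptance(0, 0, p1), 0)
})

test_that("identical seeds give byte-identical trajectory files", {
  p <- model_params(epsilon = 6, p_open = 0.5, n_particles = 30)
  s <- move_schedule()
  t1 <- run_mc(p, s, n_sweeps = 2000, record_every = 200, seed = 31)
  t2 <- run_mc(p, s, n_sweeps = 2000, record_every = 200, seed = 31)
  f1 <- tempfile(fileext = ".jsonl"); f2 <- tempfile(fileext = ".jsonl")
  write_trajectory(t1, f1)
  write_trajectory(t2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # and the reader inverts the writer
  rt <- read_trajectory(f1)
  expect_equal(length(rt$frames), length(t1$frames))
  expect_equal(rt$frames[[5]]$x, t1$frames[[5]]$x)
  expect_equal(rt$frames[[5]]$patch_states, t1$frames[[5]]$patch_states)
})

test_that("open-patch fraction at epsilon = 0 equals p_open within 3 SE", {
  for (po in c(0.2, 0.5, 0.8)) {
    p <- model_params(epsilon = 0, p_open = po, n_particles = 40)
    tr <- run_mc(p, n_sweeps = 6000, record_every = 30, seed = 100 + round(10 * po))
    fr <- vapply(tr$frames[-(1:50)], function(f) mean(f$patch_states == 0L),
                 numeric(1))
    se <- batch_se(fr)
    expect_lt(abs(mean(fr) - po), 3 * se + 1e-6)
  }
})

test_that("two-particle bonded fraction matches the quadrature oracle", {
  p <- model_params(epsilon = 6, p_open = 0.2, n_particles = 2, box_side = 5)
  expected <- oracle_bonded_fraction(p)
  tr <- run_mc(p, n_sweeps = 3e5, record_every = 60, seed = 12)
  bonded <- vapply(tr$frames[-(1:500)], function(f)
    nrow(bond_pairs(f, p)) > 0, logical(1))
  se <- batch_se(bonded)
  expect_lt(abs(mean(bonded) - expected), 3 * se)
})

test_that("cluster moves leave the two-particle equilibrium unchanged", {
  p <- model_params(epsilon = 6, p_open = 0.2, n_particles = 2, box_side = 5)
  no_cl <- move_schedule(translate = 0.45, rotate = 0.25, state_flip = 0.3,
                         cluster = 0)
  tr <- run_mc(p, no_cl, n_sweeps = 3e5, record_every = 60, seed = 13)
  bonded <- vapply(tr$frames[-(1:500)], function(f)
    nrow(bond_pairs(f, p)) > 0, logical(1))
  se <- batch_se(bonded)
  expect_lt(abs(mean(bonded) - oracle_bonded_fraction(p)), 3 * se)
})

test_that("incremental energy bookkeeping matches full recomputation", {
  p <- model_params(epsilon = 8, p_open = 0.3, n_particles = 60,
                    area_fraction = 0.15)
  tr <- run_mc(p, n_sweeps = 2e4, record_every = 500, seed = 4)
  obs <- tr$observables
  expect_lt(max(abs(obs$energy - obs$energy_recomputed)), 1e-8 * 60)
})

test_that("recorded frames never violate the hard core", {
  p <- model_params(epsilon = 8, p_open = 0.2, n_particles = 50,
                    area_fraction = 0.2)
  tr <- run_mc(p, n_sweeps = 5000, record_every = 250, seed = 6)
  for (f in tr$frames) expect_silent(total_energy(f, p))
})

test_that("strong binding aggregates particles into large clusters", {
  # always-closed patches at epsilon 8: bonded clusters past the island
  # threshold appear quickly at area fraction 0.1
  p <- model_params(epsilon = 8, p_open = 0, theta_pw = 0.44,
                    n_particles = 150, area_fraction = 0.1)
  tr <- run_mc(p, n_sweeps = 3e4, record_every = 3e4, seed = 21)
  isl <- islands(build_bond_graph(tr$frames[[1]], p))
  expect_gte(isl[[1]]$size, 24)
})

test_that("deposition inserts at the requested Poisson rate", {
  p <- model_params(epsilon = 0, p_open = 0.5, n_particles = 0, box_side = 40)
  # rate 0: count constant
  s0 <- move_schedule(deposition_rate = 0)
  cfg <- configuration(c(5, 15), c(5, 15), c(0, 0), matrix(1L, 2, 3), 40)
  tr0 <- run_mc(p, s0, init = cfg, n_sweeps = 1000, record_every = 100, seed = 3)
  expect_true(all(tr0$observables$n_particles == 2))
  # rate r over T sweeps in an empty box: final count ~ Poisson(rT)
  r <- 0.05; T_ <- 2000
  s1 <- move_schedule(deposition_rate = r)
  tr1 <- run_mc(p, s1, init = configuration(numeric(0), numeric(0), numeric(0),
                                            matrix(integer(0), 0, 3), 40),
                n_sweeps = T_, record_every = 100, seed = 8)
  final_n <- tail(tr1$observables$n_particles, 1)
  lam <- r * T_
  expect_lt(abs(final_n - lam), 4 * sqrt(lam))
})

test_that("schedule validation and calibration behave", {
  expect_error(move_schedule(translate = 0.5, rotate = 0.5, state_flip = 0.5,
                             cluster = 0), "sum to 1")
  expect_error(move_schedule(max_translate = 0), "step sizes")
  p <- model_params(epsilon = 0, n_particles = 30)
  sc <- calibrate_schedule(p, n_sweeps = 400, seed = 5)
  expect_s3_class(sc, "move_schedule")
  expect_true(sc$max_translate <= p$sigma)
})
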