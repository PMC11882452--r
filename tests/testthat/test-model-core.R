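test_that("minimum image wraps displacements into the half-open box", {
  L <- 10
  expect_equal(minimum_image(c(0.6 * L, 0), L), c(-0.4 * L, 0))
  expect_equal(minimum_image(c(0, 0), L), c(0, 0))
  expect_equal(minimum_image(c(-0.5 * L, 0.49 * L), L), c(-0.5 * L, 0.49 * L))
  # matrix form and component range
  set.seed(1)
  d <- matrix(runif(200, -3 * L, 3 * L), ncol = 2)
  w <- minimum_image(d, L)
  expect_true(all(w >= -L / 2 & w < L / 2))
})

test_that("model parameter invariants are enforced", {
  p <- model_params()
  expect_equal(p$sigma, 1)
  expect_equal(p$delta, 0.038)
  expect_equal(p$theta_pw, 0.44)
  expect_error(model_params(sigma = -1), "sigma")
  expect_error(model_params(delta = 2), "delta")
  expect_error(model_params(p_open = 1.2), "p_open")
  # theta_pw beyond the single-bond-per-patch geometric bound
  expect_error(model_params(theta_pw = 0.51), "theta_pw")
  expect_error(model_params(theta_pw = 1.2), "theta_pw")
  # derived area fraction
  p2 <- model_params(n_particles = 100, box_side = 30)
  expect_equal(p2$area_fraction, 100 * pi * 0.25 / 900)
})

test_that("model parameters round-trip through YAML", {
  p <- model_params(epsilon = 8, p_open = 0.8, n_particles = 150)
  txt <- params_to_yaml(p)
  q <- params_from_yaml(txt)
  expect_equal(unclass(q), unclass(p))
  expect_error(params_from_yaml("model:\n  epsilonn: 3\n"), "unknown key")
})

test_that("pair energy reproduces the square-well bonding rules", {
  p <- model_params(epsilon = 8, box_side = 20)
  mk <- function(x, ori, st = c(1L, 1L, 1L))
    particle(x, 10, orientation = ori, patch_states = st)
  # colinear patches, both closed, in range -> bonded at -epsilon
  a <- mk(10, 0); b <- mk(10 + 1.02, pi)
  r <- pair_energy(a, b, p)
  expect_equal(r$energy, -8)
  expect_equal(r$bond, c(1L, 1L))
  # one patch open -> no bond
  r2 <- pair_energy(a, mk(10 + 1.02, pi, st = c(0L, 1L, 1L)), p)
  expect_equal(r2$energy, 0)
  expect_null(r2$bond)
  # hard-core overlap -> sentinel
  r3 <- pair_energy(a, mk(10 + 0.99, pi), p)
  expect_true(r3$overlap)
  expect_equal(r3$energy, Inf)
  # beyond the well -> nothing
  r4 <- pair_energy(a, mk(10 + 1.05, pi), p)
  expect_equal(r4$energy, 0)
  # misaligned beyond theta_pw -> nothing
  r5 <- pair_energy(mk(10, 0.5), b, p)
  expect_equal(r5$energy, 0)
  nan_particle <- list(x = NaN, y = 10, orientation = 0,
                       patch_states = c(1L, 1L, 1L))
  expect_error(pair_energy(nan_particle, b, p), "non-finite")
})

test_that("pair energy is symmetric in its arguments", {
  p <- model_params(epsilon = 5, box_side = 15)
  set.seed(42)
  for (k in 1:50) {
    pa <- particle(runif(1, 0, 15), runif(1, 0, 15), runif(1, 0, 2 * pi),
                   sample(0:1, 3, replace = TRUE))
    pb <- particle(pa$x + runif(1, -1.5, 1.5), pa$y + runif(1, -1.5, 1.5),
                   runif(1, 0, 2 * pi), sample(0:1, 3, replace = TRUE))
    r1 <- pair_energy(pa, pb, p)
    r2 <- pair_energy(pb, pa, p)
    expect_identical(r1$energy, r2$energy)
    if (!is.null(r1$bond)) expect_identical(r1$bond, rev(r2$bond))
  }
})

test_that("total energy matches known fixtures and reports overlaps", {
  p <- model_params(epsilon = 6, box_side = 20)
  # two bonded particles
  cfg2 <- configuration(c(5, 6.02), c(5, 5), c(0, pi), matrix(1L, 2, 3), 20)
  expect_equal(total_energy(cfg2, p), -6)
  # isolated particles
  cfg0 <- configuration(c(2, 8, 14), c(2, 8, 14), c(0, 0, 0),
                        matrix(1L, 3, 3), 20)
  expect_equal(total_energy(cfg0, p), 0)
  # ideal 6-ring: 6 bonds
  ring <- hex_ring_config(p)
  expect_equal(total_energy(ring, p), -36)
  expect_equal(brute_force_energy(ring, p), -36)
  # overlap names the pair
  bad <- configuration(c(5, 5.5), c(5, 5), c(0, 0), matrix(1L, 2, 3), 20)
  expect_error(total_energy(bad, p), "overlap.*1.*2")
})

test_that("cell-list total energy equals the brute-force sum on random configurations", {
  for (k in 1:100) {
    n <- sample(5:25, 1)
    L <- runif(1, 8, 20)
    p <- model_params(epsilon = runif(1, 1, 10), n_particles = n, box_side = L,
                      theta_pw = runif(1, 0.2, 0.44))
    cfg <- random_test_config(n, L, seed = 1000 + k)
    expect_equal(total_energy(cfg, p), brute_force_energy(cfg, p),
                 tolerance = 1e-12)
  }
})

test_that("every patch holds at most one bond at the default geometry", {
  p <- model_params(epsilon = 10, p_open = 0, n_particles = 60,
                    area_fraction = 0.2)
  tr <- run_mc(p, n_sweeps = 5000, record_every = 250, seed = 9)
  for (f in tr$frames) {
    b <- bond_pairs(f, p)
    if (nrow(b) == 0) next
    keys <- c(paste(b$i, b$patch_i), paste(b$j, b$patch_j))
    expect_equal(anyDuplicated(keys), 0L)
  }
})
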