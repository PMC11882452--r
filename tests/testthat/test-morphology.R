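test_that("bond graphs from configurations and point sets match fixtures", {
  p <- model_params(epsilon = 6, box_side = 20)
  ring <- hex_ring_config(p)
  g <- build_bond_graph(ring, p)
  expect_equal(nrow(g$nodes), 6)
  expect_equal(nrow(g$edges), 6)
  expect_equal(max(g$membership), 1)
  # gas: nothing in range
  gas <- configuration(c(2, 8, 14), c(2, 8, 14), c(0, 0, 0),
                       matrix(1L, 3, 3), 20)
  g2 <- build_bond_graph(gas, p)
  expect_equal(nrow(g2$edges), 0)
  expect_equal(max(g2$membership), 3)
  # empty input is a valid empty graph
  g3 <- build_bond_graph(data.frame(x = numeric(0), y = numeric(0)))
  expect_equal(nrow(g3$nodes), 0)
})

test_that("degree-4 artefacts in point sets are pruned by longest edge", {
  # a 3-star whose hub sees a fourth, slightly more distant neighbour
  pts <- data.frame(
    x = c(0, 16, -8, -8, 16.8 * cos(pi / 3)),
    y = c(0, 0, 13.86, -13.86, 16.8 * sin(pi / 3)))
  g <- build_bond_graph(pts, cutoff = 17)
  deg <- tabulate(c(g$edges$from, g$edges$to), nbins = 5)
  expect_true(all(deg <= 3))
  # the dropped edge is the longest of the hub's original four
  expect_false(any((g$edges$from == 1 & g$edges$to == 5) |
                   (g$edges$from == 5 & g$edges$to == 1)))
})

test_that("periodic unwrapping keeps bonded components contiguous", {
  p <- model_params(epsilon = 6, box_side = 12)
  # dimer straddling the boundary
  cfg <- configuration(c(11.8, 0.82), c(6, 6), c(0, pi), matrix(1L, 2, 3), 12)
  g <- build_bond_graph(cfg, p)
  d <- sqrt(diff(g$nodes$x)^2 + diff(g$nodes$y)^2)
  expect_lt(d, 1.1)
})

test_that("face enumeration matches fixtures", {
  # triangle
  tri <- list(x = c(0, 1, 0.5), y = c(0, 0, 0.87),
              edges = data.frame(from = c(1, 2, 3), to = c(2, 3, 1)),
              size = 3L, eligible = FALSE)
  class(tri) <- "island"
  fs <- enumerate_faces(tri)
  expect_equal(fs$sizes, 3L)
  expect_true(euler_ok(tri, fs))
  # flower: 7 hexagons, the central one interior
  fl <- make_compact_island(n_rings = 2, seed = 1)
  isl <- islands(build_bond_graph(fl$points))[[1]]
  fs2 <- enumerate_faces(isl)
  expect_equal(sort(fs2$sizes), rep(6L, 7))
  expect_equal(border_ratio(isl, fs2), 6 / 7)
  expect_true(euler_ok(isl, fs2))
  # open chain: no polygons, ratio 0 by convention
  ch <- make_elongated_island(10, branch_prob = 0, seed = 2)
  isl3 <- islands(build_bond_graph(ch$points))[[1]]
  fs3 <- enumerate_faces(isl3)
  expect_equal(length(fs3$faces), 0)
  expect_equal(border_ratio(isl3, fs3), 0)
  expect_true(euler_ok(isl3, fs3))
})

test_that("face enumeration agrees with the brute-force cycle oracle on random islands", {
  n_checked <- 0
  for (s in 1:50) {
    fd <- if (s %% 2 == 0) {
      suppressWarnings(make_compact_island(
        n_particles = sample(10:28, 1),
        defect_rates = c(0.1, 0.1), seed = 300 + s))
    } else {
      make_compact_island(n_rings = 2, seed = 300 + s)
    }
    isl <- islands(build_bond_graph(fd$points))[[1]]
    if (isl$size > 30) next
    fs <- enumerate_faces(isl)
    expect_equal(sort(fs$sizes), oracle_faces(isl))
    expect_true(euler_ok(isl, fs))
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 40)
})

test_that("compact reference edge counts are exact", {
  expect_equal(compact_reference_edges(1), 0)
  expect_equal(compact_reference_edges(6), 6)   # the hexagon ring
  expect_equal(compact_reference_edges(10), 11) # two edge-fused hexagons
  expect_equal(compact_reference_edges(24), 30) # the 7-hexagon flower
  # spiral construction reproduces the exhaustive search on its shared range
  exh <- patchnet:::honeycomb_max_edges_exhaustive_cpp(12L)
  expect_equal(compact_reference_edges(1:12), exh)
  # sanity: monotone, increments of at most 2
  v <- compact_reference_edges(1:200)
  expect_true(all(diff(v) >= 1 & diff(v) <= 2))
})

test_that("network density is 1 for compact crystals and (V-1)/Emax for chains", {
  fl <- make_compact_island(n_rings = 3, seed = 1)
  isl <- islands(build_bond_graph(fl$points))[[1]]
  expect_equal(network_density(isl), 1)
  # 6-ring
  p <- model_params(box_side = 20)
  ring <- islands(build_bond_graph(hex_ring_config(p), p))[[1]]
  expect_equal(network_density(ring), 1)
  # 24-particle chain
  ch <- make_elongated_island(24, branch_prob = 0, seed = 3)
  ic <- islands(build_bond_graph(ch$points))[[1]]
  expect_equal(network_density(ic), 23 / compact_reference_edges(24))
  expect_lt(network_density(ic), 1)
})

test_that("network density is invariant under rigid motion and relabelling", {
  fd <- suppressWarnings(make_compact_island(n_particles = 30,
                                             defect_rates = c(0.1, 0.1),
                                             seed = 11))
  isl <- islands(build_bond_graph(fd$points))[[1]]
  nd0 <- network_density(isl)
  th <- 0.7
  rx <- cos(th) * fd$points$x_nm - sin(th) * fd$points$y_nm + 40
  ry <- sin(th) * fd$points$x_nm + cos(th) * fd$points$y_nm - 13
  perm <- sample(seq_along(rx))
  isl2 <- islands(build_bond_graph(data.frame(x = rx[perm], y = ry[perm])))[[1]]
  expect_equal(network_density(isl2), nd0)
})

test_that("adding a full hexagon ring strictly decreases the border ratio", {
  brs <- vapply(2:4, function(r) {
    f <- make_compact_island(n_rings = r, seed = r)
    isl <- islands(build_bond_graph(f$points))[[1]]
    border_ratio(isl)
  }, numeric(1))
  expect_true(all(diff(brs) < 0))
})

test_that("polygon distributions recover planted defect rates", {
  sizes <- integer(0)
  for (s in 1:6) {
    fd <- suppressWarnings(make_compact_island(
      n_rings = 4, defect_rates = c(0.1, 0.1), seed = 40 + s))
    pd <- polygon_distribution(fd$points)
    sizes <- c(sizes, rep(3:9, pd$counts))
  }
  non_hex <- mean(sizes != 6)
  n <- length(sizes)
  se <- sqrt(0.2 * 0.8 / n)
  expect_lt(abs(non_hex - 0.2), 3 * se + 0.02)
  # a gas frame has no polygons at all
  gas <- data.frame(x = c(0, 100, 200), y = c(0, 100, 200))
  pd0 <- polygon_distribution(gas)
  expect_true(all(pd0$counts == 0))
  expect_equal(pd0$hexagon_fraction, 0)
})

test_that("deposition growth drives the border fraction below 1 (radial growth)", {
  # continuous adsorption at strong binding: the particle density climbs,
  # islands nucleate and grow radially, and once interior polygons appear
  # the border fraction of the biggest island drops strictly below 1
  p <- model_params(epsilon = 10, p_open = 0, n_particles = 30, box_side = 25)
  s <- move_schedule(deposition_rate = 0.01)
  tr <- run_mc(p, s, n_sweeps = 3.5e4, record_every = 1750, seed = 33)
  ts <- suppressWarnings(time_series(tr))
  expect_gt(tail(ts$particle_density, 1), 2 * ts$particle_density[1])
  late_bf <- tail(ts$border_fraction_largest, 4)
  expect_true(any(late_bf > 0 & late_bf < 1))
})

test_that("morphology reports and time series summarise frames consistently", {
  fl <- make_field(n_compact = 1, n_elongated = 1, n_gas = 3, seed = 9,
                   compact_args = list(n_rings = 3))
  rep_ <- morphology_report(fl$points)
  expect_equal(rep_$summary$n_islands, nrow(fl$islands))
  expect_true(all(rep_$islands$nd >= 0 & rep_$islands$nd <= 1))
  expect_true(all(rep_$islands$border_ratio >= 0 & rep_$islands$border_ratio <= 1))
  # single compact island alone: frame ND equals that island's ND
  one <- make_field(n_compact = 1, seed = 10, compact_args = list(n_rings = 3))
  r1 <- morphology_report(one$points)
  expect_equal(r1$summary$weighted_nd, r1$islands$nd[1])
  # CSV round trip keeps island and summary rows
  f <- tempfile(fileext = ".csv")
  write_morphology(rep_, f)
  out <- read.csv(f)
  expect_equal(sum(out$row_type == "frame_summary"), 1)
  expect_equal(sum(out$row_type == "island"), nrow(rep_$islands))
  # constant trajectory gives a constant series
  p <- model_params(epsilon = 0, n_particles = 20)
  tr <- run_mc(p, move_schedule(), n_sweeps = 400, record_every = 100, seed = 2)
  ts <- time_series(tr)
  expect_equal(nrow(ts), 4)
  expect_true(all(is.finite(ts$particle_density)))
})
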