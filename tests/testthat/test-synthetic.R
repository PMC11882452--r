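test_that("the two-ring compact island is the 24-particle hexagon flower", {
  f <- make_compact_island(n_rings = 2, seed = 1)
  expect_equal(nrow(f$points), 24)
  expect_equal(nrow(f$bonds), 30)
  expect_equal(f$census$size, rep(6L, 7))
  isl <- islands(build_bond_graph(f$points))[[1]]
  expect_equal(network_density(isl), 1)
  fs <- enumerate_faces(isl)
  expect_equal(sort(fs$sizes), rep(6L, 7))
})

test_that("noiseless round trip: morphology reproduces the planted census", {
  for (s in 1:8) {
    fd <- suppressWarnings(make_compact_island(
      n_rings = sample(3:4, 1), defect_rates = c(0.1, 0.1), seed = 60 + s))
    isl <- islands(build_bond_graph(fd$points))[[1]]
    fs <- enumerate_faces(isl)
    expect_equal(sort(fs$sizes), sort(fd$census$size))
    # bond lengths within 10% of the lattice constant
    bl <- sqrt((fd$points$x_nm[fd$bonds$from] - fd$points$x_nm[fd$bonds$to])^2 +
               (fd$points$y_nm[fd$bonds$from] - fd$points$y_nm[fd$bonds$to])^2)
    expect_lt(max(abs(bl - fd$lattice_nm)), 0.1 * fd$lattice_nm)
  }
})

test_that("elongated islands are polygon-free trees with border ratio 0", {
  f <- make_elongated_island(24, branch_prob = 0, seed = 1)
  expect_equal(nrow(f$points), 24)
  expect_equal(nrow(f$bonds), 23)
  isl <- islands(build_bond_graph(f$points))[[1]]
  fs <- enumerate_faces(isl)
  expect_equal(length(fs$faces), 0)
  expect_equal(border_ratio(isl, fs), 0)
  # tree ND sits at (V-1)/Emax(V), well below a compact island
  expect_equal(network_density(isl), 23 / compact_reference_edges(24))
  # branched variant stays a tree
  fb <- make_elongated_island(40, branch_prob = 0.2, seed = 2)
  expect_equal(nrow(fb$bonds), nrow(fb$points) - 1)
  # degenerate two-particle island is valid
  f2 <- make_elongated_island(2, seed = 3)
  expect_equal(nrow(f2$points), 2)
  expect_equal(nrow(f2$bonds), 1)
})

test_that("field composition places the requested non-overlapping mixture", {
  fl <- make_field(n_compact = 3, n_elongated = 5, n_gas = 4, seed = 7)
  expect_equal(nrow(fl$islands), 12)
  expect_equal(sort(table(fl$islands$class), method = "radix"),
               sort(table(c(rep("compact", 3), rep("elongated", 5),
                            rep("gas", 4))), method = "radix"))
  rep_ <- morphology_report(fl$points)
  expect_equal(rep_$summary$n_islands, 12)
  # empty field
  f0 <- make_field(seed = 1)
  expect_equal(nrow(f0$points), 0)
  r0 <- morphology_report(f0$points)
  expect_equal(r0$summary$n_particles, 0)
  expect_equal(r0$summary$polygons_total, 0)
})

test_that("generators are seed-deterministic", {
  a <- make_compact_island(n_rings = 3, defect_rates = c(0.1, 0.1), seed = 5)
  b <- make_compact_island(n_rings = 3, defect_rates = c(0.1, 0.1), seed = 5)
  expect_identical(a$points, b$points)
  expect_identical(a$census, b$census)
  c1 <- make_field(n_compact = 1, n_elongated = 2, n_gas = 3, seed = 8)
  c2 <- make_field(n_compact = 1, n_elongated = 2, n_gas = 3, seed = 8)
  expect_identical(c1$points, c2$points)
  i1 <- rasterize(c1, seed = 4)
  i2 <- rasterize(c2, seed = 4)
  expect_identical(i1$height, i2$height)
})

test_that("rasterization geometry matches its contract", {
  fl <- make_field(n_compact = 1, seed = 2, compact_args = list(n_rings = 2))
  img <- rasterize(fl, noise_sd = 0, line_offset_sd = 0, seed = 1)
  expect_equal(img$pixel_nm, 750 / 256)
  expect_equal(dim(img$height), c(256, 256))
  # image maxima sit at monomer centres within one pixel
  for (i in seq_len(nrow(fl$points))) {
    ci <- round(fl$points$x_nm[i] / img$pixel_nm)
    ri <- round(fl$points$y_nm[i] / img$pixel_nm)
    win <- img$height[max(1, ri - 1):min(256, ri + 1),
                      max(1, ci - 1):min(256, ci + 1)]
    expect_gt(max(win), 0.97 * img$height_nm)
  }
  # background-only field is flat zero without noise
  f0 <- make_field(seed = 1)
  img0 <- rasterize(f0, noise_sd = 0, line_offset_sd = 0)
  expect_true(all(img0$height == 0))
  # with noise the background is zero-mean gaussian
  img1 <- rasterize(f0, noise_sd = 0.1, line_offset_sd = 0, seed = 3)
  expect_lt(abs(mean(img1$height)), 0.01)
  # coarse pixels warn
  expect_warning(rasterize(fl, pixels = 32), "coarser")
})

test_that("AFM images survive the TIFF round trip with metadata", {
  fl <- make_field(n_compact = 1, n_gas = 3, seed = 6)
  img <- rasterize(fl, seed = 2)
  f <- tempfile(fileext = ".tif")
  write_afm_image(img, f)
  back <- read_afm_image(f)
  expect_equal(back$pixel_nm, img$pixel_nm, tolerance = 1e-6)
  expect_equal(back$height, img$height, tolerance = 1e-5)
  # PNG preview is writable
  fp <- tempfile(fileext = ".png")
  write_afm_image(img, fp)
  expect_true(file.size(fp) > 0)
})
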