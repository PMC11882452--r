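test_that("flattening removes planted scan-line offsets", {
  fl <- make_field(n_compact = 1, n_gas = 5, seed = 3,
                   compact_args = list(n_rings = 3))
  img <- rasterize(fl, noise_sd = 0.05, line_offset_sd = 0.4, seed = 9)
  flat <- flatten_image(img, order = 0)
  # background rows: residual line offsets below 5% of the DNA height RMS
  bg <- flat$height[flat$height < 0.5]
  row_means <- apply(flat$height, 1, function(r) median(r[r < 0.5]))
  expect_lt(sd(row_means, na.rm = TRUE), 0.05 * img$height_nm)
  # an already-flat image passes through unchanged (up to the tiny
  # background median shift)
  img2 <- rasterize(fl, noise_sd = 0, line_offset_sd = 0)
  flat2 <- flatten_image(img2, order = 0)
  expect_lt(max(abs(flat2$height - img2$height)), 0.02)
  # a constant gradient is removed at order 1
  grad <- img2
  grad$height <- grad$height +
    matrix(seq(0, 1, length.out = 256), 256, 256, byrow = TRUE)
  flat3 <- flatten_image(grad, order = 1)
  bgm <- apply(flat3$height, 1, function(r) median(r[abs(r) < 0.5]))
  expect_lt(max(abs(bgm), na.rm = TRUE), 0.05 * img$height_nm)
})

test_that("segmentation covers the rendered ridges and respects overrides", {
  fl <- make_field(n_compact = 1, seed = 4, compact_args = list(n_rings = 3))
  img <- rasterize(fl, noise_sd = 0, line_offset_sd = 0)
  mask <- segment_image(img, opening_radius = 0)
  ridge <- img$height > 0.5 * img$height_nm
  expect_gte(sum(mask & ridge) / sum(ridge), 0.99)
  # manual threshold on clean data gives nearly the same mask
  mask2 <- segment_image(img, threshold_nm = 1.0, opening_radius = 0)
  expect_lt(mean(mask != mask2), 0.02)
  # a background-only image yields an empty mask
  img0 <- rasterize(make_field(seed = 1), noise_sd = 0.05, seed = 2)
  expect_warning(m0 <- segment_image(img0), "empty|contrast")
  expect_equal(sum(m0), 0)
})

test_that("centre detection finds single monomers and empty masks", {
  one <- make_field(n_gas = 1, seed = 5)
  img <- rasterize(one, noise_sd = 0, line_offset_sd = 0)
  res <- image_to_morphology(img)
  cen <- res$detection$centres
  expect_equal(nrow(cen), 1)
  expect_lt(sqrt((cen$x_nm - one$points$x_nm)^2 +
                 (cen$y_nm - one$points$y_nm)^2), img$pixel_nm)
  # empty mask gives zero centres
  det0 <- detect_centres(matrix(FALSE, 32, 32), pixel_nm = 3)
  expect_equal(nrow(det0$centres), 0)
})

test_that("rasterize-detect round trip recovers at least 95% of centres", {
  recs <- c(); precs <- c()
  for (s in 1:5) {
    fl <- make_field(n_compact = 1, n_elongated = 2, n_gas = 5, seed = 200 + s,
                     compact_args = list(n_rings = sample(2:3, 1)))
    img <- rasterize(fl, seed = 300 + s) # default noise and line offsets
    res <- image_to_morphology(img)
    sc <- detection_score(res$detection$centres, fl$points, tol_nm = 0.3 * 16)
    recs <- c(recs, sc["recall"]); precs <- c(precs, sc["precision"])
  }
  expect_gte(mean(recs), 0.95)
  expect_gte(mean(precs), 0.95)
})

test_that("the rasterized flower recovers at least 23 of its 24 centres", {
  fl <- make_field(n_compact = 1, seed = 12, compact_args = list(n_rings = 2))
  img <- rasterize(fl, seed = 13)
  res <- image_to_morphology(img)
  sc <- detection_score(res$detection$centres, fl$points, tol_nm = 0.3 * 16)
  expect_gte(sc["recall"] * 24, 23)
})

test_that("image morphology matches ground truth end to end", {
  # fields spanning compact, elongated and mixed classes
  nd_true <- c(); nd_img <- c()
  cls_true <- c(); cls_img <- c()
  for (s in 1:12) {
    kind <- s %% 3
    fl <- if (kind == 0) {
      make_field(n_compact = 2, n_gas = 4, seed = 400 + s,
                 compact_args = list(n_rings = 3,
                                     defect_rates = c(0.05, 0.05)))
    } else if (kind == 1) {
      make_field(n_elongated = 3, n_gas = 4, seed = 400 + s,
                 elongated_args = list(n_particles = 30))
    } else {
      make_field(n_compact = 1, n_elongated = 2, n_gas = 4, seed = 400 + s,
                 compact_args = list(n_rings = 3))
    }
    img <- rasterize(fl, seed = 500 + s)
    res <- image_to_morphology(img)
    tr <- morphology_report(fl$points)
    nd_true <- c(nd_true, tr$summary$weighted_nd)
    nd_img <- c(nd_img, res$report$summary$weighted_nd)
    # per-island class agreement on eligible islands, matched by size rank
    ti <- tr$islands[tr$islands$eligible, ]
    ii <- res$report$islands[res$report$islands$eligible, ]
    k <- min(nrow(ti), nrow(ii))
    if (k > 0) {
      ti2 <- ti[order(-ti$size), ][1:k, ]
      ii2 <- ii[order(-ii$size), ][1:k, ]
      cls_true <- c(cls_true, ti2$nd >= 0.75)
      cls_img <- c(cls_img, ii2$nd >= 0.75)
    }
  }
  ok <- complete.cases(nd_true, nd_img)
  expect_gte(cor(nd_true[ok], nd_img[ok], method = "spearman"), 0.9)
  expect_gte(mean(cls_true == cls_img, na.rm = TRUE), 0.9)
})

test_that("elongated rasters come back polygon-free with border ratio 0", {
  fl <- make_field(n_elongated = 1, seed = 21,
                   elongated_args = list(n_particles = 30, branch_prob = 0))
  img <- rasterize(fl, seed = 22)
  res <- image_to_morphology(img)
  expect_equal(res$report$summary$polygons_total, 0)
  expect_equal(res$report$summary$border_ratio_largest, 0)
})

test_that("pipeline errors carry the failing stage name", {
  bad <- structure(list(height = matrix(NA_real_, 8, 8), pixel_nm = 3,
                        field_nm = 24, height_nm = 2, provenance = list()),
                   class = "afm_image")
  expect_error(suppressWarnings(image_to_morphology(bad)), "stage")
})
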