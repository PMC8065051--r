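test_that("tiling discards partial border tiles and warns on tiny images", {
  img <- histology_image(matrix(0.5, 1000, 1000), 0.25)
  tiles <- tile_image(img)                # tile side = 400 px
  expect_length(tiles, 4)
  expect_true(all(vapply(tiles, function(t) all(dim(t$pixels) == 400),
                         logical(1))))
  # disjoint, axis-aligned offsets
  offs <- t(vapply(tiles, function(t) c(t$x_px, t$y_px), numeric(2)))
  expect_equal(nrow(unique(offs)), 4)
  expect_length(tile_image(histology_image(matrix(0.5, 400, 400), 0.25)), 1)
  expect_warning(
    empty <- tile_image(histology_image(matrix(0.5, 399, 400), 0.25)),
    "smaller than one")
  expect_length(empty, 0)
})

test_that("constant tiles are degenerate; stripes land in the expected bin", {
  cfg <- hog_config()
  fv <- compute_hog(matrix(0.7, 400, 400), cfg)
  expect_true(attr(fv, "degenerate"))
  expect_true(all(fv == 0))
  expect_true(tile_heterogeneity(fv)$degenerate)
  # intensity varying only along x: all gradient mass in the 0-degree bin
  p <- matrix(rep(0.5 + 0.4 * sin(2 * pi * (1:400) / 16), each = 400),
              400, 400)
  fv <- compute_hog(p, cfg)
  bins <- matrix(fv, nrow = 8)            # entries cycle through bins first
  expect_gt(sum(bins[1, ]), 0)
  expect_equal(sum(bins[2:8, ]), 0)
})

test_that("feature vector layout matches the sliding-block design", {
  fv <- compute_hog(matrix(runif(400 * 400), 400, 400))
  expect_length(fv, 19 * 19 * 4 * 8)      # 11552 for a 400-px tile
  d <- attr(fv, "dims")
  expect_equal(unname(d[c("blocks_y", "blocks_x")]), c(19, 19))
  # every block L1-normalises to at most 1 (epsilon-stabilised)
  blocks <- matrix(fv, nrow = 32)
  expect_true(all(colSums(abs(blocks)) <= 1 + 1e-9))
  expect_true(all(fv >= 0))
  # non-overlapping blocks via config
  fv2 <- compute_hog(matrix(runif(400 * 400), 400, 400),
                     hog_config(block_stride = 2))
  expect_length(fv2, 10 * 10 * 4 * 8)
})

test_that("rotating a tile by 90 degrees shifts orientation bins by 4", {
  set.seed(51)
  img <- generate_fiber_texture(fiber_texture_spec(kappa = 12, seed = 3,
                                                   size_px = 400))
  p <- img$pixels
  pr <- t(p)[, ncol(p):1]                 # 90-degree rotation
  agg <- function(fv) rowSums(matrix(fv, nrow = 8))
  a0 <- agg(compute_hog(p))
  a1 <- agg(compute_hog(pr))
  expect_equal(a1, a0[c(5:8, 1:4)], tolerance = 1e-9)
})

test_that("heterogeneity statistics follow the moment formulas", {
  fv <- c(0, 0, 0, 1)
  h <- tile_heterogeneity(fv)
  # hand computation: m2 = 3/16, m4 = 21/256, excess kurtosis = m4/m2^2 - 3
  expect_equal(h$sd, sqrt(sum((fv - 0.25)^2) / 3))
  expect_equal(h$kurtosis, (21 / 256) / (3 / 16)^2 - 3)
  expect_equal(h$kurtosis, -2 / 3, tolerance = 1e-12)
  hp <- tile_heterogeneity(fv, convention = "pearson")
  expect_equal(hp$kurtosis, h$kurtosis + 3, tolerance = 1e-12)
  # Fisher convention: standard-normal entries give kurtosis near 0
  set.seed(52)
  hn <- tile_heterogeneity(rnorm(1e5))
  expect_lt(abs(hn$kurtosis), 0.05)
  # zero-variance vector excluded
  expect_true(tile_heterogeneity(rep(0.3, 100))$degenerate)
})

test_that("identical tile and config give bit-identical features", {
  set.seed(53)
  p <- matrix(runif(400 * 400), 400, 400)
  expect_identical(compute_hog(p), compute_hog(p))
})

test_that("brightness scaling leaves per-tile kurtosis essentially unchanged", {
  img <- generate_fiber_texture(fiber_texture_spec(kappa = 8, seed = 7,
                                                   size_px = 400))
  p <- img$pixels
  k0 <- tile_heterogeneity(compute_hog(p))$kurtosis
  for (c_ in c(0.5, 0.8, 1.5, 2)) {
    kc <- tile_heterogeneity(compute_hog(c_ * p))$kurtosis
    expect_lt(abs(kc / k0 - 1), 0.01)
  }
})

test_that("ROI aggregation averages non-degenerate tiles and tissue over ROIs", {
  tt <- data.frame(roi = c("a", "a", "b", "b", "b"),
                   tissue = c("WM", "WM", "SCN", "SCN", "SCN"),
                   kurtosis = c(1, 3, 2, NA, 4),
                   sd = c(0.1, 0.3, 0.2, 0.5, 0.4),
                   degenerate = c(FALSE, FALSE, FALSE, TRUE, FALSE))
  out <- roi_heterogeneity(tt)
  expect_equal(out$roi$mean_kurtosis[out$roi$roi == "a"], 2)
  expect_equal(out$roi$mean_kurtosis[out$roi$roi == "b"], 3)
  expect_equal(out$roi$n_tiles, c(2L, 2L))
  expect_equal(out$tissue$mean_kurtosis[out$tissue$tissue == "WM"], 2)
  # single tile: ROI value equals the tile value
  one <- roi_heterogeneity(tt[1, ])
  expect_equal(one$roi$mean_kurtosis, 1)
  # all tiles degenerate -> empty flag
  expect_true(roi_heterogeneity(tt[4, ])$empty)
  # pooled mode pools tiles across the tissue class
  pooled <- roi_heterogeneity(tt, pooled = TRUE)
  expect_equal(pooled$tissue$mean_kurtosis[pooled$tissue$tissue == "SCN"],
               3)
})

test_that("coherent fiber ROIs score above random-orientation ROIs", {
  ks <- vapply(1:6, function(s) {
    co <- generate_fiber_texture(fiber_texture_spec(kappa = 32, seed = s,
                                                    size_px = 400))
    rn <- generate_fiber_texture(fiber_texture_spec(kappa = 0, seed = s,
                                                    size_px = 400))
    c(tile_heterogeneity(compute_hog(co$pixels))$kurtosis,
      tile_heterogeneity(compute_hog(rn$pixels))$kurtosis)
  }, numeric(2))
  expect_gt(mean(ks[1, ]), mean(ks[2, ]))
})
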