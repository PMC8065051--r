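test_that("tensor construction hits its directional kurtosis targets", {
  set.seed(71)
  for (rep in 1:10) {
    ax <- random_unit()
    ka <- runif(1, 0.3, 1.8); kr <- runif(1, 0.3, 2.2)
    sp <- region_spec("t", "WM", runif(1, 0.8e-3, 1.6e-3),
                      runif(1, 0.3e-3, 0.7e-3),
                      k_axial = ka, k_radial = kr, axis = ax)
    p <- build_tensors(sp)
    expect_equal(apparent_kurtosis(p$dt, p$kt, ax), ka, tolerance = 1e-9)
    perp <- dktihist:::.great_circle(ax, 8)
    for (i in 1:8)
      expect_equal(apparent_kurtosis(p$dt, p$kt, perp[i, ]), kr,
                   tolerance = 1e-9)
  }
  # isotropic spec: KFA 0
  iso <- build_tensors(region_spec("i", "GM", 1e-3, 1e-3,
                                   k_axial = 0.9, k_radial = 0.9))
  expect_lt(kfa(iso$kt), 1e-12)
})

test_that("WM-like spec round-trips through forward model and fit", {
  sch <- paper_scheme()
  sp <- region_spec("WM", "WM", 1.10e-3, 0.35e-3, k_mean = 1.17,
                    axis = c(0, 1, 0))
  p <- build_tensors(sp)
  expect_equal(mean(p$dt[1:3]), 0.60e-3, tolerance = 1e-12)
  fit <- dki_fit(forward_dki_signal(1000, p$dt, p$kt, sch), sch)
  m <- dki_metrics(fit)
  expect_equal(m$d_mean, 0.60e-3, tolerance = 1e-6)
  expect_equal(m$k_mean, 1.17, tolerance = 1e-6)
  expect_rel_equal(as.numeric(fit$kt), as.numeric(p$kt), 1e-6)
})

test_that("phantom is exact in noiseless mode and reproducible with noise", {
  sch <- paper_scheme()
  regions <- default_brain_regions(c(8, 8, 2))
  ph <- simulate_dwi_phantom(regions, sch, noise_spec("none"),
                             dims = c(8, 8, 2))
  # per-voxel signals bit-equal to the forward model
  wm <- build_tensors(regions$WM)
  expect_identical(ph$dwi[1, 1, 1, ],
                   forward_dki_signal(1000, wm$dt, wm$kt, sch))
  csf <- build_tensors(regions$CSF)
  expect_identical(ph$dwi[8, 8, 1, ],
                   forward_dki_signal(1000, csf$dt, csf$kt, sch))
  expect_equal(sort(unique(as.vector(ph$labels))), 1:4)
  # determinism under a fixed seed
  n1 <- simulate_dwi_phantom(regions, sch, noise_spec("rician", 40, 9),
                             dims = c(8, 8, 2))
  n2 <- simulate_dwi_phantom(regions, sch, noise_spec("rician", 40, 9),
                             dims = c(8, 8, 2))
  expect_identical(n1$dwi, n2$dwi)
  # overlapping or non-tiling regions are construction errors
  bad <- regions
  bad$GM$box <- bad$WM$box
  expect_error(simulate_dwi_phantom(bad, sch, dims = c(8, 8, 2)),
               "overlap")
})

test_that("Rician output converges to the noiseless signal as SNR grows", {
  sch <- paper_scheme()
  regions <- default_brain_regions(c(4, 4, 2))
  ph0 <- simulate_dwi_phantom(regions, sch, noise_spec("none"),
                              dims = c(4, 4, 2))
  mad <- vapply(c(10, 100, 1000), function(snr) {
    phn <- simulate_dwi_phantom(regions, sch, noise_spec("rician", snr, 5),
                                dims = c(4, 4, 2))
    mean(abs(phn$dwi - ph0$dwi)) / 1000
  }, numeric(1))
  expect_true(all(diff(mad) < 0))
  expect_lt(mad[3], 1e-3)
})

test_that("von Mises draws have the right concentration behaviour", {
  set.seed(72)
  img <- generate_fiber_texture(fiber_texture_spec(kappa = 32, seed = 4))
  ang <- attr(img, "orientations_deg") * pi / 180
  # circular SD of axial data via the doubled-angle resultant
  rbar <- Mod(mean(exp(2i * ang)))
  circ_sd_deg <- sqrt(-2 * log(rbar)) / 2 * 180 / pi
  expect_lt(circ_sd_deg, 12)
  # kappa = 0: orientations uniform on [0, 180)
  set.seed(73)
  u <- rvonmises(3000, mu = 1, kappa = 0) / 2
  h <- table(cut(u, breaks = seq(0, pi, length.out = 13)))
  expect_gt(chisq.test(h)$p.value, 1e-3)
  # fixed seed gives identical images
  i1 <- generate_fiber_texture(fiber_texture_spec(kappa = 8, seed = 11))
  i2 <- generate_fiber_texture(fiber_texture_spec(kappa = 8, seed = 11))
  expect_identical(i1$pixels, i2$pixels)
  expect_warning(generate_fiber_texture(fiber_texture_spec(n_fibers = 0)),
                 "zero fiber")
})

test_that("von Mises sampler matches the target density in distribution", {
  set.seed(74)
  kap <- 4
  x <- rvonmises(20000, mu = pi, kappa = kap)
  # compare binned frequencies against the analytic density
  br <- seq(0, 2 * pi, length.out = 25)
  obs <- table(cut(x, br)) / length(x)
  dens <- function(t) exp(kap * cos(t - pi)) / (2 * pi * besselI(kap, 0))
  expected <- vapply(seq_len(24), function(i)
    integrate(dens, br[i], br[i + 1])$value, numeric(1))
  expect_lt(max(abs(as.numeric(obs) - expected)), 0.012)
})
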