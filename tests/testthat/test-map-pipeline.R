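test_that("FWHM-to-sigma conversion and impulse response width are correct", {
  expect_equal(fwhm_to_sigma(3), 3 / (2 * sqrt(2 * log(2))),
               tolerance = 1e-12)
  expect_equal(fwhm_to_sigma(3), 1.27398, tolerance = 1e-5)
  # impulse response: measure the full width at half maximum on the output
  vox <- c(0.5, 0.5, 0.5)
  arr <- array(0, c(41, 41, 41)); arr[21, 21, 21] <- 1
  sm <- gaussian_smooth_3d(arr, c(3, 3, 3), vox)
  prof <- sm[, 21, 21]
  half <- max(prof) / 2
  above <- which(prof >= half)
  # linear interpolation at the half-max crossings, in mm
  lo <- min(above); hi <- max(above)
  f <- function(i1, i2) i1 + (half - prof[i1]) / (prof[i2] - prof[i1])
  width_mm <- (f(hi, hi + 1) - f(lo, lo - 1)) * vox[1]
  expect_lt(abs(width_mm - 3), 0.15)
  # approximate mass conservation away from boundaries
  expect_equal(sum(sm), 1, tolerance = 1e-6)
})

test_that("smoothing is linear, shift-equivariant and constant-preserving", {
  vox <- c(2, 2, 2)
  const <- array(4.2, c(10, 10, 6))
  expect_equal(gaussian_smooth_3d(const, c(3, 3, 3), vox), const,
               tolerance = 1e-12)
  expect_equal(median_filter_3d(const, 3), const)
  # idempotence of the median filter on constants
  expect_equal(median_filter_3d(median_filter_3d(const, 3), 3), const)
  set.seed(41)
  a <- array(rnorm(10 * 10 * 6), c(10, 10, 6))
  b <- array(rnorm(10 * 10 * 6), c(10, 10, 6))
  s <- function(x) gaussian_smooth_3d(x, c(3, 3, 3), vox)
  expect_equal(s(2 * a + 3 * b), 2 * s(a) + 3 * s(b), tolerance = 1e-10)
  # shift equivariance on interior impulses
  i1 <- array(0, c(12, 12, 12)); i1[6, 6, 6] <- 1
  i2 <- array(0, c(12, 12, 12)); i2[7, 6, 6] <- 1
  expect_equal(s(i1)[3:9, , ], s(i2)[4:10, , ], tolerance = 1e-12)
  # 4-D wrapper requires voxel dimensions
  dwi <- array(1, c(4, 4, 4, 2))
  expect_error(smooth_dwi(dwi, NULL), "voxel dimensions")
  expect_equal(smooth_dwi(dwi, vox), dwi, tolerance = 1e-12)
})

test_that("probability thresholding is strict and produces disjoint masks", {
  p_wm <- array(0, c(3, 3, 1)); p_gm <- array(0, c(3, 3, 1))
  p_csf <- array(0, c(3, 3, 1))
  p_wm[1, 1, 1] <- 0.96   # included: strictly above 0.95
  p_gm[2, 1, 1] <- 0.95   # excluded: boundary is strict
  p_csf[3, 1, 1] <- 0.951
  expect_warning(
    masks <- threshold_probability_masks(
      list(WM = p_wm, GM = p_gm, CSF = p_csf), 0.95),
    "empty mask for tissue class GM")
  expect_true(masks$WM$mask[1, 1, 1])
  expect_false(any(masks$GM$mask))
  expect_true(masks$GM$empty)
  expect_true(masks$CSF$mask[3, 1, 1])
  expect_false(any(masks$WM$mask & masks$CSF$mask))
  expect_warning(threshold_probability_masks(list(X = p_gm * 0), 0.95),
                 "empty mask")
  expect_error(threshold_probability_masks(list(X = p_wm + 10), 0.95),
               "outside")
})

test_that("ROI statistics use the n-1 convention and ignore invalid voxels", {
  v <- array(NA_real_, c(4, 1, 1))
  v[1:2, 1, 1] <- c(3, 7)
  m <- array(TRUE, c(4, 1, 1))
  st <- roi_statistics(v, m)
  expect_equal(st$mean, 5)
  expect_equal(st$sd, sd(c(3, 7)))       # sample SD, n-1 denominator
  expect_equal(st$sem, st$sd / sqrt(2))
  expect_equal(st$n_voxels, 2L)
  # constant ROI
  vc <- array(1.5, c(2, 2, 1))
  st <- roi_statistics(vc, array(TRUE, c(2, 2, 1)))
  expect_equal(st$sd, 0); expect_equal(st$sem, 0)
  # validity mask excludes voxels
  valid <- array(c(TRUE, FALSE, TRUE, TRUE), c(4, 1, 1))
  st <- roi_statistics(v, m, valid)
  expect_equal(st$mean, 3)
  # empty ROI flagged
  st <- roi_statistics(v, array(FALSE, c(4, 1, 1)))
  expect_true(st$empty)
  # permutation invariance in voxel order
  set.seed(42)
  x <- rnorm(24)
  a1 <- array(x, c(4, 3, 2))
  a2 <- array(x[sample(24)], c(4, 3, 2))
  s1 <- roi_statistics(a1, array(TRUE, c(4, 3, 2)))
  s2 <- roi_statistics(a2, array(TRUE, c(4, 3, 2)))
  expect_equal(s1$mean, s2$mean); expect_equal(s1$sd, s2$sd)
})

test_that("across-subject aggregation is unweighted with subject-count SEM", {
  tbl <- rbind(
    data.frame(subject = "S1", roi = "cc", tissue = "WM", metric = "k_mean",
               mean = 0.6, sd = 0.1, sem = 0.01, n_voxels = 100),
    data.frame(subject = "S2", roi = "cc", tissue = "WM", metric = "k_mean",
               mean = 0.6, sd = 0.1, sem = 0.01, n_voxels = 7),
    data.frame(subject = "S3", roi = "cc", tissue = "WM", metric = "k_mean",
               mean = 0.6, sd = 0.2, sem = 0.02, n_voxels = 13))
  s <- subject_summary(tbl)
  expect_equal(s$mean, 0.6)
  expect_equal(s$cv_percent, 0)        # identical subject means -> CV 0%
  expect_equal(s$n_subjects, 3L)
  tbl$mean <- c(0.5, 0.6, 0.7)
  s <- subject_summary(tbl)
  expect_equal(s$mean, 0.6)            # unweighted despite n_voxels
  expect_equal(s$sem, sd(c(0.5, 0.6, 0.7)) / sqrt(3))
  expect_equal(s$cv_percent, sd(c(0.5, 0.6, 0.7)) / 0.6 * 100)
})

test_that("volume fitting equals single-voxel fits and flags masked voxels", {
  sch <- paper_scheme()
  wm <- build_tensors(region_spec("WM", "WM", 1.10e-3, 0.35e-3, k_mean = 1.17))
  gm <- build_tensors(region_spec("GM", "GM", 1.00e-3, 0.70e-3, k_mean = 0.82))
  s_wm <- forward_dki_signal(1000, wm$dt, wm$kt, sch)
  s_gm <- forward_dki_signal(1000, gm$dt, gm$kt, sch)
  dims <- c(4, 2, 2)
  dwi <- array(0, c(dims, length(sch$bvalues)))
  for (m in seq_along(sch$bvalues)) {
    dwi[1:2, , , m] <- s_wm[m]
    dwi[3:4, , , m] <- s_gm[m]
  }
  mask <- array(TRUE, dims); mask[4, 2, 2] <- FALSE
  maps <- fit_dki_volume(dwi, sch, mask = mask)
  # homogeneity: every in-compartment voxel equals the single-voxel fit
  fit_wm <- dki_metrics(dki_fit(s_wm, sch))
  fit_gm <- dki_metrics(dki_fit(s_gm, sch))
  for (nm in c("d_mean", "fa", "k_mean", "kfa")) {
    expect_lt(max(abs(maps$metrics[[nm]][1:2, , ] - fit_wm[[nm]])),
              1e-10 * max(1, abs(fit_wm[[nm]])))
    expect_lt(max(abs(maps$metrics[[nm]][3:4, , ][-8] - fit_gm[[nm]])),
              1e-9)
  }
  # masked-out voxel is invalid in every metric
  expect_false(maps$valid[4, 2, 2])
  expect_true(all(vapply(maps$metrics,
                         function(a) is.na(a[4, 2, 2]), logical(1))))
  expect_error(fit_dki_volume(dwi[, , , 1:10], sch), "does not match")
})
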