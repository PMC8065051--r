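#' Smoothing configuration for DWI pre-processing
#'
#' @param fwhm Gaussian kernel full width at half maximum per axis (mm,
#'   length 3); the kernel standard deviation is
#'   sigma = FWHM / (2 sqrt(2 ln 2)), converted to voxel units
#' @param median_size median filter kernel side (voxels, odd, >= 1; 1
#'   disables)
#' @param gaussian,median enable flags
#' @return list of class `smoothing_config`
#' @export
smoothing_config <- function(fwhm = c(3, 3, 3), median_size = 3,
                             gaussian = TRUE, median = TRUE) {
  stopifnot(length(fwhm) == 3, all(fwhm > 0),
            median_size >= 1, median_size %% 2 == 1)
  structure(list(fwhm = fwhm, median_size = as.integer(median_size),
                 gaussian = gaussian, median = median),
            class = "smoothing_config")
}

#' Convert a Gaussian FWHM to its standard deviation
#' @param fwhm full width at half maximum (any length unit)
#' @return sigma in the same unit: fwhm / (2 sqrt(2 ln 2))
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# 1-D Gaussian convolution along one axis of a 3-D array, replicate padding
.gauss1d <- function(arr, sigma_vox, axis) {
  if (sigma_vox <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- dnorm(seq(-r, r), sd = sigma_vox)
  k <- k / sum(k)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  d <- dim(a)
  n <- d[1]
  dim(a) <- c(n, prod(d[-1]))
  out <- matrix(0, n, ncol(a))
  for (t in seq(-r, r)) {
    idx <- pmin(pmax(seq_len(n) + t, 1L), n)
    out <- out + k[t + r + 1] * a[idx, , drop = FALSE]
  }
  dim(out) <- d
  aperm(out, order(perm))
}

#' 3-D Gaussian smoothing of a scalar volume
#' @param arr 3-D array
#' @param fwhm_mm per-axis FWHM (mm, length 3)
#' @param voxdim voxel dimensions (mm, length 3)
#' @return smoothed array (separable convolution, replicate padding)
#' @export
gaussian_smooth_3d <- function(arr, fwhm_mm, voxdim) {
  stopifnot(length(voxdim) == 3, all(voxdim > 0))
  sig <- fwhm_to_sigma(fwhm_mm) / voxdim
  for (ax in 1:3) arr <- .gauss1d(arr, sig[ax], ax)
  arr
}

#' 3-D median filter (clamped borders)
#' @param arr 3-D array
#' @param size odd kernel side in voxels
#' @return filtered array
#' @export
median_filter_3d <- function(arr, size = 3) {
  stopifnot(size >= 1, size %% 2 == 1)
  if (size == 1L) return(arr)
  r <- (size - 1L) / 2L
  d <- dim(arr)
  offs <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  stack <- matrix(0, length(arr), nrow(offs))
  ix <- lapply(1:3, function(ax) seq_len(d[ax]))
  for (o in seq_len(nrow(offs))) {
    i1 <- pmin(pmax(ix[[1]] + offs$dx[o], 1L), d[1])
    i2 <- pmin(pmax(ix[[2]] + offs$dy[o], 1L), d[2])
    i3 <- pmin(pmax(ix[[3]] + offs$dz[o], 1L), d[3])
    stack[, o] <- arr[i1, i2, i3]
  }
  out <- apply(stack, 1, median)
  dim(out) <- d
  out
}

#' Smooth a 4-D DWI series measurement-by-measurement
#'
#' Applies Gaussian smoothing (sigma = FWHM/(2 sqrt(2 ln 2)) converted to
#' voxels) and a 3-D median filter to each measurement volume, the
#' pre-fitting smoothing step of the map pipeline.
#'
#' @param dwi 4-D array (x, y, z, measurement)
#' @param voxdim voxel dimensions (mm, length 3)
#' @param config a `smoothing_config`
#' @return smoothed 4-D array
#' @export
smooth_dwi <- function(dwi, voxdim, config = smoothing_config()) {
  stopifnot(length(dim(dwi)) == 4)
  if (is.null(voxdim) || any(!is.finite(voxdim)))
    stop("voxel dimensions must be known for smoothing")
  for (m in seq_len(dim(dwi)[4])) {
    v <- dwi[, , , m]
    if (config$gaussian) v <- gaussian_smooth_3d(v, config$fwhm, voxdim)
    if (config$median && config$median_size > 1L)
      v <- median_filter_3d(v, config$median_size)
    dwi[, , , m] <- v
  }
  dwi
}

#' Fit the diffusion-kurtosis model voxelwise over a volume
#'
#' Solves the shared 22-parameter linear system for every in-mask voxel at
#' once and derives the eight scalar metrics per voxel. Voxels with
#' non-positive signals, non-positive fitted mean diffusivity or a
#' non-positive-definite diffusion tensor are flagged invalid and carry NA
#' metrics (they are never silently zero-filled).
#'
#' @param dwi 4-D array (x, y, z, measurement)
#' @param scheme a `gradient_scheme`; its length must match `dim(dwi)[4]`
#' @param mask optional 3-D logical array of voxels to fit
#' @param voxdim voxel dimensions (mm, length 3)
#' @param smoothing optional `smoothing_config` applied to the DWI before
#'   fitting (NULL = no smoothing)
#' @param axis_convention passed to the metric derivations
#' @return object of class `metric_volumes`: list with `metrics` (named
#'   list of 3-D arrays, one per metric), `valid` (3-D logical), `s0`
#'   (3-D array), `voxdim`, `n_invalid`
#' @export
fit_dki_volume <- function(dwi, scheme, mask = NULL, voxdim = c(1, 1, 1),
                           smoothing = NULL,
                           axis_convention = "principal_eigenvector") {
  d <- dim(dwi)
  if (length(d) != 4) stop("dwi must be a 4-D array")
  if (d[4] != length(scheme$bvalues))
    stop("dwi measurement axis (", d[4], ") does not match scheme length (",
         length(scheme$bvalues), ")")
  if (!is.null(smoothing)) dwi <- smooth_dwi(dwi, voxdim, smoothing)
  nvox <- prod(d[1:3])
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  sel <- which(as.logical(mask))
  Y <- matrix(dwi, nvox, d[4])[sel, , drop = FALSE]
  ok <- rowSums(!is.finite(Y) | Y <= 0) == 0
  X <- .dki_design(scheme)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("rank-deficient design matrix")
  theta <- matrix(NA_real_, 22, length(sel))
  if (any(ok)) theta[, ok] <- qr.coef(qrX, t(log(Y[ok, , drop = FALSE])))
  Dmat <- t(theta[2:7, , drop = FALSE])       # nsel x 6
  Vmat <- t(theta[8:22, , drop = FALSE])      # nsel x 15 (MD^2 W)
  md <- rowMeans(Dmat[, 1:3, drop = FALSE])
  valid <- ok & is.finite(md) & md > 1e-12
  Wmat <- Vmat / md^2

  res <- matrix(NA_real_, length(sel), 8,
                dimnames = list(NULL, .metric_names))
  if (any(valid)) {
    v <- which(valid)
    lam <- matrix(NA_real_, length(sel), 3)
    e1 <- matrix(NA_real_, length(sel), 3)
    for (i in v) {
      e <- eigen(.dt6_matrix(Dmat[i, ]), symmetric = TRUE)
      lam[i, ] <- e$values
      vec <- e$vectors[, 1]
      if (vec[which.max(abs(vec))] < 0) vec <- -vec
      e1[i, ] <- vec
    }
    pd <- valid & is.finite(lam[, 3]) & lam[, 3] > 0
    valid <- pd
    v <- which(valid)
    if (length(v)) {
      lamv <- lam[v, , drop = FALSE]
      mdv <- md[v]
      res[v, "d_mean"] <- rowMeans(lamv)
      ss <- rowSums(lamv^2)
      res[v, "fa"] <- sqrt(1.5 * rowSums((lamv - mdv)^2) / ss)
      axis <- if (axis_convention == "principal_eigenvector")
        e1[v, , drop = FALSE]
      else matrix(rep(c(0, 1, 0), each = length(v)), ncol = 3)
      if (axis_convention == "principal_eigenvector") {
        res[v, "d_axial"] <- lamv[, 1]
        res[v, "d_radial"] <- rowMeans(lamv[, 2:3, drop = FALSE])
      } else {
        res[v, "d_axial"] <- rowSums(.dapp_design(axis) * Dmat[v, , drop = FALSE])
        res[v, "d_radial"] <- (3 * mdv - res[v, "d_axial"]) / 2
      }
      # spherical quadrature of K_app, vectorised across voxels
      Q <- sphere_directions(250)
      DQ <- .dapp_design(Q) %*% t(Dmat[v, , drop = FALSE])   # 250 x nv
      WQ <- .wapp_design(Q) %*% t(Wmat[v, , drop = FALSE])
      res[v, "k_mean"] <- colMeans(WQ / DQ^2) * mdv^2
      res[v, "k_axial"] <- .kapp_axis_rows(Dmat[v, , drop = FALSE],
                                           Wmat[v, , drop = FALSE], mdv, axis)
      res[v, "k_radial"] <- .kradial_rows(Dmat[v, , drop = FALSE],
                                          Wmat[v, , drop = FALSE], mdv, axis)
      w <- Wmat[v, , drop = FALSE]
      n2 <- drop(w^2 %*% .kt_mult)
      wb <- (w[, 1] + w[, 2] + w[, 3] + 2 * rowSums(w[, 10:12, drop = FALSE])) / 5
      res[v, "kfa"] <- ifelse(n2 == 0, 0, sqrt(pmax(0, n2 - 5 * wb^2) / n2))
    }
  }
  metrics <- lapply(.metric_names, function(nm) {
    a <- array(NA_real_, d[1:3]); a[sel] <- res[, nm]; a
  })
  names(metrics) <- .metric_names
  vmask <- array(FALSE, d[1:3]); vmask[sel] <- valid
  s0 <- array(NA_real_, d[1:3]); s0[sel] <- exp(theta[1, ])
  structure(list(metrics = metrics, valid = vmask, s0 = s0,
                 voxdim = voxdim, n_invalid = sum(!valid),
                 n_fitted = length(sel),
                 axis_convention = axis_convention),
            class = "metric_volumes")
}

.dt6_matrix <- function(v) {
  m <- matrix(0, 3, 3)
  m[cbind(.dt_idx[, 1], .dt_idx[, 2])] <- v
  m[cbind(.dt_idx[, 2], .dt_idx[, 1])] <- v
  m
}

# K_app along one (per-row) axis, rows of D (n x 6), W (n x 15)
.kapp_axis_rows <- function(Dmat, Wmat, md, axis) {
  dapp <- rowSums(.dapp_design(axis) * Dmat)
  wapp <- rowSums(.wapp_design(axis) * Wmat)
  md^2 / dapp^2 * wapp
}

# mean K_app over the great circle perpendicular to each row's axis
.kradial_rows <- function(Dmat, Wmat, md, axis, n_circ = 64) {
  n <- nrow(Dmat)
  ref <- matrix(rep(c(1, 0, 0), each = n), ncol = 3)
  swap <- abs(axis[, 1]) >= 0.9
  ref[swap, ] <- matrix(rep(c(0, 1, 0), each = sum(swap)), ncol = 3)
  u <- ref - rowSums(ref * axis) * axis
  u <- u / sqrt(rowSums(u^2))
  v <- cbind(axis[, 2] * u[, 3] - axis[, 3] * u[, 2],
             axis[, 3] * u[, 1] - axis[, 1] * u[, 3],
             axis[, 1] * u[, 2] - axis[, 2] * u[, 1])
  acc <- numeric(n)
  for (a in 2 * pi * (seq_len(n_circ) - 1) / n_circ) {
    dir <- cos(a) * u + sin(a) * v
    acc <- acc + .kapp_axis_rows(Dmat, Wmat, md, dir)
  }
  acc / n_circ
}

#' @export
print.metric_volumes <- function(x, ...) {
  d <- dim(x$valid)
  cat("Metric volumes ", paste(d, collapse = " x "),
      " (", x$n_fitted, " fitted voxels, ", x$n_invalid, " invalid)\n",
      sep = "")
  cat("  metrics:", paste(names(x$metrics), collapse = ", "), "\n")
  invisible(x)
}

#' Threshold tissue probability maps into masks
#'
#' A voxel enters a tissue mask when its probability strictly exceeds the
#' threshold (default 0.95). When the per-voxel probabilities sum to at
#' most 1 the resulting masks are disjoint.
#'
#' @param prob_volumes named list of 3-D probability arrays (values in
#'   \[0, 1\]), e.g. `list(WM = ..., GM = ..., CSF = ...)`
#' @param threshold inclusion threshold in (0, 1)
#' @return named list of `roi_mask` objects; empty masks trigger a warning
#'   and carry `empty = TRUE`
#' @export
threshold_probability_masks <- function(prob_volumes, threshold = 0.95) {
  stopifnot(threshold > 0, threshold < 1)
  out <- lapply(names(prob_volumes), function(nm) {
    p <- prob_volumes[[nm]]
    if (any(p < 0 | p > 1, na.rm = TRUE))
      stop("probabilities for ", nm, " fall outside [0, 1]")
    m <- !is.na(p) & p > threshold
    if (!any(m)) warning("empty mask for tissue class ", nm)
    roi_mask(m, label = nm, tissue = nm, empty = !any(m))
  })
  names(out) <- names(prob_volumes)
  out
}

#' Construct an ROI mask
#' @param mask 3-D logical array
#' @param label anatomical label
#' @param tissue tissue class, one of WM, GM, SCN, CSF (or other)
#' @param laterality optional "left"/"right"/"bilateral"
#' @param empty flag recorded by [threshold_probability_masks()]
#' @return object of class `roi_mask`
#' @export
roi_mask <- function(mask, label = "", tissue = "", laterality = "bilateral",
                     empty = !any(mask)) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3)
  structure(list(mask = mask, label = label, tissue = tissue,
                 laterality = laterality, empty = empty),
            class = "roi_mask")
}

#' Per-ROI statistics of one metric volume
#'
#' Mean, sample SD (n - 1 denominator) and SEM over the valid voxels inside
#' the ROI.
#'
#' @param volume 3-D metric array
#' @param roi an `roi_mask` (or plain logical array)
#' @param valid optional 3-D logical validity mask; invalid voxels are
#'   excluded
#' @return list with `mean`, `sd`, `sem`, `n_voxels`, `empty`
#' @export
roi_statistics <- function(volume, roi, valid = NULL) {
  m <- if (inherits(roi, "roi_mask")) roi$mask else roi
  sel <- m & !is.na(volume)
  if (!is.null(valid)) sel <- sel & valid
  x <- volume[sel]
  n <- length(x)
  if (n == 0)
    return(list(mean = NA_real_, sd = NA_real_, sem = NA_real_,
                n_voxels = 0L, empty = TRUE))
  s <- if (n > 1) sd(x) else 0
  list(mean = mean(x), sd = s, sem = s / sqrt(n), n_voxels = n,
       empty = FALSE)
}

#' ROI statistics for every metric in a fitted map set
#'
#' @param maps a `metric_volumes` object
#' @param rois named list of `roi_mask` objects
#' @param subject optional subject identifier recorded in the table
#' @return data.frame with one row per (roi, metric): subject, roi, tissue,
#'   metric, mean, sd, sem, n_voxels
#' @export
roi_stats_table <- function(maps, rois, subject = "S1") {
  rows <- list()
  for (rn in names(rois)) {
    roi <- rois[[rn]]
    for (mn in names(maps$metrics)) {
      st <- roi_statistics(maps$metrics[[mn]], roi, maps$valid)
      rows[[length(rows) + 1L]] <-
        data.frame(subject = subject, roi = rn,
                   tissue = if (inherits(roi, "roi_mask")) roi$tissue else "",
                   metric = mn, mean = st$mean, sd = st$sd, sem = st$sem,
                   n_voxels = st$n_voxels, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Across-subject regional summary
#'
#' Aggregates per-subject ROI means with an unweighted mean across subjects
#' (ROI voxel counts differ between subjects, so subjects are weighted
#' equally). SEM uses the number of subjects; the coefficient of variation
#' is SD/|mean| x 100, NA when the mean is 0.
#'
#' @param tbl a data.frame as returned by [roi_stats_table()], rows from
#'   several subjects stacked
#' @return data.frame: roi, tissue, metric, mean, sd, sem, cv_percent,
#'   n_subjects
#' @export
subject_summary <- function(tbl) {
  key <- interaction(tbl$roi, tbl$metric, drop = TRUE)
  rows <- lapply(split(tbl, key), function(g) {
    x <- g$mean[!is.na(g$mean)]
    n <- length(x)
    s <- if (n > 1) sd(x) else 0
    mu <- mean(x)
    data.frame(roi = g$roi[1], tissue = g$tissue[1], metric = g$metric[1],
               mean = mu, sd = s, sem = s / sqrt(max(n, 1)),
               cv_percent = if (isTRUE(all.equal(mu, 0))) NA_real_
                            else s / abs(mu) * 100,
               n_subjects = n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
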