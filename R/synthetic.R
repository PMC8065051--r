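#' Region specification for the synthetic DWI phantom
#'
#' Ground-truth microstructure for one phantom region: an axially
#' symmetric diffusion tensor with eigenvalues (lambda_par, lambda_perp,
#' lambda_perp) about `axis`, and a kurtosis target given either as a
#' single mean kurtosis `k_mean` (constant directional kurtosis) or as an
#' axial/radial pair (`k_axial`, `k_radial`).
#'
#' @param label region label
#' @param tissue tissue class (WM, GM, SCN, CSF)
#' @param lambda_par,lambda_perp diffusivities (mm^2/s), > 0
#' @param k_mean target mean kurtosis (constant-K construction), or NULL
#' @param k_axial,k_radial axial/radial kurtosis pair (used when `k_mean`
#'   is NULL), >= 0
#' @param axis principal axis unit 3-vector
#' @param box voxel extent `c(x0, x1, y0, y1, z0, z1)` (inclusive ranges)
#'   within the phantom grid, or NULL when used outside a phantom
#' @return list of class `region_spec`
#' @export
region_spec <- function(label, tissue, lambda_par, lambda_perp,
                        k_mean = NULL, k_axial = NULL, k_radial = NULL,
                        axis = c(1, 0, 0), box = NULL) {
  stopifnot(lambda_par > 0, lambda_perp > 0)
  axis <- axis / sqrt(sum(axis^2))
  if (is.null(k_mean)) stopifnot(k_axial >= 0, k_radial >= 0)
  else stopifnot(k_mean >= 0)
  structure(list(label = label, tissue = tissue,
                 lambda_par = lambda_par, lambda_perp = lambda_perp,
                 k_mean = k_mean, k_axial = k_axial, k_radial = k_radial,
                 axis = axis, box = box),
            class = "region_spec")
}

#' Build ground-truth tensors from a region specification
#'
#' With a `k_mean` target the kurtosis tensor is the symmetrised outer
#' product W = k/MD^2 * sym(D (x) D), which makes the directional kurtosis
#' exactly `k_mean` in every direction. With a (`k_axial`, `k_radial`)
#' pair the minimal axially symmetric tensor is built: along the axis
#' W_app = k_axial lambda_par^2 / MD^2, perpendicular to it
#' W_app = k_radial lambda_perp^2 / MD^2 (constant on the great circle),
#' and the single cross term is set to the isotropic-compatible value
#' (W1111 + W3333)/6. A closure check verifies both directional targets to
#' 1e-9.
#'
#' @param spec a `region_spec`
#' @return list with `dt` (`diffusion_tensor`) and `kt`
#'   (`kurtosis_tensor`)
#' @export
build_tensors <- function(spec) {
  lam <- c(spec$lambda_par, spec$lambda_perp, spec$lambda_perp)
  md <- mean(lam)
  R <- .rotation_to(spec$axis)
  dt <- rotate_dt(diffusion_tensor(lam[1], lam[2], lam[3]), R)
  if (!is.null(spec$k_mean)) {
    Dm <- dt_matrix(dt)
    W <- array(0, c(3, 3, 3, 3))
    for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3)
      W[i, j, k, l] <- spec$k_mean / md^2 *
        (Dm[i, j] * Dm[k, l] + Dm[i, k] * Dm[j, l] + Dm[i, l] * Dm[j, k]) / 3
    kt <- kurtosis_tensor(W)
    target_ax <- spec$k_mean; target_rad <- spec$k_mean
  } else {
    # axially symmetric about e1 before rotation
    w <- numeric(15)
    w1111 <- spec$k_axial * lam[1]^2 / md^2        # axis = x here
    wperp <- spec$k_radial * lam[2]^2 / md^2
    w[1] <- w1111            # w1111 (axis)
    w[2] <- wperp            # w2222
    w[3] <- wperp            # w3333
    w[12] <- wperp / 3       # w2233 keeps W_app constant on the circle
    w[10] <- (w[1] + w[2]) / 6   # w1122
    w[11] <- (w[1] + w[3]) / 6   # w1133
    kt <- rotate_kt(kurtosis_tensor(w), R)
    target_ax <- spec$k_axial; target_rad <- spec$k_radial
  }
  ka <- apparent_kurtosis(dt, kt, spec$axis)
  perp <- .great_circle(spec$axis, 4)[1, ]
  kr <- apparent_kurtosis(dt, kt, perp)
  if (abs(ka - target_ax) > 1e-9 || abs(kr - target_rad) > 1e-9)
    stop("tensor construction failed closure check: axial ", ka,
         " vs ", target_ax, ", radial ", kr, " vs ", target_rad)
  list(dt = dt, kt = kt)
}

# rotation taking the x axis onto a given unit vector
.rotation_to <- function(axis) {
  axis <- axis / sqrt(sum(axis^2))
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * axis) * axis
  u <- u / sqrt(sum(u^2))
  v <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  cbind(axis, u, v)
}

#' Brain-like phantom region set
#'
#' Four tissue classes at the regional values the package's worked
#' examples use throughout: WM (MD 0.60e-3 mm^2/s, K 1.17, strongly
#' anisotropic), GM (0.80e-3, 0.82, mildly anisotropic), CSF (2.07e-3,
#' 0.74, near-isotropic) and WM-like SCN (0.46e-3, 1.17). Regions are
#' axis-aligned boxes tiling the x-y plane of the grid.
#'
#' @param dims phantom grid size (voxels, length 3)
#' @return named list of `region_spec` objects covering the grid
#' @export
default_brain_regions <- function(dims = c(40, 40, 16)) {
  hx <- dims[1] %/% 2; hy <- dims[2] %/% 2
  list(
    WM = region_spec("WM", "WM", 1.10e-3, 0.35e-3, k_mean = 1.17,
                     axis = c(1, 0, 0),
                     box = c(1, hx, 1, hy, 1, dims[3])),
    GM = region_spec("GM", "GM", 1.00e-3, 0.70e-3, k_mean = 0.82,
                     axis = c(0, 1, 0),
                     box = c(hx + 1, dims[1], 1, hy, 1, dims[3])),
    SCN = region_spec("SCN", "SCN", 0.80e-3, 0.29e-3, k_mean = 1.17,
                      axis = c(0, 0, 1),
                      box = c(1, hx, hy + 1, dims[2], 1, dims[3])),
    CSF = region_spec("CSF", "CSF", 2.35e-3, 1.93e-3, k_mean = 0.74,
                      axis = c(1, 0, 0),
                      box = c(hx + 1, dims[1], hy + 1, dims[2], 1, dims[3]))
  )
}

#' Noise specification
#' @param model "none", "rician" or "gaussian"
#' @param snr signal-to-noise ratio relative to s0 (> 0 unless "none")
#' @param seed integer seed recorded in output metadata
#' @return list of class `noise_spec`
#' @export
noise_spec <- function(model = c("none", "rician", "gaussian"),
                       snr = 40, seed = 1L) {
  model <- match.arg(model)
  if (model != "none") stopifnot(snr > 0)
  structure(list(model = model, snr = snr, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Simulate a multi-region DWI phantom
#'
#' Each region's ground-truth tensors generate the noiseless forward
#' signal for every voxel in its box; optional Rician
#' (sqrt((S+e1)^2 + e2^2), e ~ N(0, (s0/SNR)^2)) or Gaussian noise is
#' added. Identical seeds give identical output.
#'
#' @param regions named list of `region_spec` objects with non-overlapping
#'   boxes tiling the grid
#' @param scheme a `gradient_scheme`
#' @param noise a `noise_spec`
#' @param dims grid size (voxels)
#' @param s0 non-diffusion-weighted signal level
#' @return list with `dwi` (4-D array), `labels` (3-D integer array),
#'   `region_names`, `truth` (per-region dt/kt and scalar ground truths),
#'   `scheme`, `noise`, `s0`
#' @export
simulate_dwi_phantom <- function(regions, scheme,
                                 noise = noise_spec("none"),
                                 dims = c(40, 40, 16), s0 = 1000) {
  nmeas <- length(scheme$bvalues)
  dwi <- array(NA_real_, c(dims, nmeas))
  labels <- array(0L, dims)
  occupied <- array(FALSE, dims)
  truth <- list()
  for (k in seq_along(regions)) {
    sp <- regions[[k]]
    b <- sp$box
    if (is.null(b)) stop("region ", sp$label, " has no box")
    xs <- b[1]:b[2]; ys <- b[3]:b[4]; zs <- b[5]:b[6]
    if (any(occupied[xs, ys, zs]))
      stop("overlapping regions at ", sp$label)
    occupied[xs, ys, zs] <- TRUE
    tn <- build_tensors(sp)
    sig <- forward_dki_signal(s0, tn$dt, tn$kt, scheme)
    for (m in seq_len(nmeas)) dwi[xs, ys, zs, m] <- sig[m]
    labels[xs, ys, zs] <- k
    dm <- diffusion_metrics(tn$dt)
    km <- kurtosis_metrics(tn$dt, tn$kt)
    truth[[names(regions)[k]]] <-
      list(dt = tn$dt, kt = tn$kt,
           d_mean = dm$d_mean, fa = dm$fa, k_mean = km$k_mean)
  }
  if (!all(occupied)) stop("regions do not tile the phantom grid")
  if (noise$model != "none") {
    set.seed(noise$seed)
    sigma <- s0 / noise$snr
    n <- length(dwi)
    if (noise$model == "rician")
      dwi <- sqrt((dwi + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
    else
      dwi <- dwi + rnorm(n, 0, sigma)
  }
  list(dwi = dwi, labels = labels, region_names = names(regions),
       truth = truth, scheme = scheme, noise = noise, s0 = s0)
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampling; kappa = 0 falls back to the uniform
#' circular distribution.
#'
#' @param n number of draws
#' @param mu mean direction (radians)
#' @param kappa concentration (>= 0)
#' @return angles in \[0, 2 pi)
#' @export
rvonmises <- function(n, mu = 0, kappa = 0) {
  stopifnot(kappa >= 0)
  if (kappa == 0) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
      i <- i + 1L
      out[i] <- (mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
    }
  }
  out
}

#' Fiber texture specification
#'
#' Parameters of the synthetic silver-stain analogue: dark fiber segments
#' on a light background, with axial orientations drawn from a von Mises
#' distribution (via the doubled-angle construction, so the orientation
#' support is \[0, 180) degrees). kappa = 0 gives uniformly random
#' orientations (the mixed-orientation tissue analogue); large kappa gives
#' coherent, parallel fibers.
#'
#' @param size_px image side (pixels)
#' @param pixel_size_um micrometres per pixel
#' @param mean_deg mean fiber orientation (degrees)
#' @param kappa von Mises concentration (>= 0)
#' @param n_fibers number of fiber segments; NULL (default) scales with
#'   image area at `fiber_density` so texture density is size-invariant
#' @param fiber_density fibers per squared pixel, used when `n_fibers` is
#'   NULL (default 600 fibers on a 512 px image)
#' @param length_px_range min/max segment length (pixels)
#' @param width_px fiber half-width (pixels)
#' @param fiber_intensity,background intensities in \[0, 1\]
#' @param noise_sd additive Gaussian noise SD
#' @param seed integer seed
#' @return list of class `fiber_texture_spec`
#' @export
fiber_texture_spec <- function(size_px = 512, pixel_size_um = 0.25,
                               mean_deg = 30, kappa = 8, n_fibers = NULL,
                               fiber_density = 600 / 512^2,
                               length_px_range = c(300, 500), width_px = 1,
                               fiber_intensity = 0.25, background = 0.9,
                               noise_sd = 0.02, seed = 1L) {
  if (is.null(n_fibers)) n_fibers <- round(fiber_density * size_px^2)
  stopifnot(kappa >= 0, size_px > 0, pixel_size_um > 0, n_fibers >= 0)
  structure(list(size_px = as.integer(size_px),
                 pixel_size_um = pixel_size_um, mean_deg = mean_deg,
                 kappa = kappa, n_fibers = as.integer(n_fibers),
                 length_px_range = length_px_range, width_px = width_px,
                 fiber_intensity = fiber_intensity,
                 background = background, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "fiber_texture_spec")
}

#' Generate a synthetic fiber-texture histology image
#'
#' Rasterises `n_fibers` dark line segments with von Mises axial
#' orientations onto a light background, adds Gaussian noise and clips to
#' \[0, 1\]. Deterministic under a fixed seed. The drawn orientation
#' angles are returned as an attribute for circular-statistics checks.
#'
#' @param spec a `fiber_texture_spec`
#' @return `histology_image` with attribute `orientations_deg`
#' @export
generate_fiber_texture <- function(spec) {
  set.seed(spec$seed)
  n <- spec$size_px
  img <- matrix(spec$background, n, n)
  if (spec$n_fibers == 0) {
    warning("zero fiber count: background-only image")
    ang <- numeric(0)
  } else {
    # axial von Mises: draw on the doubled circle, halve back
    phi <- rvonmises(spec$n_fibers, mu = 2 * spec$mean_deg * pi / 180,
                     kappa = spec$kappa)
    ang <- (phi / 2) %% pi
    len <- runif(spec$n_fibers, spec$length_px_range[1],
                 spec$length_px_range[2])
    cx <- runif(spec$n_fibers, 1, n)
    cy <- runif(spec$n_fibers, 1, n)
    for (f in seq_len(spec$n_fibers)) {
      # x = column (image x), y = row; orientation measured from x axis
      dx <- cos(ang[f]); dy <- sin(ang[f])
      t <- seq(-len[f] / 2, len[f] / 2, by = 0.5)
      for (off in seq(-spec$width_px, spec$width_px, by = 0.5)) {
        px <- round(cx[f] + t * dx - off * dy)
        py <- round(cy[f] + t * dy + off * dx)
        keep <- px >= 1 & px <= n & py >= 1 & py <= n
        img[cbind(py[keep], px[keep])] <- spec$fiber_intensity
      }
    }
  }
  if (spec$noise_sd > 0)
    img <- img + matrix(rnorm(n * n, 0, spec$noise_sd), n, n)
  img <- pmin(pmax(img, 0), 1)
  out <- histology_image(img, spec$pixel_size_um)
  attr(out, "orientations_deg") <- ang * 180 / pi
  out
}
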