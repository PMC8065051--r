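# isotropic mean of W: (1/5)(W1111 + W2222 + W3333 + 2 W1122 + 2 W1133 + 2 W2233)
.kt_mean_w <- function(kt) {
  w <- as.numeric(kt)
  (w[1] + w[2] + w[3] + 2 * (w[10] + w[11] + w[12])) / 5
}

# unique-element vector of the fully symmetric isotropic rank-4 tensor
# I4_ijkl = (d_ij d_kl + d_ik d_jl + d_il d_jk)/3
.iso4_vec <- function() {
  v <- numeric(15)
  v[1:3] <- 1
  v[10:12] <- 1 / 3
  v
}

#' Diffusion-tensor scalar metrics
#'
#' Mean, axial and radial diffusivity plus fractional anisotropy. Under the
#' `principal_eigenvector` convention the axial diffusivity is the largest
#' eigenvalue and the radial one the mean of the two smaller; under the
#' `anteroposterior` convention axial is the apparent diffusivity along the
#' y axis and radial the average over the great circle perpendicular to it.
#'
#' FA = sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||, defined as 0 for
#' the all-zero tensor.
#'
#' @param dt a `diffusion_tensor`
#' @param axis_convention "principal_eigenvector" (default) or
#'   "anteroposterior"
#' @return list with `d_mean`, `d_axial`, `d_radial`, `fa` (diffusivities in
#'   mm^2/s)
#' @export
diffusion_metrics <- function(dt,
                              axis_convention = c("principal_eigenvector",
                                                  "anteroposterior")) {
  axis_convention <- match.arg(axis_convention)
  e <- eigendecompose(dt)
  lam <- e$values
  d_mean <- mean(lam)
  ss <- sum(lam^2)
  fa <- if (ss == 0) 0 else sqrt(1.5 * sum((lam - d_mean)^2) / ss)
  if (axis_convention == "principal_eigenvector") {
    d_axial <- lam[1]
    d_radial <- mean(lam[2:3])
  } else {
    axis <- c(0, 1, 0)
    d_axial <- apparent_diffusion(dt, axis)
    circ <- .great_circle(axis, 64)
    d_radial <- mean(drop(.dapp_design(circ) %*% as.numeric(dt)))
  }
  list(d_mean = d_mean, d_axial = d_axial, d_radial = d_radial, fa = fa)
}

# n equally spaced unit directions on the great circle perpendicular to axis
.great_circle <- function(axis, n = 64) {
  axis <- axis / sqrt(sum(axis^2))
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * axis) * axis
  u <- u / sqrt(sum(u^2))
  v <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  ang <- 2 * pi * (seq_len(n) - 1) / n
  cbind(cos(ang)) %*% rbind(u) + cbind(sin(ang)) %*% rbind(v)
}

#' Kurtosis scalar metrics
#'
#' Mean kurtosis is the average of the apparent kurtosis K_app(n) over the
#' unit sphere, evaluated by numerical quadrature on the packaged
#' 250-direction near-uniform set. Axial kurtosis is K_app along the
#' reference axis (principal eigenvector by default, the y axis under the
#' anteroposterior convention); radial kurtosis averages K_app over 64
#' equally spaced directions on the perpendicular great circle.
#'
#' @param dt a `diffusion_tensor`
#' @param kt a `kurtosis_tensor`
#' @param axis_convention "principal_eigenvector" or "anteroposterior"
#' @param quadrature matrix of unit directions for the spherical average
#'   (>= 60 rows; default the packaged 250-direction set)
#' @return list with `k_mean`, `k_axial`, `k_radial` (dimensionless)
#' @export
kurtosis_metrics <- function(dt, kt,
                             axis_convention = c("principal_eigenvector",
                                                 "anteroposterior"),
                             quadrature = NULL) {
  axis_convention <- match.arg(axis_convention)
  if (is.null(quadrature)) quadrature <- sphere_directions(250)
  if (nrow(quadrature) < 60)
    stop("spherical quadrature needs at least 60 directions")
  lam <- eigendecompose(dt)
  if (min(lam$values) < 0 || mean(lam$values) <= 0)
    stop("degenerate diffusion tensor: kurtosis metrics undefined")
  k_mean <- mean(.kapp_dirs(dt, kt, quadrature))
  axis <- if (axis_convention == "principal_eigenvector")
    lam$vectors[, 1] else c(0, 1, 0)
  k_axial <- apparent_kurtosis(dt, kt, axis)
  circ <- .great_circle(axis, 64)
  k_radial <- mean(.kapp_dirs(dt, kt, circ))
  list(k_mean = k_mean, k_axial = k_axial, k_radial = k_radial)
}

#' Kurtosis fractional anisotropy
#'
#' KFA = ||W - Wbar * I4||_F / ||W||_F, where Wbar is the isotropic mean of
#' W, I4 the fully symmetric isotropic rank-4 tensor, and the Frobenius
#' norm runs over the full 81-element expansion. 0 for an isotropic kurtosis
#' tensor, 1 in the fully anisotropic limit; defined as 0 when ||W||_F = 0.
#'
#' @param kt a `kurtosis_tensor`
#' @return scalar in [0, 1]
#' @export
kfa <- function(kt) {
  w <- as.numeric(kt)
  norm2 <- sum(.kt_mult * w^2)
  if (norm2 == 0) return(0)
  wbar <- .kt_mean_w(kt)
  # ||W - wbar I4||^2 = ||W||^2 - 5 wbar^2 (since <W, I4> = 5 wbar, ||I4||^2 = 5)
  dev2 <- max(0, norm2 - 5 * wbar^2)
  sqrt(dev2 / norm2)
}

#' All eight scalar metrics from a fitted voxel
#'
#' @param fit a `dki_fit` (must be valid)
#' @param axis_convention passed to [diffusion_metrics()] and
#'   [kurtosis_metrics()]
#' @param quadrature optional quadrature direction matrix
#' @return list of class `dkti_metrics` with `d_mean`, `d_axial`,
#'   `d_radial`, `fa`, `k_mean`, `k_axial`, `k_radial`, `kfa`; diffusivities
#'   in mm^2/s
#' @export
dki_metrics <- function(fit, axis_convention = "principal_eigenvector",
                        quadrature = NULL) {
  if (!inherits(fit, "dki_fit")) stop("fit must be a dki_fit object")
  if (!fit$valid)
    return(structure(as.list(setNames(rep(NA_real_, 8),
      c("d_mean", "d_axial", "d_radial", "fa",
        "k_mean", "k_axial", "k_radial", "kfa"))), class = "dkti_metrics"))
  dm <- diffusion_metrics(fit$dt, axis_convention)
  km <- kurtosis_metrics(fit$dt, fit$kt, axis_convention, quadrature)
  structure(c(dm[c("d_mean", "d_axial", "d_radial", "fa")], km,
              list(kfa = kfa(fit$kt))), class = "dkti_metrics")
}

#' @export
print.dkti_metrics <- function(x, ...) {
  cat(sprintf("D_mean %.3f, D_axial %.3f, D_radial %.3f (x1e-3 mm^2/s)\n",
              1e3 * x$d_mean, 1e3 * x$d_axial, 1e3 * x$d_radial))
  cat(sprintf("K_mean %.3f, K_axial %.3f, K_radial %.3f, FA %.3f, KFA %.3f\n",
              x$k_mean, x$k_axial, x$k_radial, x$fa, x$kfa))
  invisible(x)
}

.metric_names <- c("d_mean", "d_axial", "d_radial", "fa",
                   "k_mean", "k_axial", "k_radial", "kfa")
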