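# Design matrix of the log-signal representation:
#   ln S(b, n) = ln s0 - b * D_app(n) + (b^2/6) * V_app(n),
# where V = MD^2 * W is estimated jointly with D and ln s0 (22 unknowns).
.dki_design <- function(scheme) {
  b <- scheme$bvalues
  N <- scheme$directions
  cbind(1, -b * .dapp_design(N), (b^2 / 6) * .wapp_design(N))
}

#' Forward diffusion-kurtosis signal
#'
#' Evaluates the two-term cumulant signal representation
#' \deqn{\ln S(b,n) = \ln s_0 - b D_{app}(n) + \tfrac{b^2}{6} MD^2 K\ldots}
#' more precisely, with W_app in place of MD^2 K_app:
#' ln S = ln s0 - b D_app(n) + (b^2/6) MD^2 W_app(n).
#'
#' @param s0 non-diffusion-weighted signal, > 0 (arbitrary units)
#' @param dt a `diffusion_tensor`
#' @param kt a `kurtosis_tensor`
#' @param scheme a `gradient_scheme`
#' @return numeric vector of signals, one per measurement; exactly `s0` at
#'   b = 0
#' @export
forward_dki_signal <- function(s0, dt, kt, scheme) {
  stopifnot(s0 > 0)
  md <- mean(dt[1:3])
  theta <- c(log(s0), as.numeric(dt), md^2 * as.numeric(kt))
  s <- drop(exp(.dki_design(scheme) %*% theta))
  s[scheme$bvalues == 0] <- s0
  s
}

#' Fit the diffusion-kurtosis model to one voxel's signals
#'
#' Ordinary linear least squares on log-signals with 22 unknowns: ln s0, the
#' 6 unique diffusion-tensor elements, and the 15 unique elements of
#' MD^2 * W. The kurtosis tensor W is recovered by dividing by the fitted
#' mean diffusivity squared. An optional constrained mode clips directional
#' kurtosis into [0, k_max] by rescaling the kurtosis tensor (the model
#' itself is always fitted unconstrained first).
#'
#' @param signals positive numeric vector, one per scheme measurement
#' @param scheme a `gradient_scheme`
#' @param constrained logical; if TRUE, post-hoc box constraints are applied
#'   to directional kurtosis over the packaged quadrature direction set
#' @param k_max upper kurtosis bound used when `constrained = TRUE`
#' @return object of class `dki_fit`: list with elements `s0`, `dt`
#'   (`diffusion_tensor`), `kt` (`kurtosis_tensor`), `md`, `residual_norm`
#'   (Euclidean norm of log-signal residuals), `valid` (FALSE when the
#'   fitted MD is non-positive, in which case `kt` and derived metrics are
#'   NA), `scheme`, and the raw coefficient vector
#' @seealso [forward_dki_signal()], [dki_metrics()]
#' @export
dki_fit <- function(signals, scheme, constrained = FALSE, k_max = 3) {
  signals <- as.numeric(signals)
  if (length(signals) != length(scheme$bvalues))
    stop("signal vector length does not match the gradient scheme")
  if (any(!is.finite(signals)) || any(signals <= 0))
    stop("all signals must be positive and finite")
  X <- .dki_design(scheme)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("gradient scheme cannot identify all 22 unknowns ",
         "(rank-deficient design matrix)")
  y <- log(signals)
  theta <- qr.coef(qrX, y)
  res <- y - drop(X %*% theta)
  s0 <- exp(theta[1])
  dt <- diffusion_tensor(theta[2:7])
  md <- mean(dt[1:3])
  # MD at or numerically indistinguishable from zero makes W unrecoverable
  valid <- is.finite(md) && md > 1e-12
  if (valid) {
    kt <- kurtosis_tensor(theta[8:22] / md^2)
    if (constrained) {
      dirs <- sphere_directions(250)
      kapp <- .kapp_dirs(dt, kt, dirs)
      # post-hoc box constraint: shrink W toward its isotropic part until
      # directional kurtosis lies in [0, k_max] over the quadrature set
      wbar <- .kt_mean_w(kt)
  iso <- kurtosis_tensor(wbar * .iso4_vec())
      f <- 1
      if (max(kapp) > 0 || min(kapp) < 0) {
        kiso <- .kapp_dirs(dt, iso, dirs)
        dev <- kapp - kiso
        f_hi <- if (max(kiso + dev) > k_max)
          max(0, min((k_max - kiso) / pmax(dev, 1e-12))) else 1
        f_lo <- if (min(kiso + dev) < 0)
          max(0, min((0 - kiso) / pmin(dev, -1e-12))) else 1
        f <- min(1, f_hi, f_lo)
      }
      kt <- kurtosis_tensor(iso + f * (as.numeric(kt) - as.numeric(iso)))
    }
  } else {
    kt <- structure(setNames(rep(NA_real_, 15), .kt_names),
                    class = "kurtosis_tensor")
  }
  structure(list(s0 = s0, dt = dt, kt = kt, md = md,
                 residual_norm = sqrt(sum(res^2)),
                 valid = valid, constrained = constrained,
                 coefficients = theta, scheme = scheme,
                 log_signals = y),
            class = "dki_fit")
}

# K_app over rows of a direction matrix (vectorised)
.kapp_dirs <- function(dt, kt, dirs) {
  dapp <- drop(.dapp_design(dirs) %*% as.numeric(dt))
  wapp <- drop(.wapp_design(dirs) %*% as.numeric(kt))
  md <- mean(dt[1:3])
  md^2 / dapp^2 * wapp
}

#' @export
print.dki_fit <- function(x, digits = 4, ...) {
  cat("Diffusion kurtosis fit (", length(x$scheme$bvalues),
      " measurements)\n", sep = "")
  cat("  s0:", signif(x$s0, digits),
      "  MD:", signif(x$md, digits), "mm^2/s",
      "  residual norm:", signif(x$residual_norm, digits), "\n")
  if (!x$valid) cat("  ** invalid voxel (fitted MD <= 0) **\n")
  invisible(x)
}

#' @export
coef.dki_fit <- function(object, ...) {
  cf <- object$coefficients
  names(cf) <- c("log_s0", .dt_names, paste0("v", substring(.kt_names, 2)))
  cf
}

#' @export
fitted.dki_fit <- function(object, ...) {
  exp(drop(.dki_design(object$scheme) %*% object$coefficients))
}

#' @export
residuals.dki_fit <- function(object, type = c("log", "signal"), ...) {
  type <- match.arg(type)
  yhat <- drop(.dki_design(object$scheme) %*% object$coefficients)
  if (type == "log") object$log_signals - yhat
  else exp(object$log_signals) - exp(yhat)
}

#' Predict signals from a fitted voxel on a (new) gradient scheme
#' @param object a `dki_fit`
#' @param scheme a `gradient_scheme`; defaults to the fitting scheme
#' @param ... unused
#' @return predicted signal vector
#' @export
predict.dki_fit <- function(object, scheme = object$scheme, ...) {
  if (!object$valid) stop("cannot predict from an invalid voxel fit")
  forward_dki_signal(object$s0, object$dt, object$kt, scheme)
}

#' Simulate noisy magnitude signals from a fitted voxel
#'
#' Draws Rician replicates of the fitted noiseless signal:
#' S' = sqrt((S + e1)^2 + e2^2), e ~ Normal(0, (s0/snr)^2).
#'
#' @param object a `dki_fit`
#' @param nsim number of replicates
#' @param seed optional integer seed
#' @param snr signal-to-noise ratio relative to s0
#' @param ... unused
#' @return matrix (measurements x nsim)
#' @export
simulate.dki_fit <- function(object, nsim = 1, seed = NULL, snr = 40, ...) {
  if (!is.null(seed)) set.seed(seed)
  s <- predict(object)
  sigma <- object$s0 / snr
  n <- length(s)
  replicate(nsim, add_rician_noise(s, sigma))
}

#' Add Rician noise to magnitude signals
#' @param s noiseless signal vector
#' @param sigma Gaussian noise SD per channel
#' @return noisy magnitude signals
#' @export
add_rician_noise <- function(s, sigma) {
  n <- length(s)
  sqrt((s + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
}

#' @export
summary.dki_fit <- function(object, ...) {
  m <- if (object$valid) dki_metrics(object) else NULL
  structure(list(fit = object, metrics = m), class = "summary.dki_fit")
}

#' @export
print.summary.dki_fit <- function(x, digits = 4, ...) {
  print(x$fit)
  if (!is.null(x$metrics)) {
    cat("Derived metrics:\n")
    m <- x$metrics
    cat(sprintf("  D_mean %.3f  D_axial %.3f  D_radial %.3f (x1e-3 mm^2/s)\n",
                1e3 * m$d_mean, 1e3 * m$d_axial, 1e3 * m$d_radial))
    cat(sprintf("  K_mean %.3f  K_axial %.3f  K_radial %.3f\n",
                m$k_mean, m$k_axial, m$k_radial))
    cat(sprintf("  FA %.3f  KFA %.3f\n", m$fa, m$kfa))
  }
  invisible(x)
}
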