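# Independent brute-force oracles and random-object generators shared by
# the test files. These deliberately avoid the package's vectorised code
# paths: sums are written out over explicit index tuples.

# apparent diffusivity by explicit double sum over all 9 index pairs
bf_dapp <- function(dt, n) {
  m <- dt_matrix(dt)
  s <- 0
  for (i in 1:3) for (j in 1:3) s <- s + n[i] * n[j] * m[i, j]
  s
}

# apparent W by explicit quadruple sum over all 81 index tuples
bf_wapp <- function(kt, n) {
  w <- kt_array(kt)
  s <- 0
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3)
    s <- s + n[i] * n[j] * n[k] * n[l] * w[i, j, k, l]
  s
}

bf_kapp <- function(dt, kt, n) {
  md <- mean(dt[1:3])
  md^2 / bf_dapp(dt, n)^2 * bf_wapp(kt, n)
}

# KFA via the full 81-element expansion and explicit Frobenius norms
bf_kfa <- function(kt) {
  w <- kt_array(kt)
  iso <- array(0, c(3, 3, 3, 3))
  d <- diag(3)
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3)
    iso[i, j, k, l] <- (d[i, j] * d[k, l] + d[i, k] * d[j, l] +
                          d[i, l] * d[j, k]) / 3
  wbar <- (w[1, 1, 1, 1] + w[2, 2, 2, 2] + w[3, 3, 3, 3] +
             2 * (w[1, 1, 2, 2] + w[1, 1, 3, 3] + w[2, 2, 3, 3])) / 5
  nw <- sqrt(sum(w^2))
  if (nw == 0) return(0)
  sqrt(sum((w - wbar * iso)^2)) / nw
}

# step-up BH by direct evaluation of the definition
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  ps <- p[o]
  for (i in seq_len(m))
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

# uniform random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

random_unit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# physically plausible diffusion tensor: eigenvalues in [0.3, 2.2] um^2/ms
random_dt <- function() {
  lam <- sort(runif(3, 0.3e-3, 2.2e-3), decreasing = TRUE)
  R <- random_rotation()
  diffusion_tensor(R %*% diag(lam) %*% t(R))
}

# physically plausible (dt, kt) pair via the axially symmetric builder,
# randomly rotated
random_dt_kt <- function() {
  sp <- region_spec("t", "WM",
                    lambda_par = runif(1, 0.8e-3, 2.0e-3),
                    lambda_perp = runif(1, 0.3e-3, 0.8e-3),
                    k_axial = runif(1, 0.4, 1.8),
                    k_radial = runif(1, 0.4, 2.2),
                    axis = random_unit())
  build_tensors(sp)
}

# arbitrary (not necessarily physical) kurtosis tensor for algebraic checks
random_kt_raw <- function(scale = 1) {
  kurtosis_tensor(rnorm(15, sd = scale))
}

paper_scheme <- function() default_scheme(c(100, 1000, 2000), 30)

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) /
                  pmax(abs(expected), 1e-4 * max(abs(expected), 1e-30))),
            tol)
}
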