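# Index bookkeeping for the symmetric rank-2 and rank-4 tensors.
# Diffusion tensor: 6 unique elements, order fixed package-wide.
.dt_names <- c("dxx", "dyy", "dzz", "dxy", "dxz", "dyz")
.dt_idx <- cbind(i = c(1L, 2L, 3L, 1L, 1L, 2L),
                 j = c(1L, 2L, 3L, 2L, 3L, 3L))

# Kurtosis tensor: 15 unique elements of a fully symmetric rank-4 tensor,
# with the multiplicity of each element in the full 3x3x3x3 expansion.
.kt_idx <- rbind(
  c(1, 1, 1, 1), c(2, 2, 2, 2), c(3, 3, 3, 3),
  c(1, 1, 1, 2), c(1, 1, 1, 3), c(1, 2, 2, 2),
  c(2, 2, 2, 3), c(1, 3, 3, 3), c(2, 3, 3, 3),
  c(1, 1, 2, 2), c(1, 1, 3, 3), c(2, 2, 3, 3),
  c(1, 1, 2, 3), c(1, 2, 2, 3), c(1, 2, 3, 3))
.kt_names <- apply(.kt_idx, 1, function(ix) paste0("w", paste(ix, collapse = "")))
.kt_mult <- c(1, 1, 1, 4, 4, 4, 4, 4, 4, 6, 6, 6, 12, 12, 12)

#' Construct a diffusion tensor from its six unique elements
#'
#' The rank-2 symmetric diffusion tensor is stored as a named numeric vector
#' of its six unique elements (units mm^2/s), in the order
#' dxx, dyy, dzz, dxy, dxz, dyz.
#'
#' @param dxx,dyy,dzz,dxy,dxz,dyz tensor elements (mm^2/s), or `dxx` may be a
#'   length-6 vector / 3x3 symmetric matrix holding all elements.
#' @return an object of class `diffusion_tensor` (named numeric, length 6).
#' @export
diffusion_tensor <- function(dxx, dyy = NULL, dzz = NULL,
                             dxy = 0, dxz = 0, dyz = 0) {
  if (is.matrix(dxx)) {
    m <- dxx
    stopifnot(all(dim(m) == c(3L, 3L)))
    if (max(abs(m - t(m))) > 1e-12 * max(1, max(abs(m))))
      stop("diffusion tensor matrix must be symmetric")
    v <- c(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[1, 3], m[2, 3])
  } else if (length(dxx) == 6L && is.null(dyy)) {
    v <- as.numeric(dxx)
  } else {
    v <- c(dxx, dyy, dzz, dxy, dxz, dyz)
  }
  stopifnot(length(v) == 6L, all(is.finite(v)))
  names(v) <- .dt_names
  structure(v, class = "diffusion_tensor")
}

#' Construct a kurtosis tensor from its fifteen unique elements
#'
#' The fully symmetric rank-4 kurtosis tensor W is stored as a named numeric
#' vector of its 15 unique elements (dimensionless), in the fixed order
#' w1111, w2222, w3333, w1112, w1113, w1222, w2223, w1333, w2333,
#' w1122, w1133, w2233, w1123, w1223, w1233.
#'
#' @param w length-15 numeric of unique elements (in the order above) or a
#'   3x3x3x3 array with full index-permutation symmetry.
#' @return an object of class `kurtosis_tensor` (named numeric, length 15).
#' @export
kurtosis_tensor <- function(w) {
  if (is.array(w) && length(dim(w)) == 4L) {
    stopifnot(all(dim(w) == 3L))
    v <- apply(.kt_idx, 1, function(ix) w[ix[1], ix[2], ix[3], ix[4]])
  } else {
    v <- as.numeric(w)
  }
  stopifnot(length(v) == 15L, all(is.finite(v)))
  names(v) <- .kt_names
  structure(v, class = "kurtosis_tensor")
}

#' @export
print.diffusion_tensor <- function(x, digits = 4, ...) {
  cat("Diffusion tensor (mm^2/s):\n")
  print(signif(dt_matrix(x), digits))
  invisible(x)
}

#' @export
print.kurtosis_tensor <- function(x, digits = 4, ...) {
  cat("Kurtosis tensor, 15 unique elements (dimensionless):\n")
  print(signif(unclass(x), digits))
  invisible(x)
}

#' 3x3 matrix form of a diffusion tensor
#' @param dt a `diffusion_tensor`
#' @return 3x3 symmetric matrix (mm^2/s)
#' @export
dt_matrix <- function(dt) {
  m <- matrix(0, 3, 3)
  m[cbind(.dt_idx[, 1], .dt_idx[, 2])] <- dt
  m[cbind(.dt_idx[, 2], .dt_idx[, 1])] <- dt
  m
}

#' Full 3x3x3x3 expansion of a kurtosis tensor
#' @param kt a `kurtosis_tensor`
#' @return 3x3x3x3 array with full permutation symmetry
#' @export
kt_array <- function(kt) {
  w <- array(0, c(3, 3, 3, 3))
  for (e in seq_len(15L)) {
    perms <- unique(.perms4(.kt_idx[e, ]))
    for (p in seq_len(nrow(perms)))
      w[perms[p, 1], perms[p, 2], perms[p, 3], perms[p, 4]] <- kt[[e]]
  }
  w
}

# all 24 index permutations of a length-4 index tuple
.perms4 <- function(ix) {
  p <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  p <- p[apply(p, 1, function(r) length(unique(r)) == 4L), ]
  matrix(ix[as.matrix(p)], ncol = 4)
}

.check_unit <- function(n, tol = 1e-6) {
  if (abs(sqrt(sum(n^2)) - 1) > tol)
    stop("direction vector must have unit Euclidean norm")
  invisible(n)
}

#' Apparent diffusion coefficient along a direction
#'
#' Projects the diffusion tensor onto a unit gradient direction:
#' D_app(n) = sum_ij n_i n_j D_ij.
#'
#' @param dt a `diffusion_tensor`
#' @param n unit 3-vector
#' @return scalar apparent diffusivity (mm^2/s)
#' @export
apparent_diffusion <- function(dt, n) {
  .check_unit(n)
  drop(crossprod(n, dt_matrix(dt) %*% n))
}

# design row mapping the 6 unique D elements to D_app(n); vectorised over
# rows of a direction matrix N
.dapp_design <- function(N) {
  if (is.null(dim(N))) N <- matrix(N, nrow = 1)
  cbind(N[, 1]^2, N[, 2]^2, N[, 3]^2,
        2 * N[, 1] * N[, 2], 2 * N[, 1] * N[, 3], 2 * N[, 2] * N[, 3])
}

# design row mapping the 15 unique W elements to W_app(n) (multiplicities in)
.wapp_design <- function(N) {
  if (is.null(dim(N))) N <- matrix(N, nrow = 1)
  out <- matrix(0, nrow(N), 15L)
  for (e in seq_len(15L)) {
    ix <- .kt_idx[e, ]
    out[, e] <- .kt_mult[e] * N[, ix[1]] * N[, ix[2]] * N[, ix[3]] * N[, ix[4]]
  }
  out
}

#' Apparent kurtosis along a direction
#'
#' K_app(n) = (MD^2 / D_app(n)^2) * W_app(n), with
#' W_app(n) = sum_ijkl n_i n_j n_k n_l W_ijkl and MD = trace(D)/3.
#'
#' @param dt a `diffusion_tensor`
#' @param kt a `kurtosis_tensor`
#' @param n unit 3-vector
#' @return scalar apparent kurtosis (dimensionless)
#' @export
apparent_kurtosis <- function(dt, kt, n) {
  .check_unit(n)
  dapp <- apparent_diffusion(dt, n)
  if (dapp <= 0) stop("degenerate tensor: D_app(n) <= 0")
  md <- mean(dt[1:3])
  wapp <- drop(.wapp_design(n) %*% as.numeric(kt))
  md^2 / dapp^2 * wapp
}

#' Eigendecomposition of a diffusion tensor
#'
#' @param dt a `diffusion_tensor`
#' @return list with `values` (descending eigenvalues) and `vectors`
#'   (orthonormal columns, sign fixed so the largest-magnitude component of
#'   each eigenvector is positive)
#' @export
eigendecompose <- function(dt) {
  e <- eigen(dt_matrix(dt), symmetric = TRUE)
  # deterministic sign convention
  for (k in 1:3) {
    v <- e$vectors[, k]
    if (v[which.max(abs(v))] < 0) e$vectors[, k] <- -v
  }
  list(values = e$values, vectors = e$vectors)
}

#' Rotate a diffusion tensor
#' @param dt a `diffusion_tensor`
#' @param R 3x3 rotation matrix
#' @return rotated `diffusion_tensor`
#' @export
rotate_dt <- function(dt, R) {
  diffusion_tensor(R %*% dt_matrix(dt) %*% t(R))
}

#' Rotate a kurtosis tensor
#' @param kt a `kurtosis_tensor`
#' @param R 3x3 rotation matrix
#' @return rotated `kurtosis_tensor`
#' @export
rotate_kt <- function(kt, R) {
  w <- kt_array(kt)
  for (mode in 1:4) w <- .mode_product(w, R, mode)
  kurtosis_tensor(w)
}

# tensor mode-m product: contracts R over mode `mode` of a 3^4 array
.mode_product <- function(w, R, mode) {
  perm <- c(mode, setdiff(1:4, mode))
  wp <- aperm(w, perm)
  dim(wp) <- c(3L, 27L)
  wp <- R %*% wp
  dim(wp) <- rep(3L, 4L)
  aperm(wp, order(perm))
}
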