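#' Diffusion gradient scheme (b-values and directions)
#'
#' A gradient scheme pairs each measurement with a b-value (s/mm^2) and a
#' unit gradient direction. b = 0 measurements may carry a zero direction.
#' Fitting the full diffusion + kurtosis representation needs at least two
#' distinct nonzero shells and at least 15 distinct nonzero-b directions.
#'
#' @param bvalues numeric vector of b-values (s/mm^2), one per measurement
#' @param directions n x 3 matrix of gradient directions (unit rows; the
#'   b = 0 rows may be zero)
#' @param validate check scheme invariants (default TRUE)
#' @return object of class `gradient_scheme`: list with `bvalues` and
#'   `directions`
#' @export
gradient_scheme <- function(bvalues, directions, validate = TRUE) {
  directions <- as.matrix(directions)
  if (ncol(directions) != 3L) stop("directions must be an n x 3 matrix")
  if (length(bvalues) != nrow(directions))
    stop("bvalues and directions disagree in length")
  sch <- structure(list(bvalues = as.numeric(bvalues),
                        directions = unname(directions)),
                   class = "gradient_scheme")
  if (validate) validate_scheme(sch)
  sch
}

#' Validate a gradient scheme's invariants
#'
#' Checks direction norms (1 within 1e-6, or 0 for b = 0 rows), b >= 0, at
#' least two distinct nonzero shells, and at least 15 distinct nonzero-b
#' directions.
#'
#' @param scheme a `gradient_scheme`
#' @return the scheme, invisibly; errors describe the offending entry
#' @export
validate_scheme <- function(scheme) {
  b <- scheme$bvalues
  nrm <- sqrt(rowSums(scheme$directions^2))
  if (any(b < 0)) stop("negative b-value at measurement ",
                       which(b < 0)[1])
  bad <- which(b > 0 & abs(nrm - 1) > 1e-6)
  if (length(bad))
    stop("non-unit gradient direction at measurement ", bad[1],
         " (norm ", format(nrm[bad[1]]), ")")
  bad0 <- which(b == 0 & nrm > 1e-6 & abs(nrm - 1) > 1e-6)
  if (length(bad0))
    stop("b = 0 direction must be zero or unit at measurement ", bad0[1])
  shells <- unique(b[b > 0])
  if (length(shells) < 2L)
    stop("scheme needs at least 2 distinct nonzero b-values, found ",
         length(shells))
  dirs <- scheme$directions[b > 0, , drop = FALSE]
  # count directions distinct up to sign
  canon <- t(apply(dirs, 1, function(v) {
    s <- sign(v[which(abs(v) > 1e-9)[1]]); round(s * v, 6)
  }))
  if (nrow(unique(canon)) < 15L)
    stop("scheme needs at least 15 distinct nonzero-b directions")
  invisible(scheme)
}

#' @export
print.gradient_scheme <- function(x, ...) {
  b <- x$bvalues
  cat("Gradient scheme:", length(b), "measurements\n")
  cat("  shells (s/mm^2):",
      paste(sort(unique(b)), collapse = ", "), "\n")
  cat("  nonzero-b directions:", sum(b > 0), "\n")
  invisible(x)
}

#' @export
length.gradient_scheme <- function(x) length(x$bvalues)

#' The acquisition scheme used throughout the package examples
#'
#' 30 gradient directions acquired at each of b = 100, 1000 and 2000 s/mm^2,
#' plus one b = 0 measurement (91 measurements). The 30 directions are a
#' fixed near-uniform subset of the packaged 250-direction sphere set.
#'
#' @param bvalues nonzero shells (s/mm^2)
#' @param n_dirs number of directions per shell
#' @return a `gradient_scheme`
#' @export
default_scheme <- function(bvalues = c(100, 1000, 2000), n_dirs = 30) {
  dirs250 <- sphere_directions(250)
  # deterministic near-uniform subset: greedy max-min angular selection
  sel <- 1L
  while (length(sel) < n_dirs) {
    cand <- setdiff(seq_len(nrow(dirs250)), sel)
    dmin <- vapply(cand, function(i) {
      min(acos(pmin(1, abs(dirs250[i, ] %*% t(dirs250[sel, , drop = FALSE])))))
    }, numeric(1))
    sel <- c(sel, cand[which.max(dmin)])
  }
  dirs <- dirs250[sel, , drop = FALSE]
  b <- c(0, rep(bvalues, each = n_dirs))
  D <- rbind(c(0, 0, 0), do.call(rbind, rep(list(dirs), length(bvalues))))
  gradient_scheme(b, D)
}

#' Read a gradient scheme from FSL-style bval/bvec text files
#'
#' The bval file holds one whitespace-separated row of b-values; the bvec
#' file holds three rows (x, y, z components), one column per measurement.
#'
#' @param bval_path,bvec_path file paths
#' @return a `gradient_scheme`
#' @export
read_bvals_bvecs <- function(bval_path, bvec_path) {
  b <- scan(bval_path, what = numeric(), quiet = TRUE)
  v <- as.matrix(read.table(bvec_path))
  if (nrow(v) != 3L)
    stop("bvec file must have exactly 3 rows, found ", nrow(v))
  if (ncol(v) != length(b))
    stop("bvec file has ", ncol(v), " columns but bval file has ",
         length(b), " values")
  gradient_scheme(b, t(v))
}

#' Write a gradient scheme to FSL-style bval/bvec text files
#' @param scheme a `gradient_scheme`
#' @param bval_path,bvec_path output paths
#' @export
write_bvals_bvecs <- function(scheme, bval_path, bvec_path) {
  cat(paste(format(scheme$bvalues, trim = TRUE), collapse = " "), "\n",
      file = bval_path, sep = "")
  m <- t(scheme$directions)
  write.table(format(m, digits = 10, trim = TRUE), bvec_path,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(scheme)
}

#' Read a gradient scheme from a JSON list of (b, direction) pairs
#' @param path JSON file: array of objects with fields `b` and `dir`
#' @return a `gradient_scheme`
#' @export
read_scheme_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  gradient_scheme(obj$b, do.call(rbind, lapply(seq_len(nrow(obj)), function(i)
    as.numeric(obj$dir[[i]]))))
}

#' Write a gradient scheme as JSON (b, direction) pairs
#' @param scheme a `gradient_scheme`
#' @param path output path
#' @export
write_scheme_json <- function(scheme, path) {
  obj <- data.frame(b = scheme$bvalues)
  obj$dir <- lapply(seq_len(nrow(obj)), function(i) scheme$directions[i, ])
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(scheme)
}

#' Packaged near-uniform unit direction sets
#'
#' Returns the fixed 250-direction electrostatic-repulsion set shipped with
#' the package (used for spherical quadrature of directional kurtosis).
#'
#' @param n currently only 250 is shipped
#' @return n x 3 matrix of unit vectors
#' @export
sphere_directions <- function(n = 250) {
  if (n != 250) stop("only the 250-direction set is shipped")
  f <- system.file("extdata", "sphere250.tsv", package = "dktihist",
                   mustWork = TRUE)
  as.matrix(read.table(f, header = TRUE))
}
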