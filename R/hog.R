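#' HOG configuration
#'
#' Defaults follow the standard tile/cell/block texture protocol: 100 um
#' square tiles, 20 px cells, 8 unsigned orientation bins over \[0, 180)
#' degrees, 2 x 2-cell blocks, L1 block normalisation with a sliding
#' one-cell stride.
#'
#' @param tile_um tile side in micrometres
#' @param cell_px cell side in pixels
#' @param bins number of orientation bins (>= 2)
#' @param block_cells block side in cells
#' @param block_stride block stride in cells (1 = sliding/overlapping,
#'   `block_cells` = non-overlapping)
#' @param epsilon L1 normalisation stabiliser
#' @return list of class `hog_config`
#' @export
hog_config <- function(tile_um = 100, cell_px = 20, bins = 8,
                       block_cells = 2, block_stride = 1,
                       epsilon = 1e-12) {
  stopifnot(tile_um > 0, cell_px >= 1, bins >= 2, block_cells >= 1,
            block_stride >= 1, block_stride <= block_cells)
  structure(list(tile_um = tile_um, cell_px = as.integer(cell_px),
                 bins = as.integer(bins),
                 block_cells = as.integer(block_cells),
                 block_stride = as.integer(block_stride),
                 epsilon = epsilon),
            class = "hog_config")
}

#' Construct a histology image object
#'
#' @param pixels 2-D matrix of grayscale intensities in \[0, 1\], or a
#'   3-D array (rows x cols x 3) of RGB converted via luminance weights
#'   0.2125/0.7154/0.0721
#' @param pixel_size_um pixel side in micrometres
#' @param label ROI label
#' @param tissue tissue class ("WM" or "SCN" in the intended use)
#' @return list of class `histology_image`
#' @export
histology_image <- function(pixels, pixel_size_um, label = "",
                            tissue = "") {
  if (length(dim(pixels)) == 3L)
    pixels <- rgb_to_gray(pixels)
  stopifnot(is.matrix(pixels), pixel_size_um > 0)
  if (min(pixels) < -1e-9 || max(pixels) > 1 + 1e-9)
    stop("intensities must lie in [0, 1]")
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 label = label, tissue = tissue),
            class = "histology_image")
}

#' RGB to grayscale luminance conversion
#' @param rgb rows x cols x 3 array in \[0, 1\]
#' @return grayscale matrix (weights 0.2125, 0.7154, 0.0721)
#' @export
rgb_to_gray <- function(rgb) {
  0.2125 * rgb[, , 1] + 0.7154 * rgb[, , 2] + 0.0721 * rgb[, , 3]
}

#' @export
print.histology_image <- function(x, ...) {
  cat("Histology image ", nrow(x$pixels), " x ", ncol(x$pixels),
      " px at ", x$pixel_size_um, " um/px",
      if (nzchar(x$label)) paste0(" [", x$label, "]"), "\n", sep = "")
  invisible(x)
}

#' Split a histology image into non-overlapping square tiles
#'
#' The tile side in pixels is round(tile_um / pixel_size); partial border
#' tiles are discarded. Each returned tile keeps its grid position.
#'
#' @param img a `histology_image`
#' @param cfg a `hog_config`
#' @return list of tiles, each a list with `pixels`, `row`, `col` (tile
#'   grid indices) and `x_px`, `y_px` (top-left pixel offsets); empty with
#'   a warning when the image is smaller than one tile
#' @export
tile_image <- function(img, cfg = hog_config()) {
  side <- as.integer(round(cfg$tile_um / img$pixel_size_um))
  p <- img$pixels
  nr <- nrow(p) %/% side
  nc <- ncol(p) %/% side
  if (nr < 1 || nc < 1) {
    warning("image (", nrow(p), " x ", ncol(p),
            " px) is smaller than one ", side, "-px tile")
    return(list())
  }
  tiles <- vector("list", nr * nc)
  k <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    k <- k + 1L
    r0 <- (i - 1L) * side
    c0 <- (j - 1L) * side
    tiles[[k]] <- list(pixels = p[r0 + seq_len(side), c0 + seq_len(side)],
                       row = i, col = j, x_px = c0, y_px = r0)
  }
  tiles
}

#' Histogram-of-oriented-gradients feature vector of one tile
#'
#' First-order gradients by central differences; unsigned orientations
#' binned over \[0, 180) degrees into `bins` bins, magnitude-weighted and
#' accumulated per cell; cell histograms contrast-normalised over
#' block-sized groups with the L1 norm and concatenated into one feature
#' vector. With the default sliding one-cell stride a 400-px tile yields
#' 19 x 19 blocks x 4 cells x 8 bins = 11552 entries.
#'
#' @param tile a tile from [tile_image()], a `histology_image`, or a plain
#'   intensity matrix whose side is a multiple of the cell size
#' @param cfg a `hog_config`
#' @return numeric feature vector with attributes `degenerate` (TRUE when
#'   every gradient is zero) and `dims` (cells/blocks layout)
#' @export
compute_hog <- function(tile, cfg = hog_config()) {
  p <- if (is.matrix(tile)) tile
       else if (inherits(tile, "histology_image")) tile$pixels
       else tile$pixels
  nr <- nrow(p); nc <- ncol(p)
  if (nr %% cfg$cell_px != 0 || nc %% cfg$cell_px != 0)
    stop("tile sides (", nr, " x ", nc,
         ") must be integer multiples of the cell size ", cfg$cell_px)
  # central differences, replicate edges (zero gradient at flat borders)
  gx <- (p[, pmin(seq_len(nc) + 1L, nc)] - p[, pmax(seq_len(nc) - 1L, 1L)]) / 2
  gy <- (p[pmin(seq_len(nr) + 1L, nr), ] - p[pmax(seq_len(nr) - 1L, 1L), ]) / 2
  mag <- sqrt(gx^2 + gy^2)
  degenerate <- all(mag == 0)
  theta <- atan2(gy, gx) * 180 / pi          # (-180, 180]
  theta <- theta %% 180                      # unsigned, [0, 180)
  bin <- pmin(floor(theta / (180 / cfg$bins)), cfg$bins - 1L)
  ncy <- nr %/% cfg$cell_px
  ncx <- nc %/% cfg$cell_px
  cell_i <- (row(p) - 1L) %/% cfg$cell_px
  cell_j <- (col(p) - 1L) %/% cfg$cell_px
  # accumulate magnitude into (cell, bin) histogram
  idx <- 1L + bin + cfg$bins * (cell_i + ncy * cell_j)
  H <- numeric(cfg$bins * ncy * ncx)
  acc <- rowsum(as.vector(mag), as.vector(idx))
  H[as.integer(rownames(acc))] <- acc
  dim(H) <- c(cfg$bins, ncy, ncx)
  bc <- cfg$block_cells
  bi <- seq(1L, ncy - bc + 1L, by = cfg$block_stride)
  bj <- seq(1L, ncx - bc + 1L, by = cfg$block_stride)
  nb <- length(bi) * length(bj)
  blk_len <- bc * bc * cfg$bins
  fv <- numeric(nb * blk_len)
  k <- 0L
  for (j in bj) for (i in bi) {
    v <- as.vector(H[, i + seq_len(bc) - 1L, j + seq_len(bc) - 1L])
    v <- v / (sum(abs(v)) + cfg$epsilon)
    fv[k + seq_len(blk_len)] <- v
    k <- k + blk_len
  }
  attr(fv, "degenerate") <- degenerate
  attr(fv, "dims") <- c(cells_y = ncy, cells_x = ncx,
                        blocks_y = length(bi), blocks_x = length(bj),
                        bins = cfg$bins)
  fv
}

#' Heterogeneity statistics of a HOG feature vector
#'
#' The tile-level heterogeneity metrics: the sample standard deviation of
#' the feature-vector entries and their kurtosis. The default kurtosis is
#' the excess (Fisher) convention m4/m2^2 - 3 computed from population
#' moments; `convention = "pearson"` drops the -3.
#'
#' @param fv feature vector from [compute_hog()]
#' @param convention "excess" (default) or "pearson"
#' @return list with `kurtosis`, `sd`, `degenerate`
#' @export
tile_heterogeneity <- function(fv, convention = c("excess", "pearson")) {
  convention <- match.arg(convention)
  deg <- isTRUE(attr(fv, "degenerate"))
  x <- as.numeric(fv)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (deg || m2 == 0)
    return(list(kurtosis = NA_real_, sd = 0, degenerate = TRUE))
  m4 <- mean((x - m)^4)
  k <- m4 / m2^2 - if (convention == "excess") 3 else 0
  list(kurtosis = k, sd = sd(x), degenerate = FALSE)
}

#' Tile-level heterogeneity for a whole histology image
#'
#' @param img a `histology_image`
#' @param cfg a `hog_config`
#' @param convention kurtosis convention, see [tile_heterogeneity()]
#' @return data.frame: tile, row, col, x_px, y_px, kurtosis, sd, degenerate
#' @export
image_heterogeneity <- function(img, cfg = hog_config(),
                                convention = "excess") {
  tiles <- tile_image(img, cfg)
  if (!length(tiles))
    return(data.frame(tile = integer(), row = integer(), col = integer(),
                      x_px = integer(), y_px = integer(),
                      kurtosis = numeric(), sd = numeric(),
                      degenerate = logical()))
  rows <- lapply(seq_along(tiles), function(k) {
    t <- tiles[[k]]
    h <- tile_heterogeneity(compute_hog(t$pixels, cfg), convention)
    data.frame(tile = k, row = t$row, col = t$col,
               x_px = t$x_px, y_px = t$y_px,
               kurtosis = h$kurtosis, sd = h$sd,
               degenerate = h$degenerate)
  })
  do.call(rbind, rows)
}

#' Aggregate tile heterogeneity to ROI and tissue level
#'
#' ROI values are unweighted means over non-degenerate tiles; tissue-class
#' values are unweighted means over member ROIs. A pooled mode concatenates
#' all member tiles instead.
#'
#' @param tile_tbl data.frame with columns `roi`, `tissue`, `kurtosis`,
#'   `sd`, `degenerate` (stack [image_heterogeneity()] outputs with roi and
#'   tissue columns added)
#' @param pooled if TRUE, tissue-class values pool tiles across ROIs
#'   rather than averaging ROI means
#' @return list with `roi` and `tissue` data.frames (mean_kurtosis,
#'   mean_sd, n_tiles)
#' @export
roi_heterogeneity <- function(tile_tbl, pooled = FALSE) {
  ok <- !tile_tbl$degenerate & !is.na(tile_tbl$kurtosis)
  tt <- tile_tbl[ok, , drop = FALSE]
  if (!nrow(tt))
    return(list(roi = NULL, tissue = NULL, empty = TRUE))
  roi <- do.call(rbind, lapply(split(tt, tt$roi), function(g)
    data.frame(roi = g$roi[1], tissue = g$tissue[1],
               mean_kurtosis = mean(g$kurtosis), mean_sd = mean(g$sd),
               n_tiles = nrow(g), stringsAsFactors = FALSE)))
  rownames(roi) <- NULL
  tissue_src <- if (pooled) tt else roi
  kcol <- if (pooled) "kurtosis" else "mean_kurtosis"
  scol <- if (pooled) "sd" else "mean_sd"
  tissue <- do.call(rbind, lapply(split(tissue_src, tissue_src$tissue),
    function(g)
      data.frame(tissue = g$tissue[1],
                 mean_kurtosis = mean(g[[kcol]]),
                 mean_sd = mean(g[[scol]]),
                 n = nrow(g), stringsAsFactors = FALSE)))
  rownames(tissue) <- NULL
  list(roi = roi, tissue = tissue, empty = FALSE)
}
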