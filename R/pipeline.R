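#' Read a NIfTI volume
#' @param path .nii or .nii.gz file
#' @return list with `data` (array), `voxdim` (mm), `affine` (4x4 or NULL)
#' @export
read_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  list(data = as.array(img),
       voxdim = pd[seq_len(min(3, length(pd)))],
       affine = structure(RNifti::xform(img), class = NULL))
}

#' Write an array as NIfTI, carrying voxel dimensions and affine through
#' @param data array (3-D or 4-D)
#' @param path output path (.nii or .nii.gz)
#' @param voxdim voxel dimensions (mm)
#' @param affine optional 4x4 affine; defaults to a scaled identity
#' @export
write_nifti <- function(data, path, voxdim = c(1, 1, 1), affine = NULL) {
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- voxdim
  if (!is.null(affine))
    img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a histology image from TIFF or PNG
#' @param path image file; RGB images are converted to grayscale luminance
#' @param pixel_size_um pixel size (um/px); when NULL, a JSON sidecar
#'   `<path>.json` with field `pixel_size_um` is required
#' @param label,tissue ROI annotations (overridden by sidecar fields when
#'   present)
#' @return a `histology_image`
#' @export
read_histology <- function(path, pixel_size_um = NULL, label = "",
                           tissue = "") {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
               tif = , tiff = tiff::readTIFF(path),
               png = png::readPNG(path),
               stop("unsupported image format: ", ext))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$pixel_size_um)) pixel_size_um <- meta$pixel_size_um
    if (!is.null(meta$label)) label <- meta$label
    if (!is.null(meta$tissue)) tissue <- meta$tissue
  }
  if (is.null(pixel_size_um))
    stop("pixel size not found: pass pixel_size_um or provide a JSON ",
         "sidecar at ", sidecar)
  if (length(dim(px)) == 3L && dim(px)[3] >= 3L)
    px <- rgb_to_gray(px[, , 1:3])
  else if (length(dim(px)) == 3L) px <- px[, , 1]
  histology_image(px, pixel_size_um, label = label, tissue = tissue)
}

#' Write a histology image as TIFF with a JSON sidecar
#' @param img a `histology_image`
#' @param path output .tif path
#' @export
write_histology <- function(img, path) {
  tiff::writeTIFF(img$pixels, path, bits.per.sample = 16L)
  jsonlite::write_json(list(pixel_size_um = img$pixel_size_um,
                            label = img$label, tissue = img$tissue),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles every stage's settings; the defaults are the package's standard
#' protocol (b = 0/100/1000/2000 s/mm^2, 30 directions, FWHM 3 mm,
#' probability threshold 0.95, 100-um tiles, 20-px cells, 8 bins, 2x2 L1
#' blocks).
#'
#' @param seed integer master seed for every random stage
#' @param dims phantom grid (voxels)
#' @param snr Rician SNR of the simulated DWI (NULL = noiseless)
#' @param n_rois number of paired regions in the end-to-end run
#' @param smoothing a `smoothing_config` or NULL
#' @param axis_convention metric axis convention
#' @param hog a `hog_config`
#' @param kurtosis_convention "excess" or "pearson"
#' @param histology_size_px side of each synthetic histology image
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(seed = 1L, dims = c(24, 24, 8), snr = 40,
                            n_rois = 8, smoothing = NULL,
                            axis_convention = "principal_eigenvector",
                            hog = hog_config(),
                            kurtosis_convention = "excess",
                            histology_size_px = 840) {
  structure(list(seed = as.integer(seed), dims = dims, snr = snr,
                 n_rois = n_rois, smoothing = smoothing,
                 axis_convention = axis_convention, hog = hog,
                 kurtosis_convention = kurtosis_convention,
                 histology_size_px = histology_size_px),
            class = "pipeline_config")
}

#' Run the full dual-modality analysis on synthetic inputs
#'
#' Builds `n_rois` paired regions spanning coherent, WM-like
#' microstructure (low diffusivity, high kurtosis, high fiber coherence)
#' to mixed, SCN-like microstructure, simulates the DWI phantom and one
#' fiber-texture histology image per region, fits the kurtosis model
#' voxelwise, summarises each ROI, computes tile heterogeneity, and
#' correlates the regional imaging metrics with the histology metrics
#' (Benjamini-Hochberg corrected). Deterministic for a fixed config.
#'
#' @param config a `pipeline_config`
#' @param outdir optional directory; when given, writes `roi_imaging.csv`,
#'   `roi_histology.csv`, `correlations.csv` and `manifest.json`
#' @return list with `roi_imaging`, `roi_histology`, `paired`,
#'   `correlations`, `maps`, `manifest`
#' @export
run_end_to_end <- function(config = pipeline_config(), outdir = NULL) {
  set.seed(config$seed)
  n <- config$n_rois
  dims <- config$dims
  stopifnot(dims[1] %% 2 == 0, n %% 2 == 0)
  # ROI grid: 2 columns x (n/2) rows of boxes tiling the volume
  nrows <- n %/% 2
  stopifnot(dims[2] %% nrows == 0)
  bx <- dims[1] %/% 2; by <- dims[2] %/% nrows
  # microstructure gradient from coherent/WM-like to mixed/SCN-like
  f <- seq(0, 1, length.out = n)
  kappas <- 32 * (1 - f) + 0.5 * f
  regions <- list()
  for (i in seq_len(n)) {
    col <- (i - 1) %% 2
    row <- (i - 1) %/% 2
    regions[[paste0("ROI", i)]] <- region_spec(
      label = paste0("ROI", i),
      tissue = if (f[i] < 0.5) "WM" else "SCN",
      lambda_par = (1.10 - 0.30 * f[i]) * 1e-3,
      lambda_perp = (0.35 - 0.06 * f[i]) * 1e-3,
      k_mean = 1.17 - 0.0 * f[i],
      axis = c(1, 0, 0),
      box = c(col * bx + 1, (col + 1) * bx,
              row * by + 1, (row + 1) * by, 1, dims[3]))
  }
  noise <- if (is.null(config$snr)) noise_spec("none")
           else noise_spec("rician", snr = config$snr,
                           seed = config$seed + 1000L)
  scheme <- default_scheme()
  ph <- simulate_dwi_phantom(regions, scheme, noise, dims = dims)
  maps <- fit_dki_volume(ph$dwi, scheme, voxdim = c(2, 2, 2),
                         smoothing = config$smoothing,
                         axis_convention = config$axis_convention)
  rois <- lapply(seq_len(n), function(i)
    roi_mask(ph$labels == i, label = paste0("ROI", i),
             tissue = regions[[i]]$tissue))
  names(rois) <- names(regions)
  roi_imaging <- roi_stats_table(maps, rois)

  tile_rows <- list()
  for (i in seq_len(n)) {
    spec <- fiber_texture_spec(size_px = config$histology_size_px,
                               kappa = kappas[i],
                               seed = config$seed + 2000L + i)
    img <- generate_fiber_texture(spec)
    het <- image_heterogeneity(img, config$hog,
                               convention = config$kurtosis_convention)
    if (nrow(het)) {
      het$roi <- paste0("ROI", i)
      het$tissue <- regions[[i]]$tissue
      tile_rows[[i]] <- het
    }
  }
  tile_tbl <- do.call(rbind, tile_rows)
  roi_histology <- roi_heterogeneity(tile_tbl)
  paired <- paired_region_table(roi_imaging, roi_histology$roi)
  correlations <- correlate_modalities(
    paired, dkti_metrics = intersect(.metric_names, names(paired)),
    histo_metrics = c("histo_kurtosis", "histo_sd"))

  manifest <- list(package_version =
                     as.character(utils::packageVersion("dktihist")),
                   seed = config$seed, dims = dims, snr = config$snr,
                   n_rois = n, kappas = kappas,
                   axis_convention = config$axis_convention,
                   kurtosis_convention = config$kurtosis_convention,
                   n_invalid_voxels = maps$n_invalid)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    .write_csv <- function(d, f)
      write.csv(d, file.path(outdir, f), row.names = FALSE)
    .write_csv(roi_imaging, "roi_imaging.csv")
    .write_csv(roi_histology$roi, "roi_histology.csv")
    .write_csv(as.data.frame(correlations), "correlations.csv")
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(roi_imaging = roi_imaging, roi_histology = roi_histology$roi,
       paired = paired, correlations = correlations, maps = maps,
       manifest = manifest)
}
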