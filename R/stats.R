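#' Pearson correlation with a two-sided p-value
#'
#' Product-moment correlation; the p-value comes from the t statistic
#' t = r sqrt((n-2)/(1-r^2)) on n-2 degrees of freedom (via
#' [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length n >= 3
#' @return list with `r`, `p`, `n`
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: zero variance in input")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: q(i) = min_{j >= i} p(j) m / j
#' on the sorted p-values, capped at 1 and mapped back to input order
#' (delegates to [stats::p.adjust()]).
#'
#' @param p p-values in \[0, 1\]
#' @return adjusted p-values, same order as input
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Cross-modality correlation of regional metrics
#'
#' Correlates every (imaging metric, histology metric) column pair of a
#' paired ROI table with Pearson's r and applies Benjamini-Hochberg
#' correction across the full family of tests run in the invocation.
#' Pairs with fewer than 3 complete rows, or with zero variance in either
#' column, are skipped (recorded in the `skipped` attribute).
#'
#' @param table data.frame keyed by ROI containing both modalities' columns
#' @param dkti_metrics names of the imaging metric columns
#' @param histo_metrics names of the histology metric columns
#' @return data.frame of class `correlation_result`: dkti_metric,
#'   histo_metric, n, r, p, p_adj; attribute `skipped` lists skipped pairs
#' @export
correlate_modalities <- function(table, dkti_metrics, histo_metrics) {
  stopifnot(all(dkti_metrics %in% names(table)),
            all(histo_metrics %in% names(table)))
  rows <- list()
  skipped <- character()
  for (dm in dkti_metrics) for (hm in histo_metrics) {
    x <- table[[dm]]; y <- table[[hm]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      skipped <- c(skipped, paste(dm, hm, sep = " ~ "))
      next
    }
    pc <- pearson_cor(x[ok], y[ok])
    rows[[length(rows) + 1L]] <-
      data.frame(dkti_metric = dm, histo_metric = hm, n = pc$n,
                 r = pc$r, p = pc$p, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(dkti_metric = character(), histo_metric = character(),
               n = integer(), r = numeric(), p = numeric())
  out$p_adj <- if (nrow(out)) bh_adjust(out$p) else numeric()
  attr(out, "skipped") <- skipped
  class(out) <- c("correlation_result", class(out))
  out
}

#' Build the paired ROI table joining imaging and histology outputs
#'
#' Joins per-ROI imaging means (long format from [roi_stats_table()] or
#' [subject_summary()]) with per-ROI histology heterogeneity on the ROI
#' label. Rows missing either modality are dropped and reported.
#'
#' @param imaging data.frame with columns roi, metric, mean
#' @param histology data.frame with columns roi, mean_kurtosis, mean_sd
#' @return wide data.frame, one row per ROI with both modalities'
#'   columns; attribute `dropped` lists ROIs without a complete pair
#' @export
paired_region_table <- function(imaging, histology) {
  wide <- reshape(imaging[, c("roi", "metric", "mean")],
                  idvar = "roi", timevar = "metric", direction = "wide")
  names(wide) <- sub("^mean\\.", "", names(wide))
  tab <- merge(wide, histology[, c("roi", "mean_kurtosis", "mean_sd")],
               by = "roi")
  names(tab)[names(tab) == "mean_kurtosis"] <- "histo_kurtosis"
  names(tab)[names(tab) == "mean_sd"] <- "histo_sd"
  dropped <- union(setdiff(wide$roi, tab$roi),
                   setdiff(histology$roi, tab$roi))
  attr(tab, "dropped") <- dropped
  tab
}
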