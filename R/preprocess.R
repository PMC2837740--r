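#' Remove genes consistently below the detection threshold
#'
#' A gene is eliminated only when its detection score falls below the
#' threshold in **every** sample ("consistently below background"); a single
#' detected sample retains the gene. Row order is preserved and the operation
#' is idempotent.
#'
#' @param em an `anro_matrix` carrying detection scores.
#' @param threshold detection score cutoff, default `0.98`.
#' @return The filtered `anro_matrix`.
#' @export
#' @examples
#' x <- matrix(c(10, 20, 30, 40), 2, 2,
#'             dimnames = list(c("A1", "B1"), c("s1", "s2")))
#' d <- matrix(c(0.5, 1, 0.6, 1), 2, 2)
#' em <- expression_matrix(x, detection = d, rna_source = "TOTAL")
#' nrow(filter_undetected(em)$intensity)  # A1 dropped: below 0.98 everywhere
filter_undetected <- function(em, threshold = 0.98) {
  stopifnot(inherits(em, "anro_matrix"))
  if (is.null(em$detection))
    stop("no detection scores present; skip the detection-filter stage ",
         "for this platform")
  keep <- apply(em$detection >= threshold, 1, any)
  em[keep, ]
}

#' Per-array Z-score normalization of log10 intensities
#'
#' Each array (column) is standardized on a stand-alone basis:
#' `z = (log10 x - mean(log10 x)) / sd(log10 x)` with the sample SD (n - 1
#' denominator), giving every column mean 0 and SD 1. Standardization is
#' invariant to per-array multiplicative scaling of the raw intensities.
#'
#' @param em an `anro_matrix` (strictly positive intensities, >= 2 genes).
#' @return Numeric matrix of z-scores, same dimnames as the input intensities.
#' @export
#' @examples
#' x <- matrix(c(10, 100, 1000), 3, 1,
#'             dimnames = list(c("A1", "B1", "C1"), "s1"))
#' ztransform_array(expression_matrix(x, rna_source = "NRO"))  # -1, 0, 1
ztransform_array <- function(em) {
  stopifnot(inherits(em, "anro_matrix"))
  lx <- log10(em$intensity)
  if (nrow(lx) < 2) stop("need at least two genes per array to standardize")
  sds <- apply(lx, 2, stats::sd)
  if (any(sds == 0))
    stop("zero within-array variance (degenerate array): ",
         paste(colnames(lx)[sds == 0], collapse = ", "))
  z <- scale(lx, center = TRUE, scale = TRUE)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  z
}

#' Per-gene log2 ratios of each timepoint to the baseline
#'
#' For every gene and timepoint, `log2(mean raw intensity at t / mean raw
#' intensity at baseline)`, the "log-ratio relative to time 0" scale used by
#' all time-course displays and by gene-set enrichment. The baseline column
#' is exactly zero.
#'
#' @param em an `anro_matrix`.
#' @param annotation a [sample_annotation()] covering the matrix samples.
#' @param baseline_timepoint baseline hours, default 0.
#' @param timepoints which timepoints to report; default all in annotation.
#' @return Numeric matrix, genes x timepoints, columns named by hours.
#' @export
log_ratio <- function(em, annotation, baseline_timepoint = 0,
                      timepoints = NULL) {
  stopifnot(inherits(em, "anro_matrix"))
  ann <- match_samples(em, annotation)
  if (is.null(timepoints)) timepoints <- sort(unique(ann$timepoint_hr))
  if (!baseline_timepoint %in% ann$timepoint_hr)
    stop("baseline timepoint ", baseline_timepoint, " absent from annotation")
  missing_tp <- setdiff(timepoints, ann$timepoint_hr)
  if (length(missing_tp))
    stop("timepoints absent from annotation: ",
         paste(missing_tp, collapse = ", "))
  base_mean <- rowMeans(
    em$intensity[, ann$timepoint_hr == baseline_timepoint, drop = FALSE])
  out <- vapply(timepoints, function(tp) {
    log2(rowMeans(em$intensity[, ann$timepoint_hr == tp, drop = FALSE]) /
           base_mean)
  }, numeric(nrow(em$intensity)))
  out <- matrix(out, nrow = nrow(em$intensity),
                dimnames = list(rownames(em$intensity), timepoints))
  out
}
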