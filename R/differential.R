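#' Z-ratio statistic between two groups of arrays
#'
#' The per-gene difference of replicate-averaged z-scores, divided by the
#' sample SD of all per-gene differences in the comparison. The division
#' self-normalizes the statistic: the returned vector always has sample SD
#' exactly 1 over the full gene list.
#'
#' @param zA,zB z-score matrices (genes x replicates) over the same gene list;
#'   the per-array z-scores of [ztransform_array()].
#' @return Named numeric vector of Z-ratios, one per gene.
#' @export
#' @examples
#' zA <- matrix(c(0.5, -0.5, 1.5, -1.5), 4, 1,
#'              dimnames = list(paste0("G", 1:4), "a1"))
#' zB <- matrix(0, 4, 1, dimnames = dimnames(zA))
#' round(z_ratio(zA, zB), 3)  # 0.387 -0.387 1.162 -1.162
z_ratio <- function(zA, zB) {
  zA <- as.matrix(zA); zB <- as.matrix(zB)
  if (nrow(zA) != nrow(zB) ||
      !identical(rownames(zA), rownames(zB)))
    stop("the two groups must cover the same gene list")
  d <- rowMeans(zA) - rowMeans(zB)
  d / sample_sd(d, "per-gene z-score differences")
}

#' Two-sided normal p-values for Z-ratios
#'
#' `p = 2 * (1 - pnorm(|z|))`: the Z-ratio is already population-standardized,
#' so significance is read from the standard normal.
#'
#' @param z finite Z-ratio values.
#' @return p-values in \[0, 1\].
#' @export
z_test_pvalues <- function(z) {
  if (any(!is.finite(z))) stop("Z-ratios must be finite")
  2 * stats::pnorm(-abs(z))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted q-values: monotone in p, elementwise `q >= p`, capped
#' at 1.
#'
#' @param p p-values in \[0, 1\].
#' @return q-values.
#' @export
fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Compound significance thresholds
#'
#' The selection rule applied to every contrast: a gene is significant iff
#' `p <= p_max` AND `q <= fdr_max` AND (fold change at least `fold_min` in
#' either direction on the ratio scale OR `|Z-ratio| >= zratio_min`). The
#' fold/Z-ratio clause is a disjunction ("either ... or").
#'
#' @param p_max maximum Z-test p-value (default 0.001).
#' @param fdr_max maximum BH q-value (default 0.1).
#' @param fold_min minimum fold change on the ratio scale (default 1.5; a
#'   gene passes with ratio >= 1.5 or <= 1/1.5).
#' @param zratio_min minimum absolute Z-ratio (default 3.0).
#' @return A list of class `anro_thresholds`.
#' @export
significance_thresholds <- function(p_max = 0.001, fdr_max = 0.1,
                                    fold_min = 1.5, zratio_min = 3.0) {
  vals <- c(p_max = p_max, fdr_max = fdr_max, fold_min = fold_min,
            zratio_min = zratio_min)
  if (any(vals <= 0)) stop("all thresholds must be positive")
  structure(as.list(vals), class = "anro_thresholds")
}

#' Differential-expression statistics for one timepoint-vs-baseline contrast
#'
#' Computes the full per-gene statistic table: mean log2-ratio of raw-scale
#' group means, fold change on the ratio scale (with the signed convention
#' `-baseline/treated` for down-regulation in `fold_signed`), Z-ratio, normal
#' p-value, BH q-value, direction and the compound filter flag.
#'
#' @param em the raw-scale `anro_matrix` (fold changes use raw means).
#' @param z matching z-score matrix from [ztransform_array()].
#' @param annotation a [sample_annotation()].
#' @param timepoint contrast timepoint (hours).
#' @param baseline baseline timepoint (hours), default 0.
#' @param thresholds a [significance_thresholds()].
#' @return A `data.frame` with columns `gene`, `mean_logratio`, `fold_change`,
#'   `fold_signed`, `z_ratio`, `p`, `q`, `direction`, `passes_filter`.
#' @export
de_stats <- function(em, z, annotation, timepoint, baseline = 0,
                     thresholds = significance_thresholds()) {
  stopifnot(inherits(em, "anro_matrix"))
  ann <- match_samples(em, annotation)
  a <- ann$timepoint_hr == timepoint
  b <- ann$timepoint_hr == baseline
  if (!any(a)) stop("timepoint ", timepoint, " absent from annotation")
  if (!any(b)) stop("baseline ", baseline, " absent from annotation")
  mean_a <- rowMeans(em$intensity[, a, drop = FALSE])
  mean_b <- rowMeans(em$intensity[, b, drop = FALSE])
  ratio <- mean_a / mean_b
  zr <- z_ratio(z[, a, drop = FALSE], z[, b, drop = FALSE])
  p <- z_test_pvalues(zr)
  q <- fdr(p)
  out <- data.frame(
    gene = rownames(em$intensity),
    mean_logratio = log2(ratio),
    fold_change = ratio,
    fold_signed = ifelse(ratio >= 1, ratio, -1 / ratio),
    z_ratio = zr, p = p, q = q,
    direction = ifelse(log2(ratio) >= 0, "up", "down"),
    stringsAsFactors = FALSE, row.names = NULL)
  out$passes_filter <- passes_filter(out, thresholds)
  out
}

#' Evaluate the compound significance filter
#'
#' @param stats a `data.frame` with columns `p`, `q`, `fold_change` (ratio
#'   scale) and `z_ratio` (as produced by [de_stats()]).
#' @param thresholds a [significance_thresholds()].
#' @return Logical vector, `TRUE` where the gene passes.
#' @export
passes_filter <- function(stats, thresholds = significance_thresholds()) {
  needed <- c("p", "q", "fold_change", "z_ratio")
  if (!all(needed %in% names(stats)))
    stop("stats table must carry columns: ", paste(needed, collapse = ", "))
  fold_ok <- stats$fold_change >= thresholds$fold_min |
    stats$fold_change <= 1 / thresholds$fold_min
  stats$p <= thresholds$p_max & stats$q <= thresholds$fdr_max &
    (fold_ok | abs(stats$z_ratio) >= thresholds$zratio_min)
}

#' Significant genes of one contrast, with directions
#'
#' @param stats a [de_stats()] table.
#' @param thresholds a [significance_thresholds()].
#' @param direction `"both"`, `"up"` or `"down"`.
#' @return The rows of `stats` passing the compound filter (and direction),
#'   ordered by `|z_ratio|` descending.
#' @export
significant_genes <- function(stats, thresholds = significance_thresholds(),
                              direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  keep <- passes_filter(stats, thresholds)
  if (direction != "both") keep <- keep & stats$direction == direction
  out <- stats[keep, , drop = FALSE]
  out[order(-abs(out$z_ratio)), , drop = FALSE]
}

#' Fold change from qPCR replicate ddCt values
#'
#' The comparative-Ct quantity: `fold = 2^(-mean(ddct))`, with
#' `ddct = (Ct_target - Ct_reference)_treated - (Ct_target - Ct_reference)_control`
#' per replicate.
#'
#' @param ddct numeric vector of per-replicate ddCt values (>= 1 value), or a
#'   `data.frame` with columns `ct_target_treated`, `ct_ref_treated`,
#'   `ct_target_control`, `ct_ref_control` from which ddCt is formed.
#' @return Average fold change (scalar).
#' @export
#' @examples
#' ddct_fold_change(c(-1, -3))  # mean ddCt -2 -> fold 4
ddct_fold_change <- function(ddct) {
  if (is.data.frame(ddct)) {
    needed <- c("ct_target_treated", "ct_ref_treated",
                "ct_target_control", "ct_ref_control")
    if (!all(needed %in% names(ddct)))
      stop("qPCR table must carry columns: ", paste(needed, collapse = ", "))
    ddct <- (ddct$ct_target_treated - ddct$ct_ref_treated) -
      (ddct$ct_target_control - ddct$ct_ref_control)
  }
  if (!length(ddct)) stop("need at least one ddCt replicate")
  if (any(!is.finite(ddct))) stop("Ct values must be finite")
  2^(-mean(ddct))
}
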