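#' Gene-by-sample expression matrix with detection scores
#'
#' The entry object of the pipeline: a matrix of strictly positive raw-scale
#' intensities with genes in rows (uppercase HUGO-style symbols) and samples in
#' columns, an optional per-gene-per-sample detection score in \[0, 1\], and
#' labels for the RNA source and array platform.
#'
#' @param intensity numeric matrix, genes x samples, strictly positive, with
#'   rownames (gene symbols) and colnames (sample ids).
#' @param detection optional numeric matrix of the same shape with detection
#'   scores in \[0, 1\]; `NULL` when the platform provides none.
#' @param rna_source `"NRO"` (nascent, nuclear run-on) or `"TOTAL"`
#'   (steady-state total RNA).
#' @param platform free-text platform label.
#'
#' @return An object of class `anro_matrix`: a list with elements `intensity`,
#'   `detection`, `rna_source`, `platform`.
#' @export
#' @examples
#' x <- matrix(c(100, 200, 50, 60), 2, 2,
#'             dimnames = list(c("MYC", "NME1"), c("s1", "s2")))
#' em <- expression_matrix(x, rna_source = "NRO", platform = "bead")
#' em
expression_matrix <- function(intensity, detection = NULL,
                              rna_source = c("NRO", "TOTAL"),
                              platform = "generic") {
  rna_source <- match.arg(rna_source)
  intensity <- as.matrix(intensity)
  if (!is.numeric(intensity)) stop("`intensity` must be numeric")
  if (is.null(rownames(intensity)) || is.null(colnames(intensity)))
    stop("`intensity` needs gene symbols as rownames and sample ids as colnames")
  bad <- which(!is.finite(intensity) | intensity <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("intensities must be finite and strictly positive (raw scale); ",
         "first offender: gene ", rownames(intensity)[bad[1, 1]],
         ", sample ", colnames(intensity)[bad[1, 2]])
  rownames(intensity) <- normalize_symbols(rownames(intensity))
  if (!is.null(detection)) {
    detection <- as.matrix(detection)
    if (!identical(dim(detection), dim(intensity)))
      stop("`detection` must have the same shape as `intensity`")
    if (any(!is.finite(detection)) || any(detection < 0 | detection > 1))
      stop("detection scores must lie in [0, 1]")
    dimnames(detection) <- dimnames(intensity)
  }
  structure(
    list(intensity = intensity, detection = detection,
         rna_source = rna_source, platform = platform),
    class = "anro_matrix")
}

#' @export
print.anro_matrix <- function(x, ...) {
  cat(sprintf("anro_matrix: %d genes x %d samples [%s, platform %s]%s\n",
              nrow(x$intensity), ncol(x$intensity), x$rna_source, x$platform,
              if (is.null(x$detection)) ", no detection scores" else ""))
  invisible(x)
}

#' @export
dim.anro_matrix <- function(x) dim(x$intensity)

#' Subset an expression matrix by gene and/or sample
#' @param x an `anro_matrix`.
#' @param i,j gene and sample indices (any form `[` accepts).
#' @param ... ignored.
#' @export
`[.anro_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$intensity))
  if (missing(j)) j <- seq_len(ncol(x$intensity))
  expression_matrix(x$intensity[i, j, drop = FALSE],
                    detection = if (!is.null(x$detection))
                      x$detection[i, j, drop = FALSE],
                    rna_source = x$rna_source, platform = x$platform)
}

#' Sample annotation table
#'
#' One row per array: sample id, timepoint in hours, replicate index, RNA
#' source and platform. Every sample id of an expression matrix must have
#' exactly one annotation row.
#'
#' @param sample_id character vector of unique sample ids.
#' @param timepoint_hr non-negative numeric timepoints.
#' @param replicate integer replicate index within a timepoint.
#' @param rna_source per-sample `"NRO"`/`"TOTAL"` labels.
#' @param platform per-sample platform label.
#' @return A `data.frame` with one row per sample and a `group` label
#'   (`<rna_source>_t<timepoint>`).
#' @export
sample_annotation <- function(sample_id, timepoint_hr, replicate,
                              rna_source, platform = "generic") {
  if (anyDuplicated(sample_id)) stop("sample ids must be unique")
  if (any(timepoint_hr < 0)) stop("timepoints must be non-negative hours")
  data.frame(sample_id = as.character(sample_id),
             timepoint_hr = as.numeric(timepoint_hr),
             replicate = as.integer(replicate),
             rna_source = as.character(rna_source),
             platform = as.character(platform),
             group = paste0(rna_source, "_t", timepoint_hr),
             stringsAsFactors = FALSE)
}

#' Write / read an expression matrix as tab-delimited text
#'
#' Genes in rows, samples in columns, first column `symbol`. Detection scores,
#' when present, go to a sidecar file with the same layout.
#'
#' @param em an `anro_matrix`.
#' @param path output TSV path.
#' @param detection_path optional path for the detection-score sidecar;
#'   defaults to `<path>` with a `.detection.tsv` suffix when scores exist.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(em, path, detection_path = NULL) {
  stopifnot(inherits(em, "anro_matrix"))
  write_gene_table(em$intensity, path)
  if (!is.null(em$detection)) {
    if (is.null(detection_path))
      detection_path <- sub("\\.tsv$", "", path)
    if (!grepl("\\.detection\\.tsv$", detection_path))
      detection_path <- paste0(detection_path, ".detection.tsv")
    write_gene_table(em$detection, detection_path)
  }
  invisible(path)
}

#' @rdname write_expression_matrix
#' @param rna_source,platform labels to attach on read.
#' @export
read_expression_matrix <- function(path, detection_path = NULL,
                                   rna_source = c("NRO", "TOTAL"),
                                   platform = "generic") {
  intensity <- read_gene_table(path)
  detection <- NULL
  if (is.null(detection_path)) {
    candidate <- paste0(sub("\\.tsv$", "", path), ".detection.tsv")
    if (file.exists(candidate)) detection_path <- candidate
  }
  if (!is.null(detection_path)) detection <- read_gene_table(detection_path)
  expression_matrix(intensity, detection = detection,
                    rna_source = match.arg(rna_source), platform = platform)
}

# gene-in-rows TSV helpers shared by matrix, log-ratio and truth output
write_gene_table <- function(mat, path) {
  df <- data.frame(symbol = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_gene_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}
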