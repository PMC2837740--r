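# shared internal helpers

# HUGO-style normalization applied before any join: uppercase, trim whitespace
normalize_symbols <- function(x) toupper(trimws(as.character(x)))

# sample SD (n-1); errors on the degenerate cases the pipeline must refuse
sample_sd <- function(x, what = "values") {
  if (length(x) < 2) stop("need at least two ", what, " to estimate an SD")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("zero variance among ", what, " (degenerate)")
  s
}

match_samples <- function(em, annotation) {
  ids <- colnames(em$intensity)
  idx <- match(ids, annotation$sample_id)
  if (anyNA(idx))
    stop("samples missing from annotation: ",
         paste(ids[is.na(idx)], collapse = ", "))
  annotation[idx, , drop = FALSE]
}
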