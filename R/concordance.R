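#' Join contrast-level log-ratio tables across platforms on gene symbols
#'
#' Within each table, duplicate symbols are first replaced by the arithmetic
#' mean of their log-ratios; the join then restricts to symbols present in
#' every table (HUGO-name intersection). Symbols are uppercased and trimmed
#' before matching.
#'
#' @param tables named list (>= 2) of `data.frame`s whose first column holds
#'   gene symbols and remaining column(s) log-ratios; single-value tables are
#'   typical (`symbol`, `logratio`).
#' @return A `data.frame`: `symbol` plus one column per input value column,
#'   prefixed by the table name; rows sorted by symbol.
#' @export
#' @examples
#' a <- data.frame(symbol = c("TP53", "TP53", "MYC"), logratio = c(0.8, 1.2, 2))
#' b <- data.frame(symbol = c("MYC", "EGFR"), logratio = c(1.8, 0.5))
#' join_platforms(list(A = a, B = b))  # MYC only; TP53 averaged then dropped
join_platforms <- function(tables) {
  if (length(tables) < 2) stop("need at least two tables to join")
  if (is.null(names(tables)))
    names(tables) <- paste0("table", seq_along(tables))
  averaged <- lapply(names(tables), function(nm) {
    tb <- as.data.frame(tables[[nm]])
    if (ncol(tb) < 2) stop("table ", nm, " needs symbol + value columns")
    sym <- normalize_symbols(tb[[1]])
    vals <- as.data.frame(lapply(tb[-1], as.numeric))
    agg <- stats::aggregate(vals, by = list(symbol = sym), FUN = mean)
    names(agg)[-1] <- paste(nm, names(vals), sep = ".")
    agg
  })
  joined <- Reduce(function(x, y) merge(x, y, by = "symbol"), averaged)
  if (!nrow(joined)) stop("no gene symbols shared by all tables")
  joined[order(joined$symbol), , drop = FALSE]
}

#' Pearson correlation matrix of joined log-ratio columns
#'
#' Standard centered Pearson correlation between every pair of value columns
#' of a [join_platforms()] table: symmetric, unit diagonal.
#'
#' @param joined a `data.frame` with a `symbol` column and >= 2 numeric
#'   columns over >= 3 genes.
#' @return Symmetric numeric correlation matrix.
#' @export
correlation_matrix <- function(joined) {
  vals <- as.matrix(joined[, setdiff(names(joined), "symbol"), drop = FALSE])
  if (nrow(vals) < 3) stop("need at least three genes")
  if (ncol(vals) < 2) stop("need at least two value columns")
  sds <- apply(vals, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance column(s): ",
         paste(colnames(vals)[sds == 0], collapse = ", "))
  stats::cor(vals)
}

#' Direct transcription-factor targets from binding and expression calls
#'
#' Intersects a ChIP binding list with up- and down-regulated gene lists:
#' `up_targets = bound AND up`, `down_targets = bound AND down`. Genes listed
#' as both up and down are excluded from both target sets with a warning and
#' reported in `conflicts`.
#'
#' @param bound,up,down character vectors of gene symbols.
#' @return A list of class `direct_targets` with sorted `up_targets`,
#'   `down_targets`, `conflicts` and a `provenance` size table.
#' @export
direct_targets <- function(bound, up, down) {
  bound <- unique(normalize_symbols(bound))
  up <- unique(normalize_symbols(up))
  down <- unique(normalize_symbols(down))
  conflicts <- intersect(up, down)
  if (length(conflicts))
    warning(length(conflicts),
            " gene(s) called both up and down excluded from the target sets")
  up <- setdiff(up, conflicts)
  down <- setdiff(down, conflicts)
  structure(list(
    up_targets = sort(intersect(bound, up)),
    down_targets = sort(intersect(bound, down)),
    conflicts = sort(conflicts),
    provenance = c(n_bound = length(bound), n_up = length(up),
                   n_down = length(down))),
    class = "direct_targets")
}

#' @export
print.direct_targets <- function(x, ...) {
  cat(sprintf("direct_targets: %d up, %d down (of %d bound genes)%s\n",
              length(x$up_targets), length(x$down_targets),
              x$provenance[["n_bound"]],
              if (length(x$conflicts))
                sprintf("; %d conflicting calls excluded", length(x$conflicts))
              else ""))
  invisible(x)
}
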