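#' First timepoint at which each gene is called significantly up-regulated
#'
#' @param flags logical matrix, genes x timepoints, `TRUE` where the gene
#'   passes the compound filter with direction "up" in the contrast of that
#'   timepoint against baseline.
#' @param timepoints_hr hours matching the columns of `flags`.
#' @return Named numeric vector: the earliest flagged timepoint per gene, `NA`
#'   where no timepoint is flagged.
#' @export
first_appearance <- function(flags, timepoints_hr) {
  flags <- as.matrix(flags)
  if (ncol(flags) != length(timepoints_hr))
    stop("flag columns and timepoints differ in length")
  if (is.unsorted(timepoints_hr, strictly = TRUE))
    stop("timepoints must be strictly increasing")
  idx <- apply(flags, 1, function(f) which(f)[1])
  stats::setNames(timepoints_hr[idx], rownames(flags))
}

#' Classify the transcriptional wave of a first-appearance time
#'
#' Waves follow the induction narrative: `early` responds within 1 hr,
#' `delayed_early` in the 3-6 hr window, `late` only at the final
#' (steady-state) timepoint; genes never significant are `unregulated`. On
#' custom grids the boundaries generalize to early <= 1 hr < delayed_early
#' <= 6 hr < late. A gene is flagged `transient` when it has a first
#' appearance but is not significant at the final timepoint; intermediate
#' dropouts do not toggle the flag.
#'
#' @param first_up numeric vector of first-appearance hours (`NA` = never).
#' @param final_flag logical vector: significant up at the final timepoint.
#' @return A `data.frame` with columns `wave_class` (factor: early,
#'   delayed_early, late, unregulated) and `transient`.
#' @export
classify_wave <- function(first_up, final_flag) {
  if (length(first_up) != length(final_flag))
    stop("`first_up` and `final_flag` differ in length")
  wave <- ifelse(is.na(first_up), "unregulated",
          ifelse(first_up <= 1, "early",
          ifelse(first_up <= 6, "delayed_early", "late")))
  data.frame(
    wave_class = factor(wave, levels = c("early", "delayed_early", "late",
                                         "unregulated")),
    transient = !is.na(first_up) & !final_flag,
    row.names = names(first_up), stringsAsFactors = FALSE)
}

#' Wave table for one channel from per-timepoint DE statistics
#'
#' Runs [first_appearance()] and [classify_wave()] over the up-regulation
#' flags of a list of per-timepoint contrast tables.
#'
#' @param de_list named list of [de_stats()] tables, one per non-baseline
#'   timepoint, names = hours, all over the same gene list.
#' @param thresholds a [significance_thresholds()].
#' @return A `data.frame` with `gene`, `first_up_hr`, `wave_class`,
#'   `transient`.
#' @export
wave_table <- function(de_list, thresholds = significance_thresholds()) {
  tp <- as.numeric(names(de_list))
  if (any(is.na(tp))) stop("`de_list` must be named by timepoint hours")
  o <- order(tp)
  de_list <- de_list[o]; tp <- tp[o]
  genes <- de_list[[1]]$gene
  flags <- vapply(de_list, function(d) {
    if (!identical(d$gene, genes)) stop("contrast tables disagree on genes")
    passes_filter(d, thresholds) & d$direction == "up"
  }, logical(length(genes)))
  flags <- matrix(flags, nrow = length(genes),
                  dimnames = list(genes, tp))
  first_up <- first_appearance(flags, tp)
  cls <- classify_wave(first_up, flags[, ncol(flags)])
  data.frame(gene = genes, first_up_hr = unname(first_up),
             wave_class = cls$wave_class, transient = cls$transient,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Lead of nascent transcription over total RNA
#'
#' For genes regulated in both channels, `lead_hr = first_up_total -
#' first_up_nro`: positive where the nuclear run-on channel anticipates the
#' steady-state change.
#'
#' @param wave_nro,wave_total [wave_table()] results over the same genes.
#' @return A list with `per_gene` (`gene`, `first_up_nro`, `first_up_total`,
#'   `lead_hr` over dually-regulated genes), `median_lead_hr` and
#'   `fraction_lead_nonneg`.
#' @export
lead_lag <- function(wave_nro, wave_total) {
  m <- merge(wave_nro[, c("gene", "first_up_hr")],
             wave_total[, c("gene", "first_up_hr")],
             by = "gene", suffixes = c("_nro", "_total"))
  both <- m[!is.na(m$first_up_hr_nro) & !is.na(m$first_up_hr_total), ]
  per_gene <- data.frame(gene = both$gene,
                         first_up_nro = both$first_up_hr_nro,
                         first_up_total = both$first_up_hr_total,
                         lead_hr = both$first_up_hr_total - both$first_up_hr_nro,
                         stringsAsFactors = FALSE)
  list(per_gene = per_gene,
       median_lead_hr = if (nrow(per_gene)) stats::median(per_gene$lead_hr)
                        else NA_real_,
       fraction_lead_nonneg = if (nrow(per_gene)) mean(per_gene$lead_hr >= 0)
                              else NA_real_)
}

#' Uncentered Pearson similarity
#'
#' `sum(x*y) / sqrt(sum(x^2) * sum(y^2))`: the cosine of the angle between
#' the raw profiles, without mean-centering. Values lie in \[-1, 1\].
#'
#' @param x,y numeric profiles of equal length, each with at least one
#'   nonzero entry.
#' @return Scalar similarity.
#' @export
uncentered_pearson <- function(x, y) {
  if (length(x) != length(y)) stop("profiles differ in length")
  sx <- sum(x^2); sy <- sum(y^2)
  if (sx == 0 || sy == 0) stop("all-zero profile has no direction")
  sum(x * y) / sqrt(sx * sy)
}

# full pairwise distance matrix 1 - uncentered Pearson
uncentered_distance <- function(profiles) {
  norms <- sqrt(rowSums(profiles^2))
  if (any(norms == 0)) stop("all-zero profile has no direction")
  sim <- tcrossprod(profiles / norms)
  sim <- pmin(pmax(sim, -1), 1)
  d <- 1 - sim
  diag(d) <- 0
  d
}

#' Complete-linkage clustering under the uncentered Pearson distance
#'
#' Agglomerative clustering of gene profiles with distance
#' `1 - uncentered_pearson` and complete (maximum) linkage, the combination
#' used for time-course heatmaps. Ties in the merge distance are broken
#' deterministically: among tied pairs, the one whose combined, sorted leaf
#' labels are lexicographically smallest merges first. Runs the
#' Lance-Williams update in O(n^3); intended for gene lists up to a few
#' thousand profiles.
#'
#' @param profiles numeric matrix, one row per gene (rownames = labels), one
#'   column per feature (e.g. log-ratios over timepoints); >= 2 rows.
#' @param distance optionally, a precomputed symmetric distance matrix to
#'   cluster instead of the uncentered-Pearson distance of `profiles`.
#' @return An object of classes `anro_hclust` and `hclust` (fields `merge`,
#'   `height`, `order`, `labels`), usable with [stats::cutree()] and
#'   `plot.hclust`.
#' @export
hierarchical_cluster <- function(profiles, distance = NULL) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  if (n < 2) stop("need at least two profiles")
  labels <- rownames(profiles)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  d <- if (is.null(distance)) uncentered_distance(profiles) else as.matrix(distance)
  if (!identical(dim(d), c(n, n))) stop("distance matrix shape mismatch")

  active <- seq_len(n)              # current cluster ids (neg = singleton row)
  node <- -seq_len(n)               # hclust merge coding
  members <- lapply(seq_len(n), function(i) labels[i])
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  D <- d

  for (step in seq_len(n - 1)) {
    k <- length(active)
    Dv <- D; Dv[lower.tri(Dv, diag = TRUE)] <- Inf
    dmin <- min(Dv)
    cand <- which(Dv <= dmin + 1e-12 * max(1, abs(dmin)), arr.ind = TRUE)
    if (nrow(cand) > 1) {           # deterministic lexicographic tie-break
      keys <- apply(cand, 1, function(ij)
        paste(sort(c(members[[ij[1]]], members[[ij[2]]])), collapse = "\r"))
      cand <- cand[order(keys)[1], , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]
    merge[step, ] <- sort(c(node[i], node[j]))
    height[step] <- D[i, j]
    # complete linkage: distance of the union to others is the max
    newd <- pmax(D[i, ], D[j, ])[-c(i, j)]
    members[[i]] <- c(members[[i]], members[[j]])
    node[i] <- step
    D <- D[-j, -j, drop = FALSE]
    members[j] <- NULL
    node <- node[-j]
    ii <- if (j < i) i - 1L else i
    D[ii, -ii] <- newd; D[-ii, ii] <- newd; D[ii, ii] <- 0
  }

  out <- list(merge = merge, height = height,
              order = dendrogram_order(merge),
              labels = labels, method = "complete",
              dist.method = "uncentered-pearson",
              call = match.call())
  class(out) <- c("anro_hclust", "hclust")
  out
}

# leaf order by left-to-right expansion of the merge tree
dendrogram_order <- function(merge) {
  expand <- function(k) {
    if (k < 0) return(-k)
    c(expand(merge[k, 1]), expand(merge[k, 2]))
  }
  expand(nrow(merge))
}

#' Leaf ordering of a dendrogram for heatmap export
#'
#' @param tree an `anro_hclust`/`hclust` object.
#' @return Character vector of labels in display order.
#' @export
leaf_order <- function(tree) tree$labels[tree$order]
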