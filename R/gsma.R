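#' Gene-set collection
#'
#' A named list of member-symbol vectors with optional per-set descriptions.
#' Set names must be unique, every set nonempty; members are uppercased and
#' deduplicated.
#'
#' @param sets named list of character vectors of gene symbols.
#' @param description optional character vector of per-set descriptions
#'   (recycled from `""`).
#' @return An object of class `gene_set_collection`.
#' @export
gene_sets <- function(sets, description = NULL) {
  if (!length(sets) || is.null(names(sets)) || any(names(sets) == ""))
    stop("`sets` must be a nonempty named list")
  if (anyDuplicated(names(sets)))
    stop("duplicate set names: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  sets <- lapply(sets, function(s) unique(normalize_symbols(s)))
  if (any(lengths(sets) == 0)) stop("every set must be nonempty")
  if (is.null(description)) description <- rep("", length(sets))
  description <- rep_len(as.character(description), length(sets))
  names(description) <- names(sets)
  structure(list(sets = sets, description = description),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, sizes %d-%d\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read / write gene sets in GMT format
#'
#' One tab-delimited line per set: name, description, then member symbols.
#' Member symbols are uppercased on read; write-then-read reproduces the
#' collection (member order preserved up to deduplication).
#'
#' @param path GMT file path.
#' @return [read_gmt()]: a `gene_set_collection`; [write_gmt()]: `path`,
#'   invisibly.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3
  if (any(short))
    stop("GMT line(s) with fewer than 3 fields: ",
         paste(which(short), collapse = ", "))
  nm <- vapply(fields, `[[`, character(1), 1)
  gene_sets(stats::setNames(lapply(fields, function(f) f[-(1:2)]), nm),
            description = vapply(fields, `[[`, character(1), 2))
}

#' @rdname read_gmt
#' @param collection a `gene_set_collection`.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$description[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' PAGE enrichment statistic for one gene set in one contrast
#'
#' The parametric gene-set enrichment score `z = (Sm - mu) * sqrt(m) / sigma`
#' where `Sm` is the median log-ratio of the set members present among the
#' measured genes, `mu` the median and `sigma` the sample SD of all measured
#' log-ratios in the contrast, and `m` the number of members present. Set
#' members absent from the measured universe are silently dropped (`m`
#' reflects the intersection). The statistic is invariant to adding a
#' constant to, or positively rescaling, the full log-ratio vector.
#'
#' @param set character vector of member gene symbols.
#' @param logratios named numeric vector: per-gene log-ratios of one contrast
#'   (>= 2 genes, positive SD).
#' @return A one-row `data.frame` with columns `Sm`, `mu`, `sigma`, `m`, `z`.
#' @export
#' @examples
#' lr <- c(A1 = -2, B1 = -1, C1 = 0, D1 = 1, E1 = 2)
#' page_z(c("D1", "E1"), lr)  # z = 1.5*sqrt(2)/sqrt(2.5) ~ 1.342
page_z <- function(set, logratios) {
  if (is.null(names(logratios))) stop("`logratios` must be named by gene")
  if (length(logratios) < 2) stop("need at least two measured genes")
  set <- unique(normalize_symbols(set))
  present <- intersect(set, names(logratios))
  m <- length(present)
  if (m < 1) stop("no set member present among the measured genes")
  sigma <- sample_sd(logratios, "log-ratios")
  Sm <- stats::median(logratios[present])
  mu <- stats::median(logratios)
  data.frame(Sm = Sm, mu = mu, sigma = sigma, m = m,
             z = (Sm - mu) * sqrt(m) / sigma)
}

#' Gene Set Matrix Analysis: PAGE scores across sets and contrasts
#'
#' Applies [page_z()] to every set in every contrast column. Sets with no
#' member in a contrast's measured universe yield an explicitly missing cell
#' (`NA` with `m = 0`), never a silent zero.
#'
#' @param collection a `gene_set_collection`.
#' @param logratios numeric matrix, measured genes x contrasts (rownames =
#'   symbols); `NA` cells are treated as unmeasured in that contrast.
#' @param contrast_info optional `data.frame` with one row per contrast
#'   (columns `contrast`, `rna_source`, `timepoint_hr`) used by
#'   [sort_by_first_appearance()]; by default parsed from column names of the
#'   form `<SOURCE>_<hours>`.
#' @return An object of class `anro_enrichment`: list with matrices `z`,
#'   `Sm`, `m` (sets x contrasts), vectors `mu`, `sigma` (per contrast), the
#'   `contrast_info` table and the collection.
#' @export
gsma_matrix <- function(collection, logratios, contrast_info = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  logratios <- as.matrix(logratios)
  if (is.null(rownames(logratios))) stop("`logratios` needs gene rownames")
  if (!length(collection$sets)) stop("empty collection")
  if (ncol(logratios) < 1) stop("need at least one contrast")
  rownames(logratios) <- normalize_symbols(rownames(logratios))
  set_names <- names(collection$sets)
  contrasts <- colnames(logratios)
  if (is.null(contrasts)) contrasts <- as.character(seq_len(ncol(logratios)))
  z <- Sm <- matrix(NA_real_, length(set_names), length(contrasts),
                    dimnames = list(set_names, contrasts))
  m <- matrix(0L, length(set_names), length(contrasts),
              dimnames = list(set_names, contrasts))
  mu <- sigma <- stats::setNames(numeric(length(contrasts)), contrasts)
  for (j in seq_along(contrasts)) {
    lr <- logratios[, j]
    lr <- lr[is.finite(lr)]
    mu[j] <- stats::median(lr)
    sigma[j] <- sample_sd(lr, "log-ratios")
    for (i in seq_along(set_names)) {
      res <- tryCatch(page_z(collection$sets[[i]], lr), error = function(e) NULL)
      if (!is.null(res)) {
        z[i, j] <- res$z; Sm[i, j] <- res$Sm; m[i, j] <- res$m
      }
    }
  }
  if (is.null(contrast_info)) contrast_info <- parse_contrast_names(contrasts)
  structure(list(z = z, Sm = Sm, m = m, mu = mu, sigma = sigma,
                 contrast_info = contrast_info, collection = collection),
            class = "anro_enrichment")
}

parse_contrast_names <- function(contrasts) {
  parts <- regmatches(contrasts,
                      regexec("^([A-Za-z]+)_([0-9.]+)$", contrasts))
  data.frame(
    contrast = contrasts,
    rna_source = vapply(parts, function(p)
      if (length(p) == 3) toupper(p[2]) else NA_character_, character(1)),
    timepoint_hr = vapply(parts, function(p)
      if (length(p) == 3) as.numeric(p[3]) else NA_real_, numeric(1)),
    stringsAsFactors = FALSE)
}

#' @export
print.anro_enrichment <- function(x, ...) {
  cat(sprintf("anro_enrichment: %d sets x %d contrasts (%d missing cells)\n",
              nrow(x$z), ncol(x$z), sum(is.na(x$z))))
  invisible(x)
}

#' Per-cell significance of an enrichment matrix
#'
#' Two-sided normal p-values on the PAGE z scores, with BH q-values computed
#' across sets within each contrast. Missing cells stay missing.
#'
#' @param em an `anro_enrichment`.
#' @return The enrichment object with matrices `p` and `q` added.
#' @export
enrichment_significance <- function(em) {
  stopifnot(inherits(em, "anro_enrichment"))
  p <- 2 * stats::pnorm(-abs(em$z))
  q <- apply(p, 2, function(col) {
    out <- rep(NA_real_, length(col))
    ok <- !is.na(col)
    out[ok] <- stats::p.adjust(col[ok], method = "BH")
    out
  })
  q <- matrix(q, nrow = nrow(p), dimnames = dimnames(p))
  em$p <- p; em$q <- q
  em
}

#' Order gene sets by first appearance as up-regulated in the NRO channel
#'
#' Rows are ordered by the earliest nuclear run-on contrast in which the
#' set's z score reaches `z_threshold`; sets never reaching it come last,
#' ordered by decreasing `|z|` at the final NRO contrast. Ties within a first
#' appearance are broken by decreasing z at that contrast.
#'
#' @param em an `anro_enrichment` whose `contrast_info` marks NRO columns
#'   with their timepoints.
#' @param z_threshold minimum z to call a set up-regulated (default 1.96).
#' @return A `data.frame` (`set`, `first_up_hr`, ordering key columns), rows
#'   in display order.
#' @export
sort_by_first_appearance <- function(em, z_threshold = 1.96) {
  stopifnot(inherits(em, "anro_enrichment"))
  info <- em$contrast_info
  nro <- which(info$rna_source == "NRO" & !is.na(info$timepoint_hr))
  if (!length(nro)) stop("no NRO contrasts in the enrichment matrix")
  nro <- nro[order(info$timepoint_hr[nro])]
  tp <- info$timepoint_hr[nro]
  zn <- em$z[, nro, drop = FALSE]
  flags <- !is.na(zn) & zn >= z_threshold
  first_up <- first_appearance(flags, tp)
  z_at_first <- vapply(seq_len(nrow(zn)), function(i) {
    if (is.na(first_up[i])) NA_real_ else zn[i, match(first_up[i], tp)]
  }, numeric(1))
  z_final <- zn[, ncol(zn)]
  ord <- order(is.na(first_up), first_up, -z_at_first,
               -abs(ifelse(is.na(z_final), 0, z_final)))
  data.frame(set = rownames(em$z), first_up_hr = unname(first_up),
             z_at_first = z_at_first, z_final_nro = z_final,
             stringsAsFactors = FALSE, row.names = NULL)[ord, ]
}

#' Write an enrichment matrix as tab-delimited text
#'
#' One row per set; per contrast a column group `<contrast>.z`,
#' `<contrast>.m` and, when present, `.p`/`.q`.
#'
#' @param em an `anro_enrichment`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(em, path) {
  stopifnot(inherits(em, "anro_enrichment"))
  blocks <- lapply(colnames(em$z), function(ct) {
    b <- data.frame(z = em$z[, ct], m = em$m[, ct])
    if (!is.null(em$p)) { b$p <- em$p[, ct]; b$q <- em$q[, ct] }
    names(b) <- paste(ct, names(b), sep = ".")
    b
  })
  df <- cbind(data.frame(set = rownames(em$z), stringsAsFactors = FALSE),
              do.call(cbind, blocks))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
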