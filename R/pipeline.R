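#' Configuration of an end-to-end pipeline run
#'
#' Either simulated input (a [sim_config()]) or paths to on-disk matrices.
#' Contrasts are always timepoint-vs-baseline within one RNA source.
#'
#' @param sim a [sim_config()] for synthetic input, or `NULL` to read files.
#' @param nro_path,total_path,annotation_path input TSVs when `sim` is `NULL`
#'   (expression matrices as written by [write_expression_matrix()]).
#' @param gmt_path optional GMT file of gene sets; when absent and no
#'   simulated collection is requested, the enrichment stage is skipped.
#' @param chip_path optional plain-text bound-gene list (one symbol per
#'   line); when absent the direct-target stage is skipped.
#' @param baseline_timepoint baseline hours (default 0).
#' @param detection_threshold detection filter cutoff (default 0.98).
#' @param thresholds a [significance_thresholds()].
#' @param gsma_universe `"all"` (default) or `"de"`: compute enrichment over
#'   all measured genes or only those significant in at least one contrast.
#' @param outdir output directory.
#' @param seed integer seed governing any simulated stage.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = NULL, nro_path = NULL, total_path = NULL,
                       annotation_path = NULL, gmt_path = NULL,
                       chip_path = NULL, baseline_timepoint = 0,
                       detection_threshold = 0.98,
                       thresholds = significance_thresholds(),
                       gsma_universe = c("all", "de"),
                       outdir = tempfile("anro_run_"), seed = 1L) {
  gsma_universe <- match.arg(gsma_universe)
  if (is.null(sim) &&
      (is.null(nro_path) || is.null(total_path) || is.null(annotation_path)))
    stop("provide either `sim` or all three input paths")
  structure(list(sim = sim, nro_path = nro_path, total_path = total_path,
                 annotation_path = annotation_path, gmt_path = gmt_path,
                 chip_path = chip_path,
                 baseline_timepoint = baseline_timepoint,
                 detection_threshold = detection_threshold,
                 thresholds = thresholds, gsma_universe = gsma_universe,
                 outdir = outdir, seed = as.integer(seed)),
            class = "run_config")
}

load_run_inputs <- function(config) {
  if (!is.null(config$sim)) {
    sim <- config$sim
    sim$seed <- config$seed
    simulate_experiment(sim)
  } else {
    ann <- utils::read.delim(config$annotation_path, stringsAsFactors = FALSE)
    list(nro = read_expression_matrix(config$nro_path, rna_source = "NRO"),
         total = read_expression_matrix(config$total_path,
                                        rna_source = "TOTAL"),
         annotation = ann, truth = NULL)
  }
}

#' Validate pipeline inputs before running
#'
#' Checks matrix/annotation consistency, positivity of intensities, symbol
#' duplication, the timepoint grid and threshold sanity, returning a
#' machine-readable issue table instead of failing.
#'
#' @param config a [run_config()].
#' @return A `data.frame` with columns `stage`, `issue` (zero rows when
#'   clean).
#' @export
validate_inputs <- function(config) {
  issues <- list()
  note <- function(stage, issue)
    issues[[length(issues) + 1]] <<- data.frame(stage = stage, issue = issue,
                                                stringsAsFactors = FALSE)
  inputs <- tryCatch(load_run_inputs(config), error = function(e) {
    note("load", conditionMessage(e)); NULL
  })
  if (!is.null(inputs)) {
    ann <- inputs$annotation
    for (ch in c("nro", "total")) {
      em <- inputs[[ch]]
      miss <- setdiff(colnames(em$intensity), ann$sample_id)
      if (length(miss))
        note("annotation", paste0(ch, ": samples without annotation: ",
                                  paste(miss, collapse = ", ")))
      bad <- which(!is.finite(em$intensity) | em$intensity <= 0, arr.ind = TRUE)
      if (nrow(bad))
        note("intensity", paste0(ch, ": non-positive intensity at gene ",
                                 rownames(em$intensity)[bad[1, 1]],
                                 ", sample ",
                                 colnames(em$intensity)[bad[1, 2]]))
      dup <- unique(rownames(em$intensity)[duplicated(rownames(em$intensity))])
      if (length(dup))
        note("symbols", paste0(ch, ": duplicate symbols (will be averaged on ",
                               "join): ", paste(utils::head(dup, 5),
                                                collapse = ", ")))
    }
    if (!config$baseline_timepoint %in% ann$timepoint_hr)
      note("timepoints", paste0("baseline ", config$baseline_timepoint,
                                " hr absent from annotation"))
    if (anyDuplicated(ann$sample_id))
      note("annotation", "duplicate sample ids")
  }
  th <- unlist(config$thresholds)
  if (any(th <= 0)) note("thresholds", "non-positive threshold")
  if (length(issues)) do.call(rbind, issues)
  else data.frame(stage = character(0), issue = character(0))
}

#' Run the full analysis pipeline
#'
#' Stages, in order: (1) simulate or ingest the paired matrices; (2)
#' detection-filter and Z-transform each channel; (3) Z-ratio differential
#' expression for every timepoint against baseline in both channels; (4)
#' wave tables and the NRO-vs-total lead summary; (5) PAGE enrichment over a
#' gene-set collection (skipped when none is supplied); (6) NRO/total
#' concordance (join + correlation matrix) and, when a binding list is
#' supplied, direct-target calls. All artifacts are written as tab-delimited
#' text under `config$outdir` and recorded in a manifest with MD5 content
#' hashes; a rerun with the same config and seed is hash-identical.
#'
#' @param config a [run_config()].
#' @return A list of class `anro_run`: `manifest` (`stage`, `file`, `md5`),
#'   `outdir`, plus the in-memory stage results (`de`, `waves`, `lead`,
#'   `enrichment`, `concordance`, `targets`, `truth`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  issues <- validate_inputs(config)
  issues <- issues[issues$stage != "symbols", , drop = FALSE]  # join handles dups
  if (nrow(issues))
    stop("input validation failed [", issues$stage[1], "]: ", issues$issue[1])
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  emit <- function(stage, file) {
    manifest[[length(manifest) + 1]] <<- data.frame(
      stage = stage, file = basename(file),
      md5 = unname(tools::md5sum(file)), stringsAsFactors = FALSE)
  }
  log_msg <- function(...) message("[anro] ", sprintf(...))

  # stage 1: input
  log_msg("stage input")
  inputs <- load_run_inputs(config)
  ann <- inputs$annotation
  if (!is.null(inputs$truth)) {
    f <- file.path(config$outdir, "truth.tsv")
    utils::write.table(inputs$truth, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    emit("input", f)
  }
  f <- file.path(config$outdir, "annotation.tsv")
  utils::write.table(ann, f, sep = "\t", quote = FALSE, row.names = FALSE)
  emit("input", f)

  # stages 2-4 per channel
  channel <- function(em) {
    ch_ann <- ann[ann$rna_source == em$rna_source, ]
    em <- if (!is.null(em$detection))
      filter_undetected(em, config$detection_threshold) else em
    z <- ztransform_array(em)
    tps <- setdiff(sort(unique(ch_ann$timepoint_hr)),
                   config$baseline_timepoint)
    de <- lapply(tps, function(tp)
      de_stats(em, z, ch_ann, tp, config$baseline_timepoint,
               config$thresholds))
    names(de) <- tps
    lr <- log_ratio(em, ch_ann, config$baseline_timepoint, tps)
    colnames(lr) <- paste(em$rna_source, tps, sep = "_")
    list(em = em, z = z, de = de, waves = wave_table(de, config$thresholds),
         logratio = lr)
  }
  log_msg("stage preprocess + differential")
  nro <- channel(inputs$nro)
  total <- channel(inputs$total)
  for (ch in list(nro, total)) {
    src <- ch$em$rna_source
    f <- file.path(config$outdir, sprintf("z_%s.tsv", src))
    write_gene_table(ch$z, f)
    emit("preprocess", f)
    for (tp in names(ch$de)) {
      f <- file.path(config$outdir, sprintf("de_%s_t%s.tsv", src, tp))
      utils::write.table(ch$de[[tp]], f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      emit("differential", f)
    }
    f <- file.path(config$outdir, sprintf("waves_%s.tsv", src))
    utils::write.table(ch$waves, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    emit("waves", f)
  }

  log_msg("stage lead-lag")
  lead <- lead_lag(nro$waves, total$waves)
  f <- file.path(config$outdir, "lead_lag.tsv")
  utils::write.table(lead$per_gene, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  emit("waves", f)

  # stage 5: enrichment (optional)
  enrichment <- NULL
  if (!is.null(config$gmt_path)) {
    log_msg("stage enrichment")
    collection <- read_gmt(config$gmt_path)
    joined_lr <- merge_logratio_channels(nro, total)
    if (config$gsma_universe == "de") {
      de_genes <- unique(unlist(c(
        lapply(nro$de, function(d) d$gene[d$passes_filter]),
        lapply(total$de, function(d) d$gene[d$passes_filter]))))
      joined_lr <- joined_lr[rownames(joined_lr) %in% de_genes, , drop = FALSE]
    }
    enrichment <- enrichment_significance(gsma_matrix(collection, joined_lr))
    f <- file.path(config$outdir, "enrichment.tsv")
    write_enrichment(enrichment, f)
    emit("enrichment", f)
    f <- file.path(config$outdir, "enrichment_order.tsv")
    utils::write.table(sort_by_first_appearance(enrichment), f, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit("enrichment", f)
  } else log_msg("stage enrichment skipped (no gene sets)")

  # stage 6: concordance + targets
  log_msg("stage concordance")
  final_tp <- max(ann$timepoint_hr)
  nro_final <- nro$de[[as.character(final_tp)]]
  total_final <- total$de[[as.character(final_tp)]]
  joined <- join_platforms(list(
    NRO = data.frame(symbol = nro_final$gene,
                     logratio = nro_final$mean_logratio),
    TOTAL = data.frame(symbol = total_final$gene,
                       logratio = total_final$mean_logratio)))
  cm <- correlation_matrix(joined)
  f <- file.path(config$outdir, "concordance.tsv")
  utils::write.table(data.frame(contrast = rownames(cm), cm,
                                check.names = FALSE),
                     f, sep = "\t", quote = FALSE, row.names = FALSE)
  emit("concordance", f)

  targets <- NULL
  if (!is.null(config$chip_path)) {
    log_msg("stage targets")
    bound <- readLines(config$chip_path)
    up <- unique(unlist(lapply(nro$de, function(d)
      d$gene[d$passes_filter & d$direction == "up"])))
    down <- unique(unlist(lapply(nro$de, function(d)
      d$gene[d$passes_filter & d$direction == "down"])))
    targets <- direct_targets(bound, up, down)
    f <- file.path(config$outdir, "direct_targets.tsv")
    utils::write.table(
      data.frame(gene = c(targets$up_targets, targets$down_targets),
                 direction = rep(c("up", "down"),
                                 c(length(targets$up_targets),
                                   length(targets$down_targets))),
                 provenance = "bound+significant"),
      f, sep = "\t", quote = FALSE, row.names = FALSE)
    emit("targets", f)
  } else log_msg("stage targets skipped (no binding list)")

  manifest <- do.call(rbind, manifest)
  f <- file.path(config$outdir, "manifest.tsv")
  utils::write.table(manifest, f, sep = "\t", quote = FALSE, row.names = FALSE)
  structure(list(manifest = manifest, outdir = config$outdir,
                 de = list(NRO = nro$de, TOTAL = total$de),
                 waves = list(NRO = nro$waves, TOTAL = total$waves),
                 lead = lead, enrichment = enrichment,
                 concordance = cm, targets = targets,
                 truth = inputs$truth, seed = config$seed),
            class = "anro_run")
}

# gene x contrast log-ratio matrix over the genes shared by both channels
merge_logratio_channels <- function(nro, total) {
  shared <- intersect(rownames(nro$logratio), rownames(total$logratio))
  cbind(nro$logratio[shared, , drop = FALSE],
        total$logratio[shared, , drop = FALSE])
}

#' @export
print.anro_run <- function(x, ...) {
  cat(sprintf("anro_run: %d artifacts in %s (seed %d)\n",
              nrow(x$manifest), x$outdir, x$seed))
  print(table(x$manifest$stage))
  invisible(x)
}
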