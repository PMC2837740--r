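#' Configuration for the synthetic paired NRO/total time-course generator
#'
#' Defines a Myc-induction-style design: a shared timepoint grid sampled in
#' both a nascent (nuclear run-on, NRO) and a total-RNA channel, a set of
#' regulated genes organized in transcriptional waves whose total-RNA onset
#' lags the NRO onset, undetected background genes, and homoscedastic
#' Gaussian replicate noise on the log scale.
#'
#' Waves: `early` genes switch on at 0.25-1 hr, `delayed_early` at 3-6 hr,
#' `late` at the final timepoint only; `transient_early` genes switch on like
#' early genes but return to baseline at the final timepoint. Effect size and
#' replicate noise are both parameterized on the log2 scale so a fold change
#' of `2^effect_log2` is planted against noise of SD `noise_sd_log` log2
#' units; internally intensities are built on the log10 scale (baseline log10
#' intensity ~ Normal(2.5, 0.5) truncated above 0.5, spanning the dynamic
#' range of bead arrays). The paper-era assay this emulates published no
#' noise model, so the distributional choices here are documented stand-ins.
#'
#' @param n_genes number of genes.
#' @param timepoints_hr strictly increasing non-negative hours; the first
#'   entry is the baseline (0 hr).
#' @param replicates_per_timepoint arrays per timepoint per channel.
#' @param replicate_override named list/vector mapping timepoint (as character
#'   hours) to a replicate count, e.g. `c("48" = 10)`.
#' @param fraction_regulated proportion of genes carrying a planted wave.
#' @param wave_mix named proportions over
#'   `early`, `delayed_early`, `late`, `transient_early`; must sum to 1.
#' @param effect_log2 planted effect size, log2 scale (> 0).
#' @param lag_steps non-negative integer: total-RNA onset is the NRO onset
#'   shifted this many positions along the timepoint grid (capped at the
#'   final timepoint).
#' @param noise_sd_log replicate noise SD, log2 scale (> 0).
#' @param fraction_background proportion of genes kept at background, i.e.
#'   with detection scores below the filter threshold in every sample.
#' @param seed integer seed; all generator randomness derives from it.
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 500, seed = 7)
#' sim <- simulate_experiment(cfg)
#' table(sim$truth$wave)
sim_config <- function(n_genes = 20000,
                       timepoints_hr = c(0, 0.25, 0.5, 1, 3, 6, 48),
                       replicates_per_timepoint = 6,
                       replicate_override = c("48" = 10),
                       fraction_regulated = 0.05,
                       wave_mix = c(early = 0.30, delayed_early = 0.30,
                                    late = 0.20, transient_early = 0.20),
                       effect_log2 = 1,
                       lag_steps = 1,
                       noise_sd_log = 0.2,
                       fraction_background = 0.10,
                       seed = 1L) {
  if (n_genes < 1) stop("`n_genes` must be positive")
  if (any(diff(timepoints_hr) <= 0)) stop("timepoints must be strictly increasing")
  if (timepoints_hr[1] != 0) stop("the first timepoint must be the 0 hr baseline")
  wanted <- c("early", "delayed_early", "late", "transient_early")
  if (!setequal(names(wave_mix), wanted)) stop("`wave_mix` must name all four waves")
  wave_mix <- wave_mix[wanted]
  if (abs(sum(wave_mix) - 1) > 1e-9) stop("`wave_mix` must sum to 1")
  if (effect_log2 <= 0) stop("`effect_log2` must be strictly positive")
  if (noise_sd_log <= 0) stop("`noise_sd_log` must be strictly positive")
  if (fraction_regulated < 0 || fraction_background < 0 ||
      fraction_regulated + fraction_background > 1)
    stop("fraction_regulated + fraction_background must lie in [0, 1]")
  if (lag_steps < 0 || lag_steps != round(lag_steps))
    stop("`lag_steps` must be a non-negative integer")
  reps <- rep(as.integer(replicates_per_timepoint), length(timepoints_hr))
  names(reps) <- as.character(timepoints_hr)
  for (tp in names(replicate_override))
    if (tp %in% names(reps)) reps[tp] <- as.integer(replicate_override[[tp]])
  structure(list(
    n_genes = as.integer(n_genes), timepoints_hr = as.numeric(timepoints_hr),
    replicates = reps, fraction_regulated = fraction_regulated,
    wave_mix = wave_mix, effect_log2 = effect_log2,
    lag_steps = as.integer(lag_steps), noise_sd_log = noise_sd_log,
    fraction_background = fraction_background, seed = as.integer(seed)),
    class = "sim_config")
}

# grid positions each wave may switch on at (indices into timepoints_hr)
wave_onset_pool <- function(tp, wave) {
  switch(wave,
    early = ,
    transient_early = which(tp > 0 & tp <= 1),
    delayed_early   = which(tp >= 3 & tp <= 6),
    late            = length(tp),
    stop("unknown wave: ", wave))
}

# expected log2-ratio profile over the grid for one gene in one channel
wave_profile <- function(tp, onset_idx, effect_log2, transient) {
  prof <- numeric(length(tp))
  if (onset_idx <= length(tp)) prof[onset_idx:length(tp)] <- effect_log2
  if (transient) prof[length(tp)] <- 0
  prof
}

#' Simulate a paired NRO/total-RNA time-course experiment
#'
#' Generates two expression matrices (nascent and total channel) over the same
#' gene universe and design, a sample annotation table, and the ground-truth
#' table used by all recovery tests. Regulated genes step up by `effect_log2`
#' (log2 scale) from their onset; `transient_early` genes drop back to
#' baseline at the final timepoint; the total-RNA onset is the NRO onset
#' shifted `lag_steps` grid positions. Background genes receive detection
#' scores drawn below the usual filter threshold in every sample; all other
#' genes score 1. Deterministic for a fixed config (the seed lives in the
#' config); the caller's RNG state is left untouched.
#'
#' @param config a [sim_config()].
#' @return A list with elements `nro` and `total` (class `anro_matrix`),
#'   `annotation` (one row per sample per channel) and `truth` (a data frame
#'   with `gene`, `regulated`, `wave`, `nro_onset_hr`, `total_onset_hr`,
#'   `effect_log2`, `persists_at_48h`, `background`).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tp <- config$timepoints_hr
  n <- config$n_genes
  withr::with_seed(config$seed, {
    genes <- sprintf("GENE%05d", seq_len(n))
    n_reg <- round(config$fraction_regulated * n)
    n_bg <- round(config$fraction_background * n)
    status <- rep("unregulated", n)
    if (n_reg > 0) status[seq_len(n_reg)] <- "regulated"
    if (n_bg > 0) status[n - seq_len(n_bg) + 1L] <- "background"
    status <- sample(status)  # shuffle labels over gene ids

    truth <- data.frame(gene = genes, regulated = status == "regulated",
                        wave = NA_character_, nro_onset_hr = NA_real_,
                        total_onset_hr = NA_real_, effect_log2 = 0,
                        persists_at_48h = NA, background = status == "background",
                        stringsAsFactors = FALSE)
    reg_idx <- which(truth$regulated)
    if (length(reg_idx)) {
      waves <- sample(rep(names(config$wave_mix),
                          diff(round(cumsum(c(0, config$wave_mix)) * length(reg_idx)))))
      onset_idx <- vapply(waves, function(w) {
        pool <- wave_onset_pool(tp, w)
        if (length(pool) == 1) pool else sample(pool, 1)
      }, integer(1))
      total_idx <- pmin(onset_idx + config$lag_steps, length(tp))
      truth$wave[reg_idx] <- waves
      truth$nro_onset_hr[reg_idx] <- tp[onset_idx]
      truth$total_onset_hr[reg_idx] <- tp[total_idx]
      truth$effect_log2[reg_idx] <- config$effect_log2
      truth$persists_at_48h[reg_idx] <- waves != "transient_early"
    }

    baseline_log10 <- rnorm_truncated(n, mean = 2.5, sd = 0.5, lower = 0.5)

    channel <- function(source) {
      onset_hr <- if (source == "NRO") truth$nro_onset_hr else truth$total_onset_hr
      profiles <- matrix(0, n, length(tp))
      for (g in which(truth$regulated)) {
        profiles[g, ] <- wave_profile(tp, match(onset_hr[g], tp),
                                      config$effect_log2,
                                      truth$wave[g] == "transient_early")
      }
      cols <- list(); det <- list(); ann <- list()
      for (k in seq_along(tp)) {
        for (r in seq_len(config$replicates[k])) {
          noise_log2 <- stats::rnorm(n, 0, config$noise_sd_log)
          log10x <- baseline_log10 + (profiles[, k] + noise_log2) * log10(2)
          id <- sprintf("%s_t%g_r%d", source, tp[k], r)
          cols[[id]] <- 10^log10x
          det[[id]] <- ifelse(truth$background, stats::runif(n, 0, 0.9), 1)
          ann[[id]] <- data.frame(sample_id = id, timepoint_hr = tp[k],
                                  replicate = r, rna_source = source,
                                  stringsAsFactors = FALSE)
        }
      }
      intensity <- do.call(cbind, cols); rownames(intensity) <- genes
      detection <- do.call(cbind, det); rownames(detection) <- genes
      list(em = expression_matrix(intensity, detection = detection,
                                  rna_source = source, platform = "simulated"),
           annotation = do.call(rbind, ann))
    }

    nro <- channel("NRO")
    total <- channel("TOTAL")
    ann <- rbind(nro$annotation, total$annotation)
    annotation <- sample_annotation(ann$sample_id, ann$timepoint_hr,
                                    ann$replicate, ann$rna_source,
                                    platform = "simulated")
    list(nro = nro$em, total = total$em, annotation = annotation, truth = truth)
  })
}

rnorm_truncated <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= lower)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Simulate gene-set collections with planted coordinate shifts
#'
#' Planted sets are drawn without replacement from regulated genes sharing one
#' wave class (cycling over the classes that have enough members); null sets
#' are drawn uniformly from all genes. Set names encode the ground truth
#' (`PLANTED_<WAVE>_<i>` / `NULL_<i>`).
#'
#' @param truth the truth table from [simulate_experiment()].
#' @param n_planted,n_null number of planted and null sets.
#' @param set_size genes per set.
#' @param seed integer seed.
#' @return A [gene_sets()] collection.
#' @export
simulate_genesets <- function(truth, n_planted, n_null, set_size, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    sets <- list()
    if (n_planted > 0) {
      counts <- table(truth$wave[truth$regulated])
      classes <- names(counts)[counts >= set_size]
      if (!length(classes))
        stop("no wave class holds ", set_size, " regulated genes")
      for (i in seq_len(n_planted)) {
        cls <- classes[(i - 1) %% length(classes) + 1]
        pool <- truth$gene[truth$regulated & truth$wave == cls]
        sets[[sprintf("PLANTED_%s_%02d", toupper(cls), i)]] <-
          sample(pool, set_size)
      }
    }
    for (i in seq_len(n_null)) {
      if (set_size > nrow(truth)) stop("set size exceeds the gene universe")
      sets[[sprintf("NULL_%02d", i)]] <- sample(truth$gene, set_size)
    }
    gene_sets(sets, description = ifelse(grepl("^PLANTED", names(sets)),
                                         "planted coordinate shift", "null set"))
  })
}

#' Simulate two platforms measuring the same contrast
#'
#' Both platforms report the same true per-gene log-ratio (the planted
#' steady-state effect: `effect_log2` for regulated genes that persist, 0
#' otherwise) plus independent Gaussian platform noise, emulating a
#' cross-vendor comparison on a common gene pool. The expected inter-platform
#' Pearson correlation is the attenuation ratio `v / (v + s^2)` where `v` is
#' the variance of the true log-ratios and `s` the platform noise SD.
#'
#' @param truth truth table from [simulate_experiment()].
#' @param shared_genes number of genes on the common pool (sampled from the
#'   universe).
#' @param platform_noise_sd per-platform noise SD (> 0), log2 scale.
#' @param seed integer seed.
#' @return A list with data frames `a` and `b` (`symbol`, `logratio`) and the
#'   vector `true_logratio` underlying both.
#' @export
simulate_two_platforms <- function(truth, shared_genes, platform_noise_sd,
                                   seed = 1L) {
  if (platform_noise_sd <= 0) stop("`platform_noise_sd` must be positive")
  if (shared_genes > nrow(truth)) stop("`shared_genes` exceeds the gene universe")
  withr::with_seed(as.integer(seed), {
    genes <- sort(sample(truth$gene, shared_genes))
    i <- match(genes, truth$gene)
    lr <- ifelse(truth$regulated[i] & truth$persists_at_48h[i],
                 truth$effect_log2[i], 0)
    mk <- function() data.frame(
      symbol = genes,
      logratio = lr + stats::rnorm(shared_genes, 0, platform_noise_sd),
      stringsAsFactors = FALSE)
    list(a = mk(), b = mk(), true_logratio = stats::setNames(lr, genes))
  })
}

#' Simulate a ChIP binding list over the synthetic truth
#'
#' Returns a gene list holding a stated fraction of the regulated genes plus
#' decoy unregulated genes, emulating a transcription-factor binding list to
#' be intersected with the expression calls.
#'
#' @param truth truth table from [simulate_experiment()].
#' @param coverage fraction of regulated genes included, in \[0, 1\].
#' @param n_decoys number of unregulated genes added.
#' @param seed integer seed.
#' @return Character vector of bound gene symbols (sorted).
#' @export
simulate_chip_list <- function(truth, coverage, n_decoys, seed = 1L) {
  if (coverage < 0 || coverage > 1) stop("`coverage` must lie in [0, 1]")
  withr::with_seed(as.integer(seed), {
    reg <- truth$gene[truth$regulated]
    unreg <- truth$gene[!truth$regulated]
    if (n_decoys > length(unreg)) stop("not enough unregulated genes for decoys")
    bound <- character(0)
    n_cov <- round(coverage * length(reg))
    if (n_cov > 0) bound <- sample(reg, n_cov)
    if (n_decoys > 0) bound <- c(bound, sample(unreg, n_decoys))
    sort(bound)
  })
}

#' Write a simulated experiment to a directory as plain text
#'
#' Intensities and detection scores as gene-in-rows TSV, the annotation and
#' truth tables as TSV.
#'
#' @param sim result of [simulate_experiment()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(sim$nro, file.path(dir, "nro.tsv"))
  write_expression_matrix(sim$total, file.path(dir, "total.tsv"))
  utils::write.table(sim$annotation, file.path(dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
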