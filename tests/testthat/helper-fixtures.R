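# shared fixtures, built once per test run

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# a mid-sized paired experiment under the default study conditions
wave_sim <- function() fixture("wave_sim", function()
  simulate_experiment(sim_config(n_genes = 4000, seed = 101)))

# per-channel preprocessing + per-timepoint DE for a simulated experiment
channel_analysis <- function(sim, source = c("NRO", "TOTAL"),
                             thresholds = significance_thresholds()) {
  source <- match.arg(source)
  em <- if (source == "NRO") sim$nro else sim$total
  ann <- sim$annotation[sim$annotation$rna_source == source, ]
  em <- filter_undetected(em)
  z <- ztransform_array(em)
  tps <- setdiff(sort(unique(ann$timepoint_hr)), 0)
  de <- lapply(tps, function(tp) de_stats(em, z, ann, tp, 0, thresholds))
  names(de) <- tps
  list(em = em, z = z, ann = ann, de = de,
       waves = wave_table(de, thresholds))
}

wave_analysis <- function() fixture("wave_analysis", function() {
  sim <- wave_sim()
  list(sim = sim,
       nro = channel_analysis(sim, "NRO"),
       total = channel_analysis(sim, "TOTAL"))
})

# small toy matrix with hand-set detection scores
toy_matrix <- function() {
  x <- matrix(10^stats::runif(30, 1, 3), 10, 3,
              dimnames = list(sprintf("G%02d", 1:10), paste0("s", 1:3)))
  d <- matrix(1, 10, 3, dimnames = dimnames(x))
  d[c(2, 5, 9), ] <- 0.5                       # consistently below threshold
  d[4, ] <- c(0.5, 0.99, 0.5)                  # detected once -> retained
  expression_matrix(x, detection = d, rna_source = "TOTAL")
}

# contrast annotation table for hand-built enrichment matrices
parse_info <- function(contrasts) data.frame(
  contrast = contrasts,
  rna_source = sub("_.*", "", contrasts),
  timepoint_hr = as.numeric(sub(".*_", "", contrasts)),
  stringsAsFactors = FALSE)
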