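test_that("the generator is deterministic for a fixed config and seed", {
  cfg <- sim_config(n_genes = 300, seed = 9)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$nro$intensity, b$nro$intensity)
  expect_identical(a$total$intensity, b$total$intensity)
  expect_identical(a$truth, b$truth)
  # and sensitive to the seed
  c <- simulate_experiment(sim_config(n_genes = 300, seed = 10))
  expect_false(identical(a$nro$intensity, c$nro$intensity))
})

test_that("planted truth matches the requested design", {
  cfg <- sim_config(n_genes = 1000, fraction_regulated = 0.1,
                    wave_mix = c(early = 1, delayed_early = 0, late = 0,
                                 transient_early = 0), seed = 2)
  sim <- simulate_experiment(cfg)
  expect_equal(sum(sim$truth$regulated), 100)
  expect_equal(sum(sim$truth$wave == "early", na.rm = TRUE), 100)
  # null construction
  null_sim <- simulate_experiment(sim_config(n_genes = 200,
                                             fraction_regulated = 0, seed = 2))
  expect_equal(sum(null_sim$truth$regulated), 0)
})

test_that("truth invariants hold: onset order, transience, positivity", {
  sim <- wave_sim()
  tr <- sim$truth[sim$truth$regulated, ]
  expect_true(all(tr$total_onset_hr >= tr$nro_onset_hr))
  expect_true(all(tr$persists_at_48h == (tr$wave != "transient_early")))
  expect_true(all(sim$nro$intensity > 0))
  expect_true(all(sim$total$intensity > 0))
  # onsets respect the wave windows on the default grid
  expect_true(all(tr$nro_onset_hr[tr$wave %in% c("early", "transient_early")] <= 1))
  expect_true(all(tr$nro_onset_hr[tr$wave == "delayed_early"] %in% c(3, 6)))
  expect_true(all(tr$nro_onset_hr[tr$wave == "late"] == 48))
})

test_that("background genes fail the detection filter in every sample", {
  sim <- wave_sim()
  bg <- sim$truth$background
  expect_true(all(sim$nro$detection[bg, ] < 0.98))
  expect_true(all(sim$nro$detection[!bg, ] >= 0.98))
  kept <- filter_undetected(sim$nro)
  expect_setequal(rownames(kept$intensity), sim$truth$gene[!bg])
})

test_that("unregulated genes keep a constant mean log intensity over time", {
  sim <- wave_sim()
  cfg_noise <- 0.2
  ann <- sim$annotation[sim$annotation$rna_source == "NRO", ]
  unreg <- !sim$truth$regulated
  lx <- log2(sim$nro$intensity[unreg, ])
  tp_means <- vapply(split(seq_len(nrow(ann)), ann$timepoint_hr),
                     function(i) mean(lx[, i]), numeric(1))
  n_arrays_min <- 6 * sum(unreg)
  expect_lt(max(abs(tp_means - mean(lx))), 3 * cfg_noise / sqrt(n_arrays_min))
})

test_that("noise-free expectations recover the planted effect exactly", {
  cfg <- sim_config(n_genes = 200, noise_sd_log = 1e-6, seed = 5)
  sim <- simulate_experiment(cfg)
  ann <- sim$annotation[sim$annotation$rna_source == "NRO", ]
  lr <- log_ratio(sim$nro, ann)
  tr <- sim$truth
  for (g in which(tr$regulated)) {
    tp <- as.numeric(colnames(lr))
    expected <- ifelse(tp >= tr$nro_onset_hr[g], tr$effect_log2[g], 0)
    if (tr$wave[g] == "transient_early") expected[length(expected)] <- 0
    expect_equal(unname(lr[g, ]), expected, tolerance = 1e-4)
  }
})

test_that("simulated gene sets encode their ground truth", {
  sim <- wave_sim()
  gs <- simulate_genesets(sim$truth, n_planted = 4, n_null = 5,
                          set_size = 20, seed = 3)
  expect_length(gs, 9)
  planted <- grep("^PLANTED_", names(gs$sets), value = TRUE)
  expect_length(planted, 4)
  for (nm in planted) {
    cls <- tolower(sub("^PLANTED_([A-Z_]+)_\\d+$", "\\1", nm))
    members <- gs$sets[[nm]]
    tr <- sim$truth[match(members, sim$truth$gene), ]
    expect_true(all(tr$regulated))
    expect_true(all(tr$wave == cls))
  }
  # all-null collections and determinism
  nulls <- simulate_genesets(sim$truth, 0, 5, 10, seed = 4)
  expect_true(all(grepl("^NULL_", names(nulls$sets))))
  expect_identical(simulate_genesets(sim$truth, 2, 2, 10, seed = 7),
                   simulate_genesets(sim$truth, 2, 2, 10, seed = 7))
})

test_that("two-platform tables converge to correlation 1 as noise vanishes", {
  sim <- wave_sim()
  pl <- simulate_two_platforms(sim$truth, shared_genes = 2000,
                               platform_noise_sd = 1e-6, seed = 11)
  expect_gt(cor(pl$a$logratio, pl$b$logratio), 0.999999)
  expect_error(simulate_two_platforms(sim$truth, 100, 0), "positive")
})

test_that("ChIP lists hold the stated coverage plus decoys", {
  sim <- wave_sim()
  reg <- sim$truth$gene[sim$truth$regulated]
  expect_setequal(simulate_chip_list(sim$truth, coverage = 1, n_decoys = 0,
                                     seed = 1), reg)
  only_decoys <- simulate_chip_list(sim$truth, coverage = 0, n_decoys = 50,
                                    seed = 1)
  expect_length(only_decoys, 50)
  expect_length(intersect(only_decoys, reg), 0)
  expect_identical(simulate_chip_list(sim$truth, 0.5, 10, seed = 8),
                   simulate_chip_list(sim$truth, 0.5, 10, seed = 8))
})

test_that("invalid configurations are refused", {
  expect_error(sim_config(n_genes = 0), "positive")
  expect_error(sim_config(fraction_regulated = 0.7, fraction_background = 0.5),
               "fraction")
  expect_error(sim_config(timepoints_hr = c(0, 2, 1)), "increasing")
  expect_error(sim_config(effect_log2 = -1), "positive")
  expect_error(sim_config(noise_sd_log = 0), "positive")
  expect_error(sim_config(wave_mix = c(early = 0.5, delayed_early = 0.5,
                                       late = 0.5, transient_early = 0.5)),
               "sum")
})
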