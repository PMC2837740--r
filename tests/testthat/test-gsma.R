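test_that("the PAGE statistic reproduces its hand-computed components", {
  lr <- c(A1 = -2, B1 = -1, C1 = 0, D1 = 1, E1 = 2)
  res <- page_z(c("D1", "E1"), lr)
  expect_equal(res$Sm, 1.5)
  expect_equal(res$mu, 0)
  expect_equal(res$sigma, sqrt(2.5))
  expect_equal(res$m, 2)
  expect_equal(res$z, 1.5 * sqrt(2) / sqrt(2.5), tolerance = 1e-12)  # 1.342
  # set at the universe median scores zero
  expect_equal(page_z(c("B1", "C1", "D1"), lr)$z, 0)
  # members absent from the universe are dropped, m reflects the intersection
  expect_equal(page_z(c("D1", "E1", "ZZ9"), lr)$m, 2)
  expect_error(page_z("ZZ9", lr), "no set member")
  expect_error(page_z("A1", c(A1 = 1, B1 = 1, C1 = 1)), "zero variance")
})

test_that("PAGE is invariant to positive affine transforms of the log-ratios", {
  set.seed(5)
  lr <- setNames(rnorm(200), sprintf("G%03d", 1:200))
  set <- sample(names(lr), 17)
  z0 <- page_z(set, lr)$z
  expect_equal(page_z(set, lr + 3.7)$z, z0, tolerance = 1e-12)
  expect_equal(page_z(set, 2.5 * lr - 1)$z, z0, tolerance = 1e-12)
})

test_that("PAGE agrees with an independent straight-line recomputation", {
  set.seed(17)
  for (i in 1:100) {
    n <- sample(10:200, 1)
    lr <- setNames(rnorm(n), sprintf("G%04d", seq_len(n)))
    set <- sample(names(lr), sample(seq_len(min(n, 40)), 1))
    got <- page_z(set, lr)
    want <- oracle_page(set, lr)
    expect_equal(got$z, want$z, tolerance = 1e-12)
    expect_equal(got$Sm, want$Sm)
    expect_equal(got$m, want$m)
  }
})

test_that("the enrichment matrix applies PAGE per set per contrast", {
  lr <- cbind(NRO_1 = c(A1 = -2, B1 = -1, C1 = 0, D1 = 1, E1 = 2),
              NRO_48 = c(2, 1, 0, -1, -2))
  coll <- gene_sets(list(S1 = c("D1", "E1"), ABSENT = c("X1", "Y1")))
  em <- gsma_matrix(coll, lr)
  expect_equal(em$z["S1", "NRO_1"], 1.5 * sqrt(2) / sqrt(2.5), tolerance = 1e-12)
  expect_equal(em$z["S1", "NRO_48"], -1.5 * sqrt(2) / sqrt(2.5), tolerance = 1e-12)
  # absent sets give flagged missing cells, never silent zeros
  expect_true(all(is.na(em$z["ABSENT", ])))
  expect_true(all(em$m["ABSENT", ] == 0))
  # every reported z is reproducible from its own components
  expect_equal(em$z["S1", "NRO_1"],
               (em$Sm["S1", "NRO_1"] - em$mu[["NRO_1"]]) *
                 sqrt(em$m["S1", "NRO_1"]) / em$sigma[["NRO_1"]])
  expect_error(gsma_matrix(coll, lr[, 0, drop = FALSE]), "")
})

test_that("cell significance is two-sided normal with BH across sets", {
  set.seed(9)
  lr <- matrix(rnorm(300), 100, 3,
               dimnames = list(sprintf("G%03d", 1:100),
                               c("NRO_1", "NRO_48", "TOTAL_48")))
  coll <- gene_sets(setNames(lapply(1:8, function(i)
    sample(rownames(lr), 10)), paste0("S", 1:8)))
  em <- enrichment_significance(gsma_matrix(coll, lr))
  expect_equal(em$p, 2 * pnorm(-abs(em$z)), tolerance = 1e-12)
  for (j in seq_len(ncol(em$p)))
    expect_equal(em$q[, j], fdr(em$p[, j]), tolerance = 1e-12,
                 ignore_attr = TRUE)
})

test_that("sets are ordered by first NRO appearance, then fallback |z|", {
  z <- rbind(SET_A = c(3, 3, 3), SET_B = c(0, 3, 3), SET_C = c(0, 0, -4),
             SET_D = c(0, 0, 1))
  colnames(z) <- c("NRO_0.25", "NRO_3", "NRO_48")
  em <- structure(list(z = z, contrast_info = parse_info(colnames(z))),
                  class = "anro_enrichment")
  ord <- sort_by_first_appearance(em, z_threshold = 1.96)
  expect_equal(ord$set, c("SET_A", "SET_B", "SET_C", "SET_D"))
  expect_equal(ord$first_up_hr, c(0.25, 3, NA, NA))
  # never-significant rows fall back to |z| at the final NRO contrast
  expect_true(abs(ord$z_final_nro[3]) > abs(ord$z_final_nro[4]))
  no_nro <- structure(list(z = z, contrast_info = parse_info(c("TOTAL_1",
                                                               "TOTAL_3",
                                                               "TOTAL_48"))),
                      class = "anro_enrichment")
  expect_error(sort_by_first_appearance(no_nro), "NRO")
})

test_that("GMT files round-trip and normalize symbols", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("SETA\tdesc\tTP53\tMYC", "SETB\t\tegfr\tkras\tEGFR"), path)
  coll <- read_gmt(path)
  expect_equal(coll$sets$SETA, c("TP53", "MYC"))
  expect_equal(coll$sets$SETB, c("EGFR", "KRAS"))   # uppercased, deduplicated
  out <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(coll, out)
  expect_identical(read_gmt(out), coll)
  writeLines("BAD\tonly-two-fields", path)
  expect_error(read_gmt(path), "3 fields")
  expect_error(gene_sets(list(S1 = "A", S1 = "B")), "duplicate")
  expect_error(gene_sets(list(S1 = character(0))), "nonempty")
})

test_that("planted gene sets dominate null sets in their planted contrast", {
  wa <- wave_analysis()
  sim <- wa$sim
  gs <- simulate_genesets(sim$truth, n_planted = 4, n_null = 60,
                          set_size = 30, seed = 21)
  lr <- cbind(log_ratio(wa$nro$em, wa$nro$ann),
              log_ratio(wa$total$em, wa$total$ann))
  colnames(lr) <- c(paste0("NRO_", c(0, 0.25, 0.5, 1, 3, 6, 48)),
                    paste0("TOTAL_", c(0, 0.25, 0.5, 1, 3, 6, 48)))
  em <- gsma_matrix(gs, lr[, !grepl("_0$", colnames(lr))])
  planted_contrast <- c(early = "NRO_1", delayed_early = "NRO_6",
                        late = "NRO_48", transient_early = "NRO_1")
  null_names <- grep("^NULL_", rownames(em$z), value = TRUE)
  for (nm in grep("^PLANTED_", rownames(em$z), value = TRUE)) {
    cls <- tolower(sub("^PLANTED_([A-Z_]+)_\\d+$", "\\1", nm))
    ct <- planted_contrast[[cls]]
    expect_gt(abs(em$z[nm, ct]), max(abs(em$z[null_names, ct])))
  }
  # null z scores center on zero
  znull <- em$z[null_names, "NRO_48"]
  expect_lt(abs(mean(znull)), 3 * sd(znull) / sqrt(length(znull)))
})
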