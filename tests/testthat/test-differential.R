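zmat <- function(d) matrix(d, length(d), 1,
                           dimnames = list(paste0("G", seq_along(d)), "a1"))

test_that("Z-ratios divide mean z differences by their SD over genes", {
  d <- c(0.5, -0.5, 1.5, -1.5)
  zr <- z_ratio(zmat(d), zmat(rep(0, 4)))
  expect_equal(unname(zr), d / sqrt(5 / 3), tolerance = 1e-12)
  expect_equal(unname(round(zr, 3)), c(0.387, -0.387, 1.162, -1.162))
  # antisymmetry and self-normalization
  expect_equal(z_ratio(zmat(rep(0, 4)), zmat(d)), -zr, tolerance = 1e-12)
  expect_equal(sd(zr), 1, tolerance = 1e-12)
  # degenerate: identical groups
  expect_error(z_ratio(zmat(d), zmat(d)), "zero variance")
  # replicate averaging: mean of the group's z-scores per gene
  zA <- cbind(a1 = c(1, 0), a2 = c(3, 0)); rownames(zA) <- c("G1", "G2")
  zB <- cbind(b1 = c(0, 1), b2 = c(0, 3)); rownames(zB) <- c("G1", "G2")
  expect_equal(unname(z_ratio(zA, zB)), c(2, -2) / sd(c(2, -2)))
})

test_that("Z-test p-values come from the two-sided standard normal", {
  expect_equal(z_test_pvalues(0), 1)
  expect_equal(z_test_pvalues(1.959964), 0.05, tolerance = 1e-6)
  z <- seq(0, 6, by = 0.25)
  p <- z_test_pvalues(z)
  expect_true(all(diff(p) < 0))                 # monotone in |z|
  expect_equal(z_test_pvalues(-z), p)           # symmetric
  expect_error(z_test_pvalues(c(1, Inf)), "finite")
})

test_that("FDR adjustment matches step-up BH computed from its definition", {
  expect_equal(fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr(rep(1, 5)), rep(1, 5))
  expect_equal(fdr(0.037), 0.037)               # single p
  set.seed(7)
  for (p in list(runif(50), rbeta(200, 0.3, 1))) {
    q <- fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    o <- order(p)
    expect_true(all(diff(q[o]) >= 0))           # monotone in p
  }
  expect_error(fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the compound filter is p AND q AND (fold OR z-ratio)", {
  th <- significance_thresholds()
  # every combination of the four clauses, evaluated independently
  grid <- expand.grid(p_ok = c(TRUE, FALSE), q_ok = c(TRUE, FALSE),
                      fold_ok = c(TRUE, FALSE), z_ok = c(TRUE, FALSE))
  stats <- data.frame(
    p = ifelse(grid$p_ok, 0.0005, 0.002),
    q = ifelse(grid$q_ok, 0.05, 0.2),
    fold_change = ifelse(grid$fold_ok, 2.0, 1.2),
    z_ratio = ifelse(grid$z_ok, 3.5, 1.0))
  expect_equal(passes_filter(stats, th),
               grid$p_ok & grid$q_ok & (grid$fold_ok | grid$z_ok))
  # spec'd spot checks: fold clause alone, z clause alone, p clause veto
  expect_true(passes_filter(data.frame(p = 5e-4, q = 0.05, fold_change = 2,
                                       z_ratio = 1), th))
  expect_true(passes_filter(data.frame(p = 5e-4, q = 0.05, fold_change = 1.2,
                                       z_ratio = 3.5), th))
  expect_false(passes_filter(data.frame(p = 0.002, q = 0.01, fold_change = 10,
                                        z_ratio = 10), th))
  # down-regulation passes the fold clause through the reciprocal
  expect_true(passes_filter(data.frame(p = 5e-4, q = 0.05, fold_change = 0.5,
                                       z_ratio = 1), th))
  expect_error(passes_filter(data.frame(p = 0.1)), "columns")
})

test_that("boundary values are inclusive, per the at-most / at-least wording", {
  th <- significance_thresholds()
  at_bound <- data.frame(p = 0.001, q = 0.1, fold_change = 1.5, z_ratio = 0)
  expect_true(passes_filter(at_bound, th))
  z_bound <- data.frame(p = 0.001, q = 0.1, fold_change = 1.0, z_ratio = 3.0)
  expect_true(passes_filter(z_bound, th))
})

test_that("DE statistics carry coherent signs, folds and directions", {
  an <- wave_analysis()$nro
  d48 <- an$de[["48"]]
  expect_true(all(d48$q >= d48$p))
  expect_equal(sd(d48$z_ratio), 1, tolerance = 1e-12)
  expect_equal(d48$direction, ifelse(d48$mean_logratio >= 0, "up", "down"))
  expect_equal(d48$mean_logratio, log2(d48$fold_change), tolerance = 1e-12)
  neg <- d48$fold_change < 1
  expect_equal(d48$fold_signed[neg], -1 / d48$fold_change[neg])
  expect_equal(d48$fold_signed[!neg], d48$fold_change[!neg])
  # significant_genes returns the flagged rows, strongest first
  sig <- significant_genes(d48)
  expect_true(all(sig$passes_filter))
  expect_true(all(diff(abs(sig$z_ratio)) <= 0))
  expect_true(all(significant_genes(d48, direction = "up")$direction == "up"))
})

test_that("planted regulated genes are recovered at high power", {
  wa <- wave_analysis()
  truth <- wa$sim$truth
  d48 <- wa$nro$de[["48"]]
  persistent <- truth$gene[truth$regulated & truth$persists_at_48h]
  hit <- d48$passes_filter[match(persistent, d48$gene)]
  expect_gte(mean(hit), 0.9)
})

test_that("qPCR fold change is 2 to the minus mean ddCt", {
  expect_equal(ddct_fold_change(-2), 4)
  expect_equal(ddct_fold_change(0), 1)
  expect_equal(ddct_fold_change(c(-1, -3)), 4)
  tab <- data.frame(ct_target_treated = c(20, 20), ct_ref_treated = c(18, 18),
                    ct_target_control = c(24, 24), ct_ref_control = c(18, 18))
  expect_equal(ddct_fold_change(tab), 16)       # ddCt = -4 per replicate
  expect_error(ddct_fold_change(numeric(0)), "replicate")
  expect_error(ddct_fold_change(c(1, NA)), "finite")
})
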