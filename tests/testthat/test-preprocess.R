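sheet4 <- make_sheet(4)

test_that("beta and M formulas reproduce hand-computed values", {
  m <- matrix(c(300, 0, 900, 100, 300, 700), 3, 2)
  u <- matrix(c(100, 0, 0, 100, 100, 100), 3, 2)
  b <- compute_beta(m, u, alpha = 100)
  expect_equal(as.vector(b), c(0.6, 0, 0.9, 100 / 300, 0.6, 700 / 900))
  mm <- compute_m(m, u, alpha = 100)
  expect_equal(as.vector(mm)[4:6], c(0, 1, 2))
  expect_error(compute_beta(-m, u), "negative")
  expect_error(compute_m(m, -u), "negative")
  expect_error(compute_beta(m, u, alpha = 0), "alpha")
})

test_that("logit2 bridge is exact and clamps boundary values", {
  expect_equal(as.vector(beta_to_m(c(0.5, 0.8, 0.2))), c(0, 2, -2))
  expect_warning(m0 <- beta_to_m(c(0, 1)), "clamped")
  expect_true(all(is.finite(m0)))
  expect_equal(as.vector(m_to_beta(beta_to_m(0.37))), 0.37, tolerance = 1e-12)
})

test_that("intensity and bridge M-values agree when the offset vanishes", {
  set.seed(7)
  m <- matrix(runif(200, 750, 5000), 20, 10)
  u <- matrix(runif(200, 750, 5000), 20, 10)
  # alpha = 0 limit: exact identity
  expect_equal(unname(compute_m(m, u, alpha = 1e-12)),
               unname(beta_to_m(compute_beta(m, u, alpha = 1e-12))),
               tolerance = 1e-6, ignore_attr = TRUE)
  # alpha = 100 at high intensity: within 0.2 M-units.  The deviation is
  # exactly log2(1 + alpha/m), so it is bounded by 0.2 once the methylated
  # channel exceeds ~700 (the offset vanishes with intensity).
  d <- abs(compute_m(m, u, 100) - beta_to_m(compute_beta(m, u, 100)))
  expect_lt(max(d), 0.2)
  expect_equal(max(d), max(log2(1 + 100 / m)), tolerance = 1e-10)
})

test_that("beta and M are strictly increasing in methylated signal", {
  m <- matrix(seq(0, 5000, length.out = 50), 50, 1)
  u <- matrix(500, 50, 1)
  expect_true(all(diff(compute_beta(m, u, 100)) > 0))
  expect_true(all(diff(compute_m(m, u, 100)) > 0))
})

test_that("detection filter excludes a probe failing in any sample", {
  p <- make_matrix(0.001, 3, sheet4)
  expect_equal(detection_filter(p), rownames(p))
  p["cg0002", 5] <- 0.02
  expect_equal(detection_filter(p), c("cg0001", "cg0003"))
  expect_equal(detection_filter(p, threshold = 1), rownames(p))
  p["cg0001", 1] <- 1.5
  expect_error(detection_filter(p), "0, 1")
})

test_that("SNP filter drops flagged probes and demands full coverage", {
  ann <- data.frame(probe_id = sprintf("cg%04d", 1:10),
                    snp_overlap = c(rep(TRUE, 3), rep(FALSE, 7)))
  expect_equal(snp_filter(ann), sprintf("cg%04d", 4:10))
  ann$snp_overlap <- FALSE
  expect_equal(snp_filter(ann), ann$probe_id)
  ann$snp_overlap <- TRUE
  expect_warning(none <- snp_filter(ann), "empty")
  expect_length(none, 0L)
  expect_error(snp_filter(ann, probes = "cg9999"), "cg9999")
})

test_that("detection and SNP filters commute (set intersection)", {
  sim <- simulate_dataset(sim_config(n_sites = 500, seed = 13,
                                     frac_detection_fail = 0.005))
  k1 <- intersect(detection_filter(sim$detp),
                  snp_filter(sim$annotation))
  k2 <- intersect(snp_filter(sim$annotation),
                  detection_filter(sim$detp))
  expect_setequal(k1, k2)
})

test_that("batch correction handles identity, pure shifts and noise", {
  sheet1 <- make_sheet(6)
  M <- make_matrix(rnorm(60), 5, sheet1)
  expect_message(out <- batch_correct(M, sheet1), "single batch")
  expect_identical(unname(out), unname(M))

  # two batches differing by a constant shift at every site, no noise:
  # the shift is fully absorbed
  sheet2 <- make_sheet(6, batches = rep(c("b1", "b2"), each = 3))
  base <- make_matrix(rep(seq(-2, 2, length.out = 5), 12), 5, sheet2)
  shift <- matrix(0, 5, 12,
                  dimnames = dimnames(base))
  in_b2 <- sheet2$batch[match(colnames(base), sheet2$sample_id)] == "b2"
  shift[, in_b2] <- 1
  cor0 <- batch_correct(base + shift, sheet2)
  bm <- function(X) rowMeans(X[, in_b2]) - rowMeans(X[, !in_b2])
  expect_lt(max(abs(bm(cor0))), 1e-6)

  # batch with < 2 samples
  sheet_bad <- make_sheet(3, batches = c("b1", "b1", "b2"))
  sheet_bad$batch[sheet_bad$subject_id == "P03"] <- c("b2", "b3")
  Mb <- make_matrix(rnorm(30), 5, sheet_bad)
  expect_error(batch_correct(Mb, sheet_bad), "fewer than 2")
})

test_that("batch correction shrinks planted batch effects and preserves means", {
  sim <- simulate_dataset(sim_config(n_sites = 2000, batch_shift = 1,
                                     noise_sd = 0.2, frac_smp = 0,
                                     frac_dmp = 0, seed = 42))
  M <- sim$mvalues
  in_b2 <- sim$sheet$batch[match(colnames(M), sim$sheet$sample_id)] == "batch2"
  gap <- function(X) mean(abs(rowMeans(X[, in_b2]) - rowMeans(X[, !in_b2])))
  Mc <- batch_correct(M, sim$sheet)
  expect_gte(gap(M) / gap(Mc), 5)
  # location adjustments are residual-space: site means preserved
  expect_lt(max(abs(rowMeans(Mc) - rowMeans(M))), 1e-9)
  # tissue signal is protected: tissue contrast essentially unchanged
  bone <- sim$sheet$tissue[match(colnames(M), sim$sheet$sample_id)] == "bone"
  tc <- function(X) rowMeans(X[, bone]) - rowMeans(X[, !bone])
  expect_lt(max(abs(tc(Mc) - tc(M))), 0.1)
})

test_that("batch correction agrees with the reference implementation", {
  sim <- simulate_dataset(sim_config(n_sites = 500, batch_shift = 1,
                                     noise_sd = 0.2, seed = 43))
  M <- sim$mvalues
  sheet <- sim$sheet[match(colnames(M), sim$sheet$sample_id), ]
  mine <- batch_correct(M, sim$sheet)
  ref <- sva::ComBat(M, batch = sheet$batch,
                     mod = model.matrix(~ factor(tissue), data = sheet))
  expect_gt(cor(as.vector(mine), as.vector(ref)), 0.999)
  expect_lt(mean(abs(mine - ref)), 0.05)
})

test_that("the preprocessing pipeline chains filters and correction", {
  sim <- simulate_dataset(sim_config(n_sites = 800, seed = 14,
                                     frac_detection_fail = 0.003))
  pp <- preprocess_pipeline(m = sim$intensities$m, u = sim$intensities$u,
                            detp = sim$detp, annotation = sim$annotation,
                            sheet = sim$sheet)
  expect_equal(pp$qc$n_input, 800L)
  expect_equal(pp$qc$n_kept, length(pp$probes))
  expect_identical(rownames(pp$beta), pp$probes)
  expect_identical(rownames(pp$mvalues), pp$probes)
  expect_equal(pp$qc$n_input - pp$qc$n_failed_detection - pp$qc$n_snp_removed,
               pp$qc$n_kept)
  expect_equal(nrow(pp$qc$sample_medians), 24L)
  # beta-only path uses the logit2 bridge
  pp2 <- preprocess_pipeline(beta = sim$beta, detp = sim$detp,
                             annotation = sim$annotation, sheet = sim$sheet,
                             correct_batch = FALSE)
  expect_equal(unname(pp2$mvalues),
               unname(sim$mvalues[pp2$probes, ]), tolerance = 1e-10,
               ignore_attr = TRUE)
})
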