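test_that("candidate restriction removes DMP-significant sites", {
  ids <- sprintf("cg%02d", 1:10)
  q <- c(rep(0.01, 4), rep(0.5, 6))
  expect_equal(candidate_sites(ids, q), ids[5:10])
  expect_equal(candidate_sites(ids, rep(0.9, 10)), ids)
  expect_error(candidate_sites(ids, q[1:9]), "every probe")
  expect_error(candidate_sites(ids, replace(q, 3, NA)), "every probe")
  # named q-vectors are aligned by probe id, not position
  qn <- setNames(rev(q), rev(ids))
  expect_equal(candidate_sites(ids, qn), ids[5:10])
})

test_that("per-site correlations match hand-computed values", {
  sheet <- make_sheet(3)
  M <- make_matrix(0, 3, sheet)
  M[1, ] <- c(1, 2, 3, 1, 2, 3)    # bone then blood, subject-aligned
  M[2, ] <- c(1, 2, 3, 3, 2, 1)
  M[3, ] <- c(1, 2, 3, 1, 2, 4)
  r <- sitewise_pair_correlation(M, sheet)
  expect_equal(unname(r[1]), 1)
  expect_equal(unname(r[2]), -1)
  expect_equal(unname(r[3]), 0.9820, tolerance = 1e-4)
  # hand oracle: cov / (sd * sd) = 1.5 / (1 * 1.527525)
  expect_equal(unname(r[3]), 1.5 / (1 * sd(c(1, 2, 4))), tolerance = 1e-12)
})

test_that("correlation is symmetric in tissue order and affine-invariant", {
  sim <- simulate_dataset(sim_config(n_sites = 100, seed = 19))
  r1 <- sitewise_pair_correlation(sim$mvalues, sim$sheet)
  swapped <- sim$sheet
  swapped$tissue <- ifelse(swapped$tissue == "bone", "blood", "bone")
  r2 <- sitewise_pair_correlation(sim$mvalues, swapped)
  expect_equal(unname(r1), unname(r2), tolerance = 1e-12)

  # positive-slope affine transform of one tissue leaves r unchanged
  M3 <- sim$mvalues
  bone <- sim$sheet$sample_id[sim$sheet$tissue == "bone"]
  M3[, bone] <- 2.5 * M3[, bone] + 7
  r3 <- sitewise_pair_correlation(M3, sim$sheet)
  expect_equal(unname(r1), unname(r3), tolerance = 1e-10)
})

test_that("zero-variance sites yield NaN and are excluded from testing", {
  sheet <- make_sheet(3)
  M <- make_matrix(rnorm(12), 2, sheet)
  M[2, sheet$tissue == "bone"] <- 5
  expect_message(r <- sitewise_pair_correlation(M, sheet), "zero variance")
  expect_true(is.nan(r[2]))
  ct <- correlation_test(r, 3)
  expect_true(is.nan(ct$p[2]))
})

test_that("the correlation t-test matches its closed form and an integration oracle", {
  ct <- correlation_test(0, 12)
  expect_equal(ct$t_r, 0)
  expect_equal(ct$p, 1)

  # the study's shortlist bound: r = 0.74 at n = 12
  ct74 <- correlation_test(0.74, 12)
  expect_equal(ct74$t_r, 3.479, tolerance = 1e-3)
  expect_equal(ct74$p, 0.0059, tolerance = 1e-2)

  # independent oracle: two-sided p by numerical integration of the t density
  t_density <- function(x, df)
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  for (r in seq(0.1, 0.9, by = 0.2)) {
    ct_r <- correlation_test(r, 12)
    p_num <- 2 * integrate(t_density, lower = abs(ct_r$t_r), upper = Inf,
                           df = 10, rel.tol = 1e-12)$value
    expect_equal(ct_r$p, p_num, tolerance = 1e-8)
  }

  # limits and conventions
  expect_message(ct1 <- correlation_test(c(1, -1), 5), "convention")
  expect_equal(ct1$p, c(0, 0))
  expect_true(all(diff(correlation_test(seq(0.5, 0.999, 0.05), 12)$p) < 0))
  expect_error(correlation_test(0.5, 2), "n >= 3")
})

test_that("max paired delta-beta takes the per-pair maximum", {
  sheet <- make_sheet(3)
  b <- make_matrix(0.5, 2, sheet)
  b[1, sheet$tissue == "bone"] <- c(0.55, 0.60, 0.65)
  b[2, sheet$tissue == "bone"] <- c(0.75, 0.51, 0.49)
  db <- max_pair_delta_beta(b, sheet)
  expect_equal(unname(db), c(0.15, 0.25), tolerance = 1e-12)
  expect_equal(unname(max_pair_delta_beta(make_matrix(0.4, 1, sheet), sheet)), 0)
})

test_that("SMP calling enforces q, similarity and positive-r filters", {
  tab <- call_smps(probe_ids = c("a", "b", "c", "d"),
                   r = c(0.95, 0.95, -0.95, 0.9),
                   t_r = c(9, 9, -9, 6),
                   p = c(1e-4, 1e-4, 1e-4, 1e-3),
                   max_pair_dbeta = c(0.05, 0.30, 0.05, 0.1),
                   beta_mean = c(0.1, 0.5, 0.5, 0.9))
  expect_equal(tab$is_smp, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(tab$beta_class, c("hypo", "mid", "mid", "hyper"))
  expect_error(call_smps("a", 0.5, 1, 0.5, 0.1, 0.5, q_threshold = 0),
               "q_threshold")
})

test_that("SMP and DMP calls are mutually exclusive by construction", {
  sim <- simulate_dataset(sim_config(n_sites = 1500, seed = 23))
  M <- batch_correct(sim$mvalues, sim$sheet)
  dmp <- suppressMessages(dmp_analysis(M, sim$beta, sim$sheet))
  smp <- smp_analysis(M, sim$beta, sim$sheet,
                      dmp_q = setNames(dmp$q, dmp$probe_id))
  both <- intersect(smp$probe_id[smp$is_smp], dmp$probe_id[dmp$is_dmp])
  expect_length(both, 0L)
  # candidates are exactly the q >= 0.05 sites
  expect_setequal(smp$probe_id, dmp$probe_id[dmp$q >= 0.05])
})

test_that("the dbeta rule switch selects mean instead of max", {
  sim <- simulate_dataset(sim_config(n_sites = 300, seed = 24))
  smax <- smp_analysis(sim$mvalues, sim$beta, sim$sheet, dbeta_rule = "max")
  smean <- smp_analysis(sim$mvalues, sim$beta, sim$sheet, dbeta_rule = "mean")
  expect_true(all(smean$max_pair_dbeta <= smax$max_pair_dbeta + 1e-12))
  # the max rule is the stricter filter: its SMP set is a subset
  expect_true(all(smax$is_smp <= smean$is_smp |
                    smax$max_pair_dbeta == smean$max_pair_dbeta))
})

test_that("permutation null is reproducible and degenerates correctly", {
  sim <- simulate_dataset(sim_config(n_sites = 400, frac_smp = 0.3,
                                     batch_shift = 0, seed = 25))
  M <- sim$mvalues; B <- sim$beta
  p1 <- suppressWarnings(
    permutation_null(M, B, sim$sheet, n_iterations = 50, seed = 7))
  p2 <- suppressWarnings(
    permutation_null(M, B, sim$sheet, n_iterations = 50, seed = 7))
  expect_identical(p1$null_counts, p2$null_counts)
  expect_identical(p1$p_empirical, p2$p_empirical)

  # forcing the identity permutation: every null count equals the observed
  pid <- suppressWarnings(
    permutation_null(M, B, sim$sheet, n_iterations = 20, seed = 7,
                     perm_fun = function(n) seq_len(n)))
  expect_true(all(pid$null_counts == pid$observed))
  expect_equal(pid$p_empirical, 1)

  expect_warning(permutation_null(M, B, sim$sheet, n_iterations = 10,
                                  seed = 1), "unstable")
})

test_that("permutation results serialise to JSON", {
  sim <- simulate_dataset(sim_config(n_sites = 200, seed = 26))
  pn <- suppressWarnings(
    permutation_null(sim$mvalues, sim$beta, sim$sheet,
                     n_iterations = 30, seed = 2))
  f <- tempfile(fileext = ".json")
  write_permutation_json(pn, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$observed, pn$observed)
  expect_equal(back$p_empirical, pn$p_empirical)
  expect_equal(sum(unlist(back$null_count_histogram$frequency)), 30L)
})
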