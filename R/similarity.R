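#' Candidate sites for similarity testing
#'
#' Similarly methylated positions are searched only among sites that are
#' \emph{not} statistically differentially methylated: probes whose
#' DMP-stage q-value is at or above `q_threshold`.
#'
#' @param probe_ids Character vector of all analysis probes.
#' @param dmp_q Named or aligned numeric vector of DMP-stage q-values, one
#'   per probe; a missing q for any probe is an error.
#' @param q_threshold Exclusion threshold (default 0.05).
#' @return Character vector of candidate probe ids, in input order.
#' @export
candidate_sites <- function(probe_ids, dmp_q, q_threshold = 0.05) {
  if (!is.null(names(dmp_q))) dmp_q <- dmp_q[probe_ids]
  if (length(dmp_q) != length(probe_ids) || anyNA(dmp_q))
    .stopf("a q-value is required for every probe")
  probe_ids[dmp_q >= q_threshold]
}

#' Within-subject cross-tissue correlation per site
#'
#' For each site, the Pearson correlation between the subject-aligned
#' vector of bone M-values and the vector of blood M-values.  This is the
#' core similarity statistic: a high positive r means blood tracks bone
#' across individuals at that site.
#'
#' @param M M-value matrix (typically restricted to candidate sites).
#' @param sheet Sample sheet defining the matched pairs (`n >= 3`).
#' @return Named numeric vector of correlations in `[-1, 1]`; sites with
#'   zero variance in either tissue give NaN (counted in a message) and
#'   are excluded from downstream testing.
#' @export
sitewise_pair_correlation <- function(M, sheet) {
  if (length(unique(sheet$subject_id)) < 3L)
    .stopf("at least 3 subjects are required for correlation")
  pr <- .pair_matrices(M, sheet)
  r <- .row_cor(pr$bone, pr$blood)
  if (any(is.nan(r)))
    message(sum(is.nan(r)), " site(s) with zero variance: r undefined (NaN)")
  names(r) <- rownames(M)
  r
}

#' t-test on per-site correlations
#'
#' Standard transform `t = r sqrt(n - 2) / sqrt(1 - r^2)`, referred
#' two-sided to a Student t with `n - 2` degrees of freedom.  `r = +-1`
#' yields `t = +-Inf`, `p = 0` by convention (counted in a message).
#'
#' @param r Numeric vector of correlations (NaN allowed; propagated).
#' @param n Number of subjects (`>= 3`).
#' @return `data.frame` with `r`, `t_r`, `p`.
#' @export
correlation_test <- function(r, n) {
  if (!.is_count(n) || n < 3) .stopf("correlation test needs n >= 3 subjects")
  t_r <- r * sqrt(n - 2) / sqrt(1 - r^2)
  exact <- !is.nan(r) & abs(r) == 1
  if (any(exact)) {
    message(sum(exact), " site(s) with |r| = 1: p = 0 by convention")
    t_r[exact] <- sign(r[exact]) * Inf
  }
  p <- 2 * stats::pt(-abs(t_r), df = n - 2)
  p[exact] <- 0
  data.frame(r = as.numeric(r), t_r = t_r, p = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Maximum paired beta difference per site
#'
#' The strictest similarity screen: the largest `|beta_bone - beta_blood|`
#' over subjects.  A site passes the similarity filter only if no single
#' pair differs by more than the threshold.
#'
#' @inheritParams mean_paired_delta_beta
#' @return Numeric vector, one value per site.
#' @export
max_pair_delta_beta <- function(beta, sheet) {
  pr <- .pair_matrices(beta, sheet)
  .row_max_absdiff(pr$bone, pr$blood)
}

#' Call similarly methylated positions (SMPs)
#'
#' A site is an SMP iff its correlation q-value is below `q_threshold`,
#' its paired beta difference is below `dbeta_threshold`, and `r > 0`
#' (anti-correlated sites are not "similar").  Sites are classed by mean
#' beta over all samples: hypo (`< 0.2`), hyper (`> 0.8`), mid otherwise.
#'
#' @param probe_ids Candidate probe ids.
#' @param r,t_r,p Per-site correlation statistics (see
#'   [sitewise_pair_correlation()] and [correlation_test()]).
#' @param max_pair_dbeta Per-site paired beta difference
#'   ([max_pair_delta_beta()] or [mean_paired_delta_beta()] according to
#'   `dbeta_rule` used upstream).
#' @param beta_mean Per-site mean beta over all samples.
#' @param q_threshold,dbeta_threshold Call thresholds (defaults 0.05,
#'   0.2); must lie in (0, 1).
#' @return An SMP table: `probe_id`, `r`, `t_r`, `p`, `q`,
#'   `max_pair_dbeta`, `beta_class`, `is_smp`.
#' @export
call_smps <- function(probe_ids, r, t_r, p, max_pair_dbeta, beta_mean,
                      q_threshold = 0.05, dbeta_threshold = 0.2) {
  .check_threshold(q_threshold, "q_threshold")
  .check_threshold(dbeta_threshold, "dbeta_threshold")
  lens <- lengths(list(r, t_r, p, max_pair_dbeta, beta_mean))
  if (any(lens != length(probe_ids)))
    .stopf("all per-site inputs must align with probe_ids")
  q <- bh_fdr(p)
  data.frame(probe_id = probe_ids,
             r = as.numeric(r), t_r = as.numeric(t_r),
             p = as.numeric(p), q = q,
             max_pair_dbeta = as.numeric(max_pair_dbeta),
             beta_class = ifelse(beta_mean < 0.2, "hypo",
                                 ifelse(beta_mean > 0.8, "hyper", "mid")),
             is_smp = !is.na(q) & q < q_threshold &
               max_pair_dbeta < dbeta_threshold & !is.nan(r) & r > 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' One-call SMP analysis
#'
#' Restricts to candidate (non-DMP) sites, computes per-site within-subject
#' correlations, tests them, applies BH FDR and the beta-similarity
#' filter, and returns the SMP table.
#'
#' @param M,beta M-value and beta-value matrices over the same probes.
#' @param sheet Sample sheet.
#' @param dmp_q Named vector of DMP-stage q-values covering all probes of
#'   `M` (as produced by [call_dmps()]); `NULL` treats all probes as
#'   candidates.
#' @param q_threshold,dbeta_threshold Call thresholds.
#' @param dbeta_rule `"max"` (default; per-pair maximum difference) or
#'   `"mean"` (subject-averaged absolute difference).
#' @return An SMP table over the candidate sites (see [call_smps()]).
#' @export
smp_analysis <- function(M, beta, sheet, dmp_q = NULL,
                         q_threshold = 0.05, dbeta_threshold = 0.2,
                         dbeta_rule = c("max", "mean")) {
  dbeta_rule <- match.arg(dbeta_rule)
  probes <- rownames(M)
  if (!is.null(dmp_q)) probes <- candidate_sites(probes, dmp_q, q_threshold)
  Mc <- M[probes, , drop = FALSE]
  Bc <- beta[probes, , drop = FALSE]
  n <- length(unique(sheet$subject_id))
  r <- sitewise_pair_correlation(Mc, sheet)
  ct <- correlation_test(r, n)
  db <- switch(dbeta_rule,
               max = max_pair_delta_beta(Bc, sheet),
               mean = mean_paired_delta_beta(Bc, sheet))
  call_smps(probes, ct$r, ct$t_r, ct$p, db, rowMeans(Bc),
            q_threshold, dbeta_threshold)
}

#' Subject-label permutation null for the SMP count
#'
#' Breaks the matched pairing by shuffling which subject's blood sample is
#' paired with which bone sample, and re-runs the full SMP selection
#' (per-site correlation, BH FDR \emph{within the iteration}, and the
#' beta-similarity filter against the permuted pairing) at each iteration.
#' The identity permutation is an allowed draw.  The empirical p-value is
#' `(1 + #(null count >= observed)) / (n_iterations + 1)`.
#'
#' @param M,beta Matrices restricted to the candidate probes.
#' @param sheet Sample sheet.
#' @param n_iterations Number of shuffles (study default 10,000; fewer
#'   than 100 triggers an instability warning).
#' @param seed Integer seed; results are bit-reproducible given it.
#' @param q_threshold,dbeta_threshold,dbeta_rule As in [smp_analysis()].
#' @param perm_fun Optional `function(n)` returning a permutation of
#'   `1..n` (testing hook; default draws uniform random permutations).
#' @return List of class `"permutation_null"`: `observed` count,
#'   `null_counts` (length `n_iterations`), `p_empirical`, `n_iterations`,
#'   `seed`.
#' @export
permutation_null <- function(M, beta, sheet, n_iterations = 10000,
                             seed = 1L, q_threshold = 0.05,
                             dbeta_threshold = 0.2,
                             dbeta_rule = c("max", "mean"),
                             perm_fun = NULL) {
  dbeta_rule <- match.arg(dbeta_rule)
  if (n_iterations < 100) .warnf("fewer than 100 iterations: empirical p is unstable")
  set.seed(as.integer(seed))
  prM <- .pair_matrices(M, sheet)
  prB <- .pair_matrices(beta, sheet)
  n <- length(prM$subjects)
  if (n < 3L) .stopf("at least 3 subjects are required")

  # standardised rows: r under any pairing is a plain cross-product, since
  # permuting a row's entries leaves its mean and SD unchanged
  std <- function(x) {
    xc <- x - rowMeans(x)
    s <- sqrt(rowSums(xc^2))
    sweep(xc, 1L, pmax(s, .Machine$double.xmin), "/")
  }
  Zb <- std(prM$bone)
  Zl <- std(prM$blood)
  degenerate <- rowSums((prM$bone - rowMeans(prM$bone))^2) == 0 |
    rowSums((prM$blood - rowMeans(prM$blood))^2) == 0

  count_pass <- function(perm) {
    r <- rowSums(Zb * Zl[, perm, drop = FALSE])
    r <- pmin(pmax(r, -1), 1)
    r[degenerate] <- NaN
    t_r <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 0))
    p <- 2 * stats::pt(-abs(t_r), df = n - 2)
    p[!is.nan(r) & abs(r) == 1] <- 0
    ok <- !is.nan(r)
    q <- rep(NA_real_, length(p))
    q[ok] <- stats::p.adjust(p[ok], method = "BH")
    db <- switch(dbeta_rule,
                 max = .row_max_absdiff(prB$bone,
                                        prB$blood[, perm, drop = FALSE]),
                 mean = abs(rowMeans(prB$bone -
                                       prB$blood[, perm, drop = FALSE])))
    sum(ok & q < q_threshold & db < dbeta_threshold & r > 0, na.rm = TRUE)
  }

  observed <- count_pass(seq_len(n))
  draw <- if (is.null(perm_fun)) function(n) sample.int(n) else perm_fun
  null_counts <- integer(n_iterations)
  for (i in seq_len(n_iterations)) null_counts[i] <- count_pass(draw(n))
  structure(list(observed = observed, null_counts = null_counts,
                 p_empirical = (1 + sum(null_counts >= observed)) /
                   (n_iterations + 1),
                 n_iterations = n_iterations, seed = as.integer(seed)),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat("Subject-label permutation null\n")
  cat(sprintf("  observed passing count: %d\n", x$observed))
  cat(sprintf("  null counts (n = %d): mean %.2f, max %d\n",
              x$n_iterations, mean(x$null_counts), max(x$null_counts)))
  cat(sprintf("  empirical p = %.4g\n", x$p_empirical))
  invisible(x)
}

#' Write a permutation result (with histogram) to JSON
#'
#' @param perm A `"permutation_null"` object.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_permutation_json <- function(perm, path) {
  h <- table(perm$null_counts)
  jsonlite::write_json(
    list(observed = perm$observed,
         n_iterations = perm$n_iterations,
         p_empirical = perm$p_empirical,
         seed = perm$seed,
         null_count_histogram = list(count = as.integer(names(h)),
                                     frequency = as.integer(h))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
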