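#' Site-wise linear model of M-values on tissue and covariates
#'
#' Fits, by ordinary least squares and independently at each site, the
#' model `M ~ tissue + age` (age optional), and returns the tissue
#' contrast (bone minus blood), the residual variance and the residual
#' degrees of freedom.  The estimate is identical under group-mean and
#' treatment parametrisations of the tissue factor.
#'
#' @param M M-value matrix, probes in rows, samples in columns.
#' @param sheet Sample sheet covering the columns of `M`.
#' @param covariates Character vector of sheet columns to adjust for
#'   (default `"age"`).  A covariate that is constant (making the design
#'   rank-deficient) is dropped with a warning.
#' @return `data.frame` with `probe_id`, `effect` (bone - blood M
#'   difference), `s2` (residual variance), `df` (residual degrees of
#'   freedom, constant) and `stdev_unscaled` (the unscaled standard error
#'   of the contrast, `sqrt([ (X'X)^-1 ]_tissue)`).
#' @export
fit_sitewise_model <- function(M, sheet, covariates = "age") {
  .check_named_matrix(M, "M-value matrix")
  idx <- match(colnames(M), sheet$sample_id)
  if (anyNA(idx)) .stopf("samples in M absent from sheet")
  sheet <- sheet[idx, ]
  tissue <- factor(sheet$tissue, levels = c("blood", "bone"))
  df_design <- data.frame(tissue = tissue)
  for (cv in covariates) {
    if (!cv %in% names(sheet)) .stopf("covariate '%s' not in sample sheet", cv)
    v <- sheet[[cv]]
    if (length(unique(v)) < 2L) {
      .warnf("covariate '%s' is constant; dropped from the design", cv)
      next
    }
    df_design[[cv]] <- if (is.numeric(v)) v else factor(v)
  }
  X <- stats::model.matrix(~ ., df_design)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    # drop aliased covariate columns (keep intercept + tissue)
    keep <- qrX$pivot[seq_len(qrX$rank)]
    if (!all(1:2 %in% keep)) .stopf("design is rank-deficient in tissue")
    .warnf("rank-deficient design; dropping aliased column(s): %s",
           paste(colnames(X)[-keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
    qrX <- qr(X)
  }
  coefs <- qr.coef(qrX, t(M))
  fitted <- X %*% coefs
  resid <- t(M) - fitted
  dfree <- nrow(X) - qrX$rank
  if (dfree < 1L) .stopf("no residual degrees of freedom (n = rank)")
  s2 <- colSums(resid^2) / dfree
  xtx_inv <- chol2inv(qr.R(qrX))
  j <- match("tissuebone", colnames(X))
  data.frame(probe_id = rownames(M),
             effect = coefs[j, ],
             s2 = s2,
             df = dfree,
             stdev_unscaled = sqrt(xtx_inv[j, j]),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Invert the trigamma function by Newton iteration (monotone decreasing on
# (0, Inf)); used to moment-match the prior degrees of freedom.
.trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

#' Empirical-Bayes moderation of site-wise variances
#'
#' Shrinks the per-site residual variances toward a common prior and forms
#' moderated t-statistics.  The prior degrees of freedom `d0` and prior
#' variance `s0^2` are estimated by moment-matching the distribution of
#' `log(s2)` against a scaled F (via digamma/trigamma inversion); the
#' posterior variance is `(d0 s0^2 + d s2) / (d0 + d)` and the moderated t
#' is referred to a Student t with `d + d0` degrees of freedom (normal in
#' the `d0 = Inf` limit).
#'
#' @param fit Output of [fit_sitewise_model()] (`effect`, `s2`, `df`,
#'   `stdev_unscaled`), or a compatible `data.frame`.
#' @param prior_df Optional override of the estimated `d0`.  `0` gives
#'   ordinary (unmoderated) t-statistics; `Inf` fixes every posterior
#'   variance at `s0^2`.
#' @param prior_var Optional override of the estimated `s0^2`.
#' @return `data.frame` with `probe_id`, `effect`, `t_mod`, `p`
#'   (two-sided), `s2_post`, plus attributes `d0` and `s02` carrying the
#'   hyperparameters.  `d0` estimates above `1e7` are reported as `Inf`.
#' @export
moderate_statistics <- function(fit, prior_df = NULL, prior_var = NULL) {
  s2 <- fit$s2
  dfree <- fit$df
  if (length(s2) < 10L && is.null(prior_df))
    .stopf("hyperparameter estimation needs at least 10 sites")
  ok <- is.finite(s2) & s2 > 0
  if (!all(ok)) .warnf("%d site(s) with zero residual variance excluded from hyperparameter estimation",
                       sum(!ok))
  if (is.null(prior_df) || is.null(prior_var)) {
    z <- log(s2[ok])
    d_ok <- if (length(dfree) == 1L) rep(dfree, sum(ok)) else dfree[ok]
    e <- z - digamma(d_ok / 2) + log(d_ok / 2)
    emean <- mean(e)
    evar <- stats::var(e) - mean(trigamma(d_ok / 2))
    if (is.finite(evar) && evar > 0) {
      d0 <- 2 * .trigamma_inverse(evar)
      s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
      if (d0 > 1e7) d0 <- Inf
    } else {
      d0 <- Inf
      s02 <- exp(emean)
      message("no excess spread in log-variances: prior df set to infinity")
    }
  }
  if (!is.null(prior_df)) d0 <- prior_df
  if (!is.null(prior_var)) s02 <- prior_var
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2))
  else (d0 * s02 + dfree * s2) / (d0 + dfree)
  t_mod <- fit$effect / (fit$stdev_unscaled * sqrt(s2_post))
  df_total <- dfree + d0
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  out <- data.frame(probe_id = fit$probe_id, effect = fit$effect,
                    t_mod = t_mod, p = p, s2_post = s2_post,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  out
}

#' Benjamini--Hochberg adjusted p-values (q-values)
#'
#' Step-up FDR adjustment: `q_i` is the smallest value of `m p_(j) / j`
#' over ranks `j` at or above the rank of `p_i`, capped at 1; ties share a
#' q and output order matches input order.  NaN p-values propagate to NaN
#' q-values with a warning and do not count toward `m`.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NaN/NA allowed).
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  bad <- is.na(p)
  if (any(bad)) .warnf("%d NaN/NA p-value(s) propagated to q", sum(bad))
  if (any(p[!bad] < 0 | p[!bad] > 1))
    .stopf("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  q[!bad] <- stats::p.adjust(p[!bad], method = "BH")
  q
}

#' Mean paired beta difference per site
#'
#' The absolute value of the subject-averaged signed difference
#' `beta_bone - beta_blood` (cancellation across subjects is intended:
#' only consistent-direction differences count).
#'
#' @param beta Beta-value matrix.
#' @param sheet Sample sheet defining the pairs.
#' @return Named numeric vector of delta-beta values, one per site.
#' @export
mean_paired_delta_beta <- function(beta, sheet) {
  pr <- .pair_matrices(beta, sheet)
  abs(rowMeans(pr$bone - pr$blood))
}

#' Call differentially methylated positions (DMPs)
#'
#' Two-step call: a site is a DMP iff its BH q-value is below
#' `q_threshold` \emph{and} its mean paired beta difference exceeds
#' `dbeta_threshold`.  Direction (bone relative to blood) comes from the
#' sign of the mean M-value difference.
#'
#' @param stats Output of [moderate_statistics()] (or any `data.frame`
#'   with `probe_id`, `effect`, `t_mod`, `p`).
#' @param delta_beta Per-site delta-beta from [mean_paired_delta_beta()],
#'   aligned with `stats$probe_id`.
#' @param q_threshold,dbeta_threshold Call thresholds (defaults 0.05 and
#'   0.2); must lie in (0, 1).
#' @return A DMP table: `probe_id`, `effect`, `delta_beta`, `t_mod`, `p`,
#'   `q`, `direction` (`"hypo"`/`"hyper"`), `is_dmp`.
#' @export
call_dmps <- function(stats, delta_beta, q_threshold = 0.05,
                      dbeta_threshold = 0.2) {
  .check_threshold(q_threshold, "q_threshold")
  .check_threshold(dbeta_threshold, "dbeta_threshold")
  if (length(delta_beta) != nrow(stats))
    .stopf("delta_beta and stats must cover the same probe set")
  q <- bh_fdr(stats$p)
  data.frame(probe_id = stats$probe_id,
             effect = stats$effect,
             delta_beta = as.numeric(delta_beta),
             t_mod = stats$t_mod,
             p = stats$p,
             q = q,
             direction = ifelse(stats$effect < 0, "hypo", "hyper"),
             is_dmp = !is.na(q) & q < q_threshold &
               delta_beta > dbeta_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

.check_threshold <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || x <= 0 || x >= 1)
    .stopf("%s must lie in (0, 1)", what)
}

#' Classical paired t-test per site (cross-check)
#'
#' Paired t-test on the within-subject M-value differences, the
#' paired-analysis counterpart of the linear-model route.  With strong
#' effects both routes call the same sites.
#'
#' @param M M-value matrix.
#' @param sheet Sample sheet defining the pairs (`n >= 2` subjects).
#' @return `data.frame` with `probe_id`, `mean_diff`, `t_paired`, `p`
#'   (two-sided, `n - 1` df).  Zero-variance differences give
#'   `t = +-Inf`, `p = 0` (counted in a message).
#' @export
paired_test_crosscheck <- function(M, sheet) {
  pr <- .pair_matrices(M, sheet)
  n <- length(pr$subjects)
  if (n < 2L) .stopf("paired test needs at least 2 subjects")
  d <- pr$bone - pr$blood
  mu <- rowMeans(d)
  sd_d <- sqrt(rowSums((d - mu)^2) / (n - 1))
  t_p <- mu / (sd_d / sqrt(n))
  degenerate <- sd_d == 0
  if (any(degenerate)) {
    message(sum(degenerate),
            " site(s) with zero-variance differences: t = +-Inf, p = 0")
    t_p[degenerate] <- sign(mu[degenerate]) * Inf
  }
  p <- 2 * stats::pt(-abs(t_p), df = n - 1)
  p[degenerate] <- 0
  data.frame(probe_id = rownames(M), mean_diff = mu, t_paired = t_p, p = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' One-call DMP analysis
#'
#' Convenience wrapper: [fit_sitewise_model()] then
#' [moderate_statistics()], [mean_paired_delta_beta()] and [call_dmps()].
#'
#' @inheritParams fit_sitewise_model
#' @inheritParams call_dmps
#' @param beta Beta-value matrix aligned with `M`.
#' @param prior_df Passed to [moderate_statistics()].
#' @return A DMP table (see [call_dmps()]).
#' @export
dmp_analysis <- function(M, beta, sheet, covariates = "age",
                         q_threshold = 0.05, dbeta_threshold = 0.2,
                         prior_df = NULL) {
  fit <- fit_sitewise_model(M, sheet, covariates)
  st <- moderate_statistics(fit, prior_df = prior_df)
  db <- mean_paired_delta_beta(beta, sheet)
  call_dmps(st, db[st$probe_id], q_threshold, dbeta_threshold)
}
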