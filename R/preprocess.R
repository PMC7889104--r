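#' Compute beta-values from methylated/unmethylated intensities
#'
#' `beta = m / (m + u + alpha)`, where `alpha` is a positive offset
#' (customarily 100) stabilising the ratio at low total signal.  The
#' denominator is at least `alpha`, so the result is never NaN.
#'
#' @param m,u Non-negative numeric matrices of methylated and unmethylated
#'   signal, same shape, probes in rows and samples in columns.
#' @param alpha Positive intensity offset (default 100).
#' @return Matrix of beta-values in `[0, 1)` (attribute `domain = "beta"`).
#' @export
compute_beta <- function(m, u, alpha = 100) {
  .check_intensities(m, u, alpha)
  .set_domain(m / (m + u + alpha), "beta")
}

#' Compute M-values from methylated/unmethylated intensities
#'
#' `M = log2((m + alpha) / (u + alpha))`; finite for all non-negative
#' intensities because `alpha > 0`.
#'
#' @inheritParams compute_beta
#' @return Matrix of M-values (attribute `domain = "mvalue"`).
#' @export
compute_m <- function(m, u, alpha = 100) {
  .check_intensities(m, u, alpha)
  .set_domain(log2((m + alpha) / (u + alpha)), "mvalue")
}

.check_intensities <- function(m, u, alpha) {
  if (!identical(dim(m), dim(u)))
    .stopf("m and u must have the same shape")
  if (any(m < 0, na.rm = TRUE) || any(u < 0, na.rm = TRUE))
    .stopf("negative intensity value")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    .stopf("alpha must be a positive scalar")
  invisible(NULL)
}

#' Convert beta-values to M-values (logit2 bridge)
#'
#' `M = log2(beta / (1 - beta))`.  Exactly inverse to [m_to_beta()]; agrees
#' with [compute_m()] only in the limit `alpha = 0` (see the package
#' vignette for the offset's effect).
#'
#' @param beta Matrix or vector of beta-values in `(0, 1)`.  Values at the
#'   boundary are clamped to `[eps, 1 - eps]` with a warning.
#' @param eps Clamping tolerance for boundary values (default `1e-6`).
#' @return M-values, same shape as `beta`.
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    .stopf("beta values must lie in [0, 1]")
  if (any(beta <= 0 | beta >= 1, na.rm = TRUE)) {
    .warnf("beta values at 0 or 1 clamped to [%g, %g]", eps, 1 - eps)
    beta <- pmin(pmax(beta, eps), 1 - eps)
  }
  .set_domain(.logit2(beta), "mvalue")
}

#' Convert M-values to beta-values
#'
#' Inverse of [beta_to_m()]: `beta = 2^M / (2^M + 1)`.
#'
#' @param m Matrix or vector of M-values.
#' @return Beta-values in `(0, 1)`, same shape.
#' @export
m_to_beta <- function(m) .set_domain(.expit2(m), "beta")

#' Filter probes by detection p-value
#'
#' A probe is kept only if its detection p-value is at or below `threshold`
#' in \emph{every} sample; failure in any single sample excludes it (the
#' most conservative aggregation of per-sample detection calls).
#'
#' @param detp Detection p-value matrix, probes in rows, samples in
#'   columns, values in `[0, 1]`.
#' @param threshold Exclusion threshold (default 0.01).
#' @return Character vector of kept probe ids, in input row order.
#' @export
detection_filter <- function(detp, threshold = 0.01) {
  .check_named_matrix(detp, "detection p-value matrix")
  if (any(detp < 0 | detp > 1, na.rm = TRUE))
    .stopf("detection p-values must lie in [0, 1]")
  keep <- rowSums(detp > threshold) == 0L
  rownames(detp)[keep]
}

#' Filter probes overlapping SNPs
#'
#' Removes probes whose annotation flags a SNP overlap; such probes measure
#' genetic rather than epigenetic variation.
#'
#' @param annotation Probe annotation (see [read_annotation()]).
#' @param probes Optional character vector of probes to filter; defaults to
#'   all annotated probes.  Every probe must be annotated.
#' @return Character vector of kept (non-SNP) probe ids, in input order.
#' @export
snp_filter <- function(annotation, probes = NULL) {
  if (is.null(probes)) probes <- annotation$probe_id
  idx <- match(probes, annotation$probe_id)
  if (anyNA(idx))
    .stopf("probe(s) missing from annotation: %s",
           paste(utils::head(probes[is.na(idx)], 5L), collapse = ", "))
  keep <- probes[!annotation$snp_overlap[idx]]
  if (!length(keep)) .warnf("all probes are SNP-flagged; empty keep-list")
  keep
}

#' Empirical-Bayes batch correction of M-values
#'
#' Parametric location/scale batch adjustment in the spirit of ComBat:
#' per site, the model mean (grand mean + tissue effect) is removed, the
#' residuals standardised, per-batch location and scale estimated and
#' shrunk toward batch-level priors (normal prior for locations,
#' inverse-gamma for scales, moments-matched in a single pass), and the
#' adjusted residuals restored to the original scale and mean.  Tissue is
#' protected as a covariate so biological signal is not removed.  Each
#' site's overall mean is preserved exactly (the adjustment is a pure
#' residual-space transform followed by re-centring).
#'
#' @param M M-value matrix, probes in rows, samples in columns.
#' @param sheet Sample sheet covering the columns of `M`.
#' @return Corrected M-value matrix, same shape and dimnames.  With a
#'   single batch the input is returned unchanged (with a message).
#' @export
batch_correct <- function(M, sheet) {
  .check_named_matrix(M, "M-value matrix")
  idx <- match(colnames(M), sheet$sample_id)
  if (anyNA(idx)) .stopf("samples in M absent from sheet")
  sheet <- sheet[idx, ]
  batch <- factor(sheet$batch)
  if (nlevels(batch) == 1L) {
    message("single batch: batch correction is the identity")
    return(M)
  }
  nb <- table(batch)
  if (any(nb < 2L))
    .stopf("batch(es) with fewer than 2 samples: %s",
           paste(names(nb)[nb < 2L], collapse = ", "))
  n <- ncol(M)
  tissue <- factor(sheet$tissue, levels = c("blood", "bone"))
  Xb <- stats::model.matrix(~ 0 + batch)
  Xc <- stats::model.matrix(~ tissue)[, -1L, drop = FALSE]
  X <- cbind(Xb, Xc)
  # per-site OLS of M on batch + tissue; B is sites x p
  B <- t(solve(crossprod(X), crossprod(X, t(M))))
  k <- nlevels(batch)
  grand <- drop(B[, seq_len(k), drop = FALSE] %*% (as.numeric(nb) / n))
  stand_mean <- outer(grand, rep(1, n)) + B[, -seq_len(k), drop = FALSE] %*% t(Xc)
  resid_full <- M - t(X %*% t(B))
  var_pooled <- rowSums(resid_full^2) / n
  sd_pooled <- sqrt(pmax(var_pooled, 1e-12))
  Z <- (M - stand_mean) / sd_pooled

  out <- Z
  gamma_hat <- sapply(levels(batch), function(b)
    rowMeans(Z[, batch == b, drop = FALSE]))
  delta_hat <- sapply(levels(batch), function(b)
    apply(Z[, batch == b, drop = FALSE], 1L, stats::var))
  gamma_hat <- matrix(gamma_hat, nrow = nrow(M))
  delta_hat <- matrix(delta_hat, nrow = nrow(M))
  for (j in seq_len(k)) {
    nbj <- as.numeric(nb[j])
    g <- gamma_hat[, j]
    d2 <- delta_hat[, j]
    g_bar <- mean(g)
    t2 <- stats::var(g)
    m_d <- mean(d2)
    v_d <- stats::var(d2)
    # inverse-gamma prior moments-matched to the observed scale estimates;
    # one-pass posterior means (no joint iteration)
    if (is.finite(v_d) && v_d > 1e-12 && m_d > 0) {
      a_prior <- (2 * v_d + m_d^2) / v_d
      b_prior <- (m_d * v_d + m_d^3) / v_d
      sse <- (nbj - 1) * d2
      d2_star <- (b_prior + 0.5 * sse) / (nbj / 2 + a_prior - 1)
    } else {
      d2_star <- d2
    }
    d2_star <- pmax(d2_star, 1e-12)
    g_star <- if (is.finite(t2) && t2 > 1e-12)
      (nbj * t2 * g + d2_star * g_bar) / (nbj * t2 + d2_star)
    else rep(g_bar, length(g))
    cols <- which(batch == levels(batch)[j])
    out[, cols] <- (Z[, cols, drop = FALSE] - g_star) / sqrt(d2_star)
  }
  corrected <- out * sd_pooled + stand_mean
  # pure location re-centring: preserve each site's overall mean exactly
  corrected <- corrected - rowMeans(corrected) + rowMeans(M)
  dimnames(corrected) <- dimnames(M)
  .set_domain(corrected, "mvalue")
}

#' Per-sample median intensities (QC report)
#'
#' Sample-level quality summary: the median methylated and unmethylated
#' channel intensity per sample.  Reported for inspection only; no
#' automatic sample exclusion is applied.
#'
#' @inheritParams compute_beta
#' @return `data.frame` with `sample_id`, `median_m`, `median_u`.
#' @export
sample_medians <- function(m, u) {
  .check_intensities(m, u, 100)
  data.frame(sample_id = colnames(m),
             median_m = apply(m, 2L, stats::median),
             median_u = apply(u, 2L, stats::median),
             row.names = NULL)
}

#' Run the full preprocessing chain
#'
#' Detection-p filter, SNP filter, beta/M computation and batch
#' correction in one call, mirroring a standard array QC pipeline.
#'
#' @param m,u Intensity matrices (or `NULL` if `beta` is given).
#' @param beta Beta-value matrix, used when intensities are unavailable
#'   (M-values then come from the logit2 bridge [beta_to_m()]).
#' @param detp Detection p-value matrix.
#' @param annotation Probe annotation.
#' @param sheet Sample sheet.
#' @param alpha Intensity offset for [compute_beta()]/[compute_m()].
#' @param detp_threshold Detection p-value threshold (default 0.01).
#' @param correct_batch Apply [batch_correct()] to the M-values?
#' @return List with filtered `beta` and `mvalues` matrices, the kept
#'   `probes`, and `qc` (probes dropped per filter plus, when intensities
#'   are given, per-sample medians).
#' @export
preprocess_pipeline <- function(m = NULL, u = NULL, beta = NULL, detp,
                                annotation, sheet, alpha = 100,
                                detp_threshold = 0.01,
                                correct_batch = TRUE) {
  if (is.null(beta)) {
    if (is.null(m) || is.null(u))
      .stopf("either intensities (m, u) or beta must be supplied")
    beta <- compute_beta(m, u, alpha)
    mval <- compute_m(m, u, alpha)
  } else {
    mval <- beta_to_m(beta)
  }
  keep_det <- detection_filter(detp, detp_threshold)
  keep_snp <- snp_filter(annotation, rownames(beta))
  keep <- intersect(keep_det, keep_snp)
  qc <- list(n_input = nrow(beta),
             n_failed_detection = nrow(beta) - length(keep_det),
             n_snp_removed = length(keep_det) - length(intersect(keep_det, keep_snp)),
             n_kept = length(keep))
  if (!is.null(m)) qc$sample_medians <- sample_medians(m, u)
  beta <- beta[keep, , drop = FALSE]
  mval <- mval[keep, , drop = FALSE]
  if (correct_batch) mval <- batch_correct(mval, sheet)
  list(beta = .set_domain(beta, "beta"),
       mvalues = .set_domain(mval, "mvalue"),
       probes = keep, qc = qc)
}
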