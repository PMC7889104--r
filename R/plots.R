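# Diagnostic plots, in the style of array-QC density and MDS figures.

#' Beta-value density plot by tissue
#'
#' Overlays per-sample beta densities, coloured by tissue; bone and blood
#' typically show distinct bimodal profiles.
#'
#' @param beta Beta-value matrix.
#' @param sheet Sample sheet covering its columns.
#' @param main Plot title.
#' @return Invisibly, `NULL`; draws on the current device.
#' @export
plot_beta_density <- function(beta, sheet, main = "Beta-value density") {
  idx <- match(colnames(beta), sheet$sample_id)
  col <- ifelse(sheet$tissue[idx] == "bone", "#D55E00", "#0072B2")
  dens <- apply(beta, 2L, stats::density, from = 0, to = 1)
  ylim <- c(0, max(vapply(dens, function(d) max(d$y), 0)))
  graphics::plot(NA, xlim = c(0, 1), ylim = ylim, xlab = "beta",
                 ylab = "density", main = main)
  for (j in seq_along(dens))
    graphics::lines(dens[[j]], col = col[j])
  graphics::legend("top", legend = c("bone", "blood"),
                   col = c("#D55E00", "#0072B2"), lty = 1, bty = "n")
  invisible(NULL)
}

#' Multi-dimensional scaling plot of samples
#'
#' Classical MDS of the Euclidean distances between sample M-value
#' profiles; tissues should separate on the first dimension, residual
#' batch structure may appear on later ones.
#'
#' @param M M-value matrix.
#' @param sheet Sample sheet covering its columns.
#' @param main Plot title.
#' @return Invisibly, the 2-column coordinate matrix.
#' @export
plot_mds <- function(M, sheet, main = "MDS of M-values") {
  idx <- match(colnames(M), sheet$sample_id)
  coords <- stats::cmdscale(stats::dist(t(M)), k = 2)
  col <- ifelse(sheet$tissue[idx] == "bone", "#D55E00", "#0072B2")
  pch <- as.integer(factor(sheet$batch[idx]))
  graphics::plot(coords, col = col, pch = pch, xlab = "dim 1",
                 ylab = "dim 2", main = main)
  graphics::text(coords, labels = sheet$subject_id[idx], pos = 3,
                 cex = 0.6, col = col)
  invisible(coords)
}
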