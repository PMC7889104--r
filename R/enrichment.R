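#' Genomic-feature and CpG-island enrichment of called sites
#'
#' For every genomic feature class and CpG-island class, counts how many
#' called sites and how many universe probes annotate to it, and reports
#' the ratio (calls per array probe in the region).  A probe with several
#' feature annotations (gene isoforms) contributes one hit to \emph{each}
#' of its classes, so feature hits can sum to more than the number of
#' calls.  Island classes are single-valued.
#'
#' @param calls Character vector of called probe ids, or a site result
#'   table with `probe_id` and (optionally) a `direction` or `beta_class`
#'   column used for the hypo/hyper split.
#' @param annotation Probe annotation covering the universe.
#' @param universe Character vector of all analysis probes; calls must be
#'   a subset.
#' @return `data.frame` with `region_type` (`"feature"`/`"island"`),
#'   `region`, `n_hits`, `n_array`, `ratio`, `hypo_fraction`,
#'   `hyper_fraction` (fractions of the region's hits labelled hypo/hyper;
#'   NA when no label column is available).
#' @export
region_enrichment <- function(calls, annotation, universe) {
  label <- NULL
  if (is.data.frame(calls)) {
    if ("direction" %in% names(calls)) label <- calls$direction
    else if ("beta_class" %in% names(calls)) label <- calls$beta_class
    ids <- calls$probe_id
  } else ids <- calls
  if (!all(ids %in% universe))
    .stopf("calls must be a subset of the universe")
  idx_u <- match(universe, annotation$probe_id)
  if (anyNA(idx_u))
    .stopf("universe probe(s) missing from annotation: %s",
           paste(utils::head(universe[is.na(idx_u)], 5L), collapse = ", "))
  idx_c <- match(ids, annotation$probe_id)

  count_class <- function(fc_list, level)
    sum(vapply(fc_list, function(v) level %in% v, NA))
  rows <- list()
  fc_u <- annotation$feature_class[idx_u]
  fc_c <- annotation$feature_class[idx_c]
  for (lv in .feature_levels) {
    hit <- vapply(fc_c, function(v) lv %in% v, NA)
    rows[[length(rows) + 1L]] <- data.frame(
      region_type = "feature", region = lv,
      n_hits = sum(hit), n_array = count_class(fc_u, lv),
      hypo_fraction = if (is.null(label)) NA_real_ else
        if (sum(hit)) mean(label[hit] == "hypo") else 0,
      hyper_fraction = if (is.null(label)) NA_real_ else
        if (sum(hit)) mean(label[hit] == "hyper") else 0)
  }
  ic_u <- annotation$island_class[idx_u]
  ic_c <- annotation$island_class[idx_c]
  for (lv in .island_levels) {
    hit <- ic_c == lv
    rows[[length(rows) + 1L]] <- data.frame(
      region_type = "island", region = lv,
      n_hits = sum(hit), n_array = sum(ic_u == lv),
      hypo_fraction = if (is.null(label)) NA_real_ else
        if (sum(hit)) mean(label[hit] == "hypo") else 0,
      hyper_fraction = if (is.null(label)) NA_real_ else
        if (sum(hit)) mean(label[hit] == "hyper") else 0)
  }
  out <- do.call(rbind, rows)
  out$ratio <- ifelse(out$n_array > 0, out$n_hits / out$n_array, NA_real_)
  out[c("region_type", "region", "n_hits", "n_array", "ratio",
        "hypo_fraction", "hyper_fraction")]
}

#' Overlap of called sites with a disease-locus gene list
#'
#' Counts, for a user-supplied list of catalogue loci (gene symbols), how
#' many called sites fall within those genes (by annotated gene symbol,
#' case-insensitive) and how many loci contain at least one called site.
#'
#' @param calls Character vector of called probe ids or a site result
#'   table with `probe_id`.
#' @param annotation Probe annotation covering the calls.
#' @param loci Character vector of catalogue gene symbols (deduplicated
#'   case-insensitively); must be non-empty.
#' @param label Free-text phenotype label carried into the report.
#' @param unique_sites If `TRUE`, a called site annotated to two catalogue
#'   genes counts once in `n_overlapping_sites`; default `FALSE` counts
#'   site--locus incidences.
#' @return List: `phenotype`, `n_catalog_loci`, `n_overlapping_sites`,
#'   `n_loci_represented`, `percent_represented`
#'   (`100 * represented / loci`).
#' @export
locus_overlap <- function(calls, annotation, loci, label = "phenotype",
                          unique_sites = FALSE) {
  ids <- if (is.data.frame(calls)) calls$probe_id else calls
  loci <- loci[nzchar(loci)]
  loci <- loci[!duplicated(toupper(loci))]
  if (!length(loci)) .stopf("empty locus list")
  idx <- match(ids, annotation$probe_id)
  if (anyNA(idx))
    .stopf("called probe(s) missing from annotation: %s",
           paste(utils::head(ids[is.na(idx)], 5L), collapse = ", "))
  loci_up <- toupper(loci)
  gene_hits <- lapply(annotation$genes[idx],
                      function(g) intersect(toupper(g), loci_up))
  n_inc <- if (unique_sites) sum(lengths(gene_hits) > 0L)
  else sum(lengths(gene_hits))
  represented <- unique(unlist(gene_hits))
  list(phenotype = label,
       n_catalog_loci = length(loci),
       n_overlapping_sites = n_inc,
       n_loci_represented = length(represented),
       percent_represented = 100 * length(represented) / length(loci))
}

#' Gene universe of a probe set
#'
#' The union of gene symbols annotated to the given probes; the background
#' for over-representation testing.
#'
#' @param probes Character vector of probe ids.
#' @param annotation Probe annotation covering them.
#' @return Character vector of unique gene symbols (empty with a warning
#'   if all probes are intergenic).
#' @export
gene_universe <- function(probes, annotation) {
  idx <- match(probes, annotation$probe_id)
  if (anyNA(idx))
    .stopf("probe(s) missing from annotation: %s",
           paste(utils::head(probes[is.na(idx)], 5L), collapse = ", "))
  genes <- unique(unlist(annotation$genes[idx]))
  if (!length(genes)) .warnf("no genes annotated to the given probes")
  genes
}

#' Hypergeometric gene-set over-representation
#'
#' For each gene set, tests whether the called genes over-represent the
#' set relative to the gene universe, using the plain hypergeometric upper
#' tail: with `N = |universe|`, `K = |set in universe|`,
#' `n = |called genes|`, `k = |set in called genes|`, reports
#' `p = P(X >= k)`, `X ~ Hypergeometric(N, K, n)`.  No correction for the
#' number of probes per gene is applied (and no correction across sets).
#'
#' @param called_genes Character vector of genes hit by called sites; must
#'   be a subset of `universe`.
#' @param universe Character vector, the gene universe.
#' @param sets Named list of gene sets (see [read_gmt()]).  Sets are
#'   intersected with the universe first; sets with no universe genes are
#'   skipped.
#' @return `data.frame` with `set`, `n_set_genes` (K), `n_called_genes`
#'   (k), `p`, ordered by `p`.
#' @export
hypergeom_enrichment <- function(called_genes, universe, sets) {
  called_genes <- unique(called_genes)
  universe <- unique(universe)
  if (!all(called_genes %in% universe))
    .stopf("called_genes must be a subset of the universe")
  N <- length(universe)
  n <- length(called_genes)
  rows <- lapply(names(sets), function(nm) {
    inU <- intersect(sets[[nm]], universe)
    K <- length(inU)
    if (K == 0L) return(NULL)
    k <- length(intersect(inU, called_genes))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, n_set_genes = K, n_called_genes = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(set = character(0), n_set_genes = integer(0),
                      n_called_genes = integer(0), p = numeric(0)))
  out[order(out$p), , drop = FALSE]
}
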