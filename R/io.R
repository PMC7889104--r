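#' Read and validate a sample sheet
#'
#' The sample sheet maps each array sample to its subject, tissue, batch and
#' age, and defines the matched bone--blood pairs on which all within-subject
#' statistics are computed.
#'
#' @param path Path to a CSV file with a header row containing at least the
#'   columns `sample_id`, `subject_id`, `tissue`, `batch`, `age`.
#'
#' @details Validation enforces the pairing design: sample identifiers must
#' be unique, `tissue` must be `"bone"` or `"blood"`, every subject must
#' appear exactly once per tissue, and at least 3 subjects are required (the
#' correlation test needs `n - 2 >= 1` degrees of freedom).
#'
#' @return A `data.frame` with columns `sample_id`, `subject_id`, `tissue`,
#'   `batch` (character) and `age` (numeric), one row per sample.
#' @seealso [validate_sample_sheet()]
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_sample_sheet(df)
}

#' Validate a sample-sheet data frame
#'
#' @param df A `data.frame` with the five sample-sheet columns (see
#'   [read_sample_sheet()]).
#' @return The validated (and type-normalised) data frame, invisibly usable
#'   as a sample sheet.
#' @export
validate_sample_sheet <- function(df) {
  required <- c("sample_id", "subject_id", "tissue", "batch", "age")
  missing <- setdiff(required, names(df))
  if (length(missing))
    .stopf("sample sheet is missing column(s): %s",
           paste(missing, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$subject_id <- as.character(df$subject_id)
  df$tissue <- as.character(df$tissue)
  df$batch <- as.character(df$batch)
  if (!is.numeric(df$age)) {
    age <- suppressWarnings(as.numeric(df$age))
    if (anyNA(age)) .stopf("non-numeric age value(s) in sample sheet")
    df$age <- age
  }
  if (anyNA(df[required])) .stopf("sample sheet contains missing values")
  if (anyDuplicated(df$sample_id))
    .stopf("duplicated sample_id: %s",
           df$sample_id[duplicated(df$sample_id)][1L])
  bad <- setdiff(unique(df$tissue), c("bone", "blood"))
  if (length(bad))
    .stopf("tissue must be 'bone' or 'blood'; found: %s",
           paste(bad, collapse = ", "))
  tab <- table(df$subject_id, df$tissue)
  if (!all(c("bone", "blood") %in% colnames(tab)) || any(tab != 1L)) {
    off <- rownames(tab)[rowSums(tab != 1L) > 0L]
    if (!length(off)) off <- unique(df$subject_id)
    .stopf("pairing violated: subject(s) without exactly one sample per tissue: %s",
           paste(utils::head(off, 5L), collapse = ", "))
  }
  if (length(unique(df$subject_id)) < 3L)
    .stopf("at least 3 subjects are required (got %d)",
           length(unique(df$subject_id)))
  df[required]
}

.island_levels <- c("island", "n_shore", "s_shore", "n_shelf", "s_shelf",
                    "open_sea")
.feature_levels <- c("TSS200", "TSS1500", "5UTR", "1stExon", "Body", "3UTR",
                     "intergenic")

#' Read a probe annotation table
#'
#' @param path CSV with columns `probe_id`, `chrom`, `pos`, `feature_class`,
#'   `island_class`, `genes`, `snp_overlap`.  `feature_class` and `genes`
#'   cells may hold several values separated by semicolons (a probe can
#'   annotate to several gene features via isoforms).
#'
#' @details Empty `feature_class` cells become `{intergenic}` and empty
#' `island_class` cells `open_sea` (unmapped probes).  `snp_overlap` accepts
#' 0/1 or TRUE/FALSE.  Duplicate probe identifiers and unknown island-class
#' tokens are errors.
#'
#' @return A `data.frame` with one row per probe; `feature_class` and
#'   `genes` are list-columns of character vectors.
#' @export
read_annotation <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(pos = "integer"))
  required <- c("probe_id", "chrom", "pos", "feature_class", "island_class",
                "genes", "snp_overlap")
  missing <- setdiff(required, names(df))
  if (length(missing))
    .stopf("annotation is missing column(s): %s", paste(missing, collapse = ", "))
  if (anyDuplicated(df$probe_id))
    .stopf("duplicated probe_id in annotation: %s",
           df$probe_id[duplicated(df$probe_id)][1L])
  split_cell <- function(x) {
    out <- strsplit(as.character(x), ";", fixed = TRUE)
    lapply(out, function(v) unique(v[nzchar(v)]))
  }
  fc <- split_cell(df$feature_class)
  fc <- lapply(fc, function(v) if (length(v)) v else "intergenic")
  badf <- setdiff(unique(unlist(fc)), .feature_levels)
  if (length(badf))
    .stopf("unknown feature_class token(s): %s", paste(badf, collapse = ", "))
  ic <- as.character(df$island_class)
  ic[!nzchar(ic) | is.na(ic)] <- "open_sea"
  badi <- setdiff(unique(ic), .island_levels)
  if (length(badi))
    .stopf("unknown island_class token(s): %s", paste(badi, collapse = ", "))
  snp <- df$snp_overlap
  if (!is.logical(snp)) snp <- as.integer(snp) != 0L
  if (anyNA(snp)) .stopf("snp_overlap must be 0/1 or TRUE/FALSE")
  data.frame(probe_id = as.character(df$probe_id),
             chrom = as.character(df$chrom),
             pos = as.integer(df$pos),
             feature_class = I(fc),
             island_class = ic,
             genes = I(split_cell(df$genes)),
             snp_overlap = snp,
             stringsAsFactors = FALSE)
}

#' Write a probe annotation table
#'
#' Inverse of [read_annotation()]: list-columns are joined with semicolons.
#'
#' @param annotation Annotation `data.frame` as returned by [read_annotation()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_annotation <- function(annotation, path) {
  df <- data.frame(probe_id = annotation$probe_id,
                   chrom = annotation$chrom,
                   pos = annotation$pos,
                   feature_class = vapply(annotation$feature_class,
                                          paste, "", collapse = ";"),
                   island_class = annotation$island_class,
                   genes = vapply(annotation$genes, paste, "", collapse = ";"),
                   snp_overlap = as.integer(annotation$snp_overlap))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' @param path Tab-delimited GMT file: set name, description, then gene
#'   symbols.  The standard MSigDB exchange format.
#' @return A named list of character vectors (deduplicated gene symbols).
#'   An empty file yields an empty list with a warning.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    .warnf("empty GMT file: %s", path)
    return(structure(list(), names = character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    .stopf("GMT line %d has fewer than 3 fields", short[1L])
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names(sets)))
    .stopf("duplicated gene-set name: %s",
           names(sets)[duplicated(names(sets))][1L])
  if (any(lengths(sets) == 0L)) .stopf("GMT contains an empty gene set")
  sets
}

#' Read a gene list (one symbol per line)
#'
#' @param path Plain-text file, one gene symbol per line; `#` starts a
#'   comment.  Duplicates (case-insensitive) are dropped.
#' @return Character vector of unique gene symbols.
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  lines[!duplicated(toupper(lines))]
}

#' Write a per-site result table to TSV
#'
#' Writes DMP/SMP result tables (see [call_dmps()], [call_smps()]) with one
#' row per site, full numeric precision, suitable for round-tripping with
#' [read_site_table()].
#'
#' @param table A site result `data.frame` whose first column is `probe_id`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_site_table <- function(table, path) {
  stopifnot(is.data.frame(table), "probe_id" %in% names(table))
  out <- table
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- sprintf("%.17g", out[[j]])
    if (is.list(out[[j]]))
      out[[j]] <- vapply(out[[j]], paste, "", collapse = ";")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a per-site result table written by [write_site_table()]
#'
#' @param path TSV path.
#' @return A `data.frame`; logical columns written as TRUE/FALSE are
#'   restored, numeric columns parsed at full precision.
#' @export
read_site_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a site-by-sample matrix to TSV
#'
#' First column `probe_id`, remaining columns one per sample.
#'
#' @param x Numeric matrix with probe rownames and sample colnames.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_matrix_tsv <- function(x, path) {
  .check_named_matrix(x, "matrix")
  df <- data.frame(probe_id = rownames(x),
                   apply(x, 2L, function(col) sprintf("%.17g", col)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a site-by-sample matrix from TSV
#'
#' @param path TSV whose first column is `probe_id` and remaining columns
#'   are samples.
#' @return Numeric matrix with probe rownames and sample colnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1L] != "probe_id")
    .stopf("matrix TSV must have 'probe_id' as its first column")
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) .stopf("non-numeric values in matrix TSV")
  rownames(m) <- df$probe_id
  m
}
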