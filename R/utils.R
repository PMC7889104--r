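# Internal helpers shared across modules.

# logit2 / inverse-logit2: the alpha-free bridge between beta and M scales.
.logit2 <- function(beta) log2(beta / (1 - beta))
.expit2 <- function(m) 1 / (1 + 2^(-m))

.is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x == round(x) && x >= 0

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Check that a matrix has probe rownames and sample colnames.
.check_named_matrix <- function(x, what) {
  if (!is.matrix(x) || !is.numeric(x))
    .stopf("%s must be a numeric matrix", what)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    .stopf("%s must have probe rownames and sample colnames", what)
  invisible(x)
}

# Split a matrix into subject-aligned bone and blood halves.
# Returns list(bone, blood, subjects): columns of both halves are ordered by
# the same subject vector, so column j of each is the same individual.
.pair_matrices <- function(x, sheet) {
  .check_named_matrix(x, "methylation matrix")
  missing <- setdiff(sheet$sample_id, colnames(x))
  if (length(missing))
    .stopf("samples in sheet absent from matrix: %s",
           paste(utils::head(missing, 5L), collapse = ", "))
  subjects <- sort(unique(sheet$subject_id))
  id_of <- function(tis) {
    idx <- match(paste(subjects, tis), paste(sheet$subject_id, sheet$tissue))
    sheet$sample_id[idx]
  }
  list(bone = x[, id_of("bone"), drop = FALSE],
       blood = x[, id_of("blood"), drop = FALSE],
       subjects = subjects)
}

# Row-wise Pearson correlation between two matrices with aligned columns.
# Zero-variance rows yield NaN.
.row_cor <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  n <- ncol(a)
  ac <- a - rowMeans(a)
  bc <- b - rowMeans(b)
  num <- rowSums(ac * bc)
  den <- sqrt(rowSums(ac^2) * rowSums(bc^2))
  r <- num / den
  r[den == 0] <- NaN
  # guard against rounding slightly outside [-1, 1]
  pmin(pmax(r, -1), 1)
}

# Row-wise max of |a - b|.
.row_max_absdiff <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  out <- abs(a[, 1L] - b[, 1L])
  for (j in seq_len(ncol(a))[-1L]) out <- pmax(out, abs(a[, j] - b[, j]))
  out
}

.set_domain <- function(x, domain) {
  attr(x, "domain") <- domain
  x
}
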