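# Shared fixtures and independent oracles.

# A minimal valid sample sheet for n subjects (single batch unless given).
make_sheet <- function(n, batches = rep("b1", n), ages = seq(66, 85, length.out = n)) {
  subj <- sprintf("P%02d", seq_len(n))
  data.frame(
    sample_id = c(paste0(subj, "_bone"), paste0(subj, "_blood")),
    subject_id = rep(subj, 2L),
    tissue = rep(c("bone", "blood"), each = n),
    batch = rep(batches, 2L),
    age = rep(ages, 2L),
    stringsAsFactors = FALSE)
}

# A named site-by-sample matrix filled from a vector or generator.
make_matrix <- function(values, n_sites, sheet) {
  m <- matrix(values, n_sites, nrow(sheet))
  rownames(m) <- sprintf("cg%04d", seq_len(n_sites))
  colnames(m) <- sheet$sample_id
  m
}

# Brute-force Benjamini-Hochberg step-up, straight from the definition:
# q_i = min over ranks j with p_(j) >= p_i of m * p_(j) / j, capped at 1.
bh_brute <- function(p) {
  m <- length(p)
  ps <- sort(p)
  vapply(p, function(pi) {
    js <- which(ps >= pi)
    min(1, min(m * ps[js] / js))
  }, 0)
}

# Brute-force hypergeometric upper tail by direct combinatorial enumeration.
hyper_brute <- function(k, K, N, n) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Write a data.frame to a temp CSV and return the path.
tmp_csv <- function(df) {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE, quote = FALSE)
  f
}
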