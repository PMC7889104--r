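#' Simulation configuration for matched two-tissue methylation data
#'
#' Bundles and validates the parameters of the synthetic-data generator.
#' Defaults emulate a matched bone--blood study of 12 elderly women run in
#' two array batches: 12 subjects, ages uniform on 66--85, subjects split
#' evenly over batches with both tissues of a subject always co-batched.
#'
#' @param n_subjects Number of subjects (matched pairs); at least 3.
#' @param n_sites Number of CpG sites.
#' @param frac_smp,frac_dmp Fractions of sites planted as similarly
#'   methylated (shared subject effect in both tissues) and differentially
#'   methylated (tissue offset); `frac_smp + frac_dmp <= 1`.
#' @param smp_subject_sd Between-subject SD (M-value units) of the shared
#'   subject effect at planted SMP sites.  The induced within-subject
#'   cross-tissue correlation is approximately
#'   `smp_subject_sd^2 / (smp_subject_sd^2 + noise_sd^2)`.
#' @param noise_sd Within-tissue residual SD (M-value units), all sites.
#' @param dmp_delta_beta Target mean paired beta difference at planted DMP
#'   sites; must lie in (0.2, 1) so planted DMPs clear the standard
#'   `delta-beta > 0.2` call threshold.
#' @param batch_shift Additive M-value shift applied to every site of the
#'   samples in batches beyond the first (a technical batch effect).
#' @param n_batches Number of batches; subjects are split as evenly as the
#'   configuration allows.
#' @param frac_detection_fail Per-cell probability that a (site, sample)
#'   measurement fails detection (detection p drawn from Uniform(0.011, 1)
#'   instead of Uniform(0, 0.009)).
#' @param frac_snp_overlap Fraction of sites flagged as overlapping a SNP,
#'   independent of planted class.
#' @param age_range Length-2 numeric, subject ages drawn uniformly in it.
#' @param age_slope_sd SD of an optional per-site linear age effect
#'   (M-units per year); 0 (default) means age has no true effect.
#' @param seed Integer seed; the same configuration and seed reproduce the
#'   dataset bit-identically.
#'
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_subjects = 12, n_sites = 10000,
                       frac_smp = 0.1, frac_dmp = 0.1,
                       smp_subject_sd = 1.0, noise_sd = 0.25,
                       dmp_delta_beta = 0.4, batch_shift = 0.5,
                       n_batches = 2, frac_detection_fail = 0.00015,
                       frac_snp_overlap = 0.034,
                       age_range = c(66, 85), age_slope_sd = 0,
                       seed = 1L) {
  cfg <- list(n_subjects = n_subjects, n_sites = n_sites,
              frac_smp = frac_smp, frac_dmp = frac_dmp,
              smp_subject_sd = smp_subject_sd, noise_sd = noise_sd,
              dmp_delta_beta = dmp_delta_beta, batch_shift = batch_shift,
              n_batches = n_batches,
              frac_detection_fail = frac_detection_fail,
              frac_snp_overlap = frac_snp_overlap,
              age_range = age_range, age_slope_sd = age_slope_sd,
              seed = as.integer(seed))
  if (!.is_count(n_subjects) || n_subjects < 3)
    .stopf("n_subjects must be an integer >= 3")
  if (!.is_count(n_sites) || n_sites < 1)
    .stopf("n_sites must be a positive integer")
  for (nm in c("frac_smp", "frac_dmp", "frac_detection_fail",
               "frac_snp_overlap")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1)
      .stopf("%s must be a proportion in [0, 1]", nm)
  }
  if (frac_smp + frac_dmp > 1)
    .stopf("frac_smp + frac_dmp must not exceed 1")
  if (!is.numeric(dmp_delta_beta) || dmp_delta_beta <= 0.2 ||
      dmp_delta_beta >= 1)
    .stopf("dmp_delta_beta must lie in (0.2, 1)")
  if (dmp_delta_beta > 0.88)
    .stopf("infeasible config: dmp_delta_beta = %.2f leaves no baseline range for planted dmp sites",
           dmp_delta_beta)
  if (smp_subject_sd < 0 || noise_sd <= 0)
    .stopf("smp_subject_sd must be >= 0 and noise_sd > 0")
  if (!.is_count(n_batches) || n_batches < 1 || n_batches > n_subjects)
    .stopf("n_batches must be an integer in [1, n_subjects]")
  if (length(age_range) != 2L || diff(age_range) < 0)
    .stopf("age_range must be c(lo, hi) with lo <= hi")
  structure(cfg, class = "sim_config")
}

# Baseline beta mixture: hypo (beta < 0.2 typically), mid, hyper (> 0.8),
# mimicking the bimodal-with-middle shape of array methylation densities.
.draw_baseline_beta <- function(n) {
  comp <- sample.int(3L, n, replace = TRUE, prob = c(0.35, 0.45, 0.20))
  beta <- numeric(n)
  beta[comp == 1L] <- stats::rbeta(sum(comp == 1L), 2, 18)
  beta[comp == 2L] <- stats::runif(sum(comp == 2L), 0.2, 0.8)
  beta[comp == 3L] <- stats::rbeta(sum(comp == 3L), 18, 2)
  pmin(pmax(beta, 0.01), 0.99)
}

#' Generate a matched two-tissue methylation dataset with planted truth
#'
#' Simulates bone and blood methylation for `n_subjects` matched pairs on
#' the M-value scale (where effects are additive), converts to beta via the
#' logistic relation, and synthesises intensities, detection p-values, a
#' sample sheet, a probe annotation and the planted truth.
#'
#' @details Site classes partition the probes:
#' \describe{
#'   \item{smp}{baseline + a subject effect `u_j ~ N(0, smp_subject_sd^2)`
#'     shared by \emph{both} tissues of subject `j`, plus independent noise
#'     per sample.  This induces within-subject cross-tissue correlation
#'     `smp_subject_sd^2 / (smp_subject_sd^2 + noise_sd^2)`.}
#'   \item{dmp}{a tissue offset applied to the bone samples, sized on the
#'     beta scale at the site's baseline so the mean paired beta difference
#'     equals `dmp_delta_beta` (direction random per site).}
#'   \item{null}{independent noise only.}
#' }
#' Samples in batches beyond the first get `batch_shift` added to every
#' site.  Detection p-values are drawn Uniform(0.011, 1) for a random
#' `frac_detection_fail` of cells and Uniform(0, 0.009) otherwise, so a
#' failed cell always exceeds the conventional 0.01 threshold.  SNP flags
#' are assigned independently of class.  Intensities are generated as
#' `m = T * beta`, `u = T * (1 - beta)` with total signal
#' `T ~ LogNormal(log 3000, 0.3)`, so [compute_beta()] recovers the beta
#' values up to the offset `alpha`.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `mvalues`, `beta` (site-by-sample matrices),
#'   `intensities` (list with `m`, `u`, `alpha = 100`), `detp` (detection
#'   p-value matrix), `sheet` (sample sheet), `annotation` (probe
#'   annotation) and `truth` (`data.frame`: `probe_id`, `class`,
#'   `baseline_beta`, `subject_sd`, `tissue_offset_m`).
#' @export
simulate_dataset <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) .stopf("config must come from sim_config()")
  set.seed(config$seed)
  n <- config$n_subjects
  ns <- config$n_sites

  subjects <- sprintf("S%02d", seq_len(n))
  batch_of_subject <- rep(sprintf("batch%d", seq_len(config$n_batches)),
                          length.out = n)
  ages <- round(stats::runif(n, config$age_range[1L], config$age_range[2L]), 1)
  sheet <- data.frame(
    sample_id = c(paste0(subjects, "_bone"), paste0(subjects, "_blood")),
    subject_id = rep(subjects, 2L),
    tissue = rep(c("bone", "blood"), each = n),
    batch = rep(batch_of_subject, 2L),
    age = rep(ages, 2L),
    stringsAsFactors = FALSE)
  sheet <- validate_sample_sheet(sheet)

  probes <- sprintf("cg%07d", seq_len(ns))
  n_smp <- round(config$frac_smp * ns)
  n_dmp <- round(config$frac_dmp * ns)
  cls <- rep("null", ns)
  planted <- sample.int(ns, n_smp + n_dmp)
  cls[planted[seq_len(n_smp)]] <- "smp"
  cls[planted[seq_len(n_dmp) + n_smp]] <- "dmp"

  base_beta <- .draw_baseline_beta(ns)
  offset_m <- numeric(ns)
  is_dmp <- cls == "dmp"
  if (any(is_dmp)) {
    # restrict dmp baselines so the target beta offset fits inside (0, 1)
    lo <- 0.05
    hi <- 0.95 - config$dmp_delta_beta
    base_beta[is_dmp] <- stats::runif(sum(is_dmp), lo, hi)
    up <- stats::runif(sum(is_dmp)) < 0.5
    b0 <- base_beta[is_dmp]
    b1 <- b0 + config$dmp_delta_beta
    # bone is hyper-methylated at 'up' sites, hypo-methylated otherwise:
    # swap which tissue sits at the raised level
    blood_b <- ifelse(up, b0, b1)
    bone_b <- ifelse(up, b1, b0)
    base_beta[is_dmp] <- blood_b
    offset_m[is_dmp] <- .logit2(bone_b) - .logit2(blood_b)
  }
  base_m <- .logit2(base_beta)

  subj_sd <- ifelse(cls == "smp", config$smp_subject_sd, 0)
  u_subj <- matrix(stats::rnorm(ns * n), ns, n) * subj_sd
  age_slope <- if (config$age_slope_sd > 0)
    stats::rnorm(ns, 0, config$age_slope_sd) else numeric(ns)

  batch_idx <- match(batch_of_subject, sort(unique(batch_of_subject)))
  shift_subj <- config$batch_shift * (batch_idx - 1L)
  age_c <- ages - mean(ages)

  make_tissue <- function(tissue_offset) {
    base_m + tissue_offset + u_subj +
      outer(age_slope, age_c) +
      matrix(shift_subj, ns, n, byrow = TRUE) +
      matrix(stats::rnorm(ns * n, 0, config$noise_sd), ns, n)
  }
  m_bone <- make_tissue(offset_m)
  m_blood <- make_tissue(0)
  M <- cbind(m_bone, m_blood)
  rownames(M) <- probes
  colnames(M) <- sheet$sample_id
  B <- .expit2(M)

  alpha <- 100
  total <- matrix(stats::rlnorm(length(M), log(3000), 0.3), ns, 2L * n)
  mi <- total * B
  ui <- total * (1 - B)
  dimnames(mi) <- dimnames(ui) <- dimnames(M)

  fail <- matrix(stats::runif(length(M)) < config$frac_detection_fail,
                 ns, 2L * n)
  detp <- matrix(stats::runif(length(M), 0, 0.009), ns, 2L * n)
  detp[fail] <- stats::runif(sum(fail), 0.011, 1)
  dimnames(detp) <- dimnames(M)

  annotation <- .simulate_annotation(probes, config$frac_snp_overlap)

  truth <- data.frame(probe_id = probes, class = cls,
                      baseline_beta = base_beta,
                      subject_sd = subj_sd,
                      tissue_offset_m = offset_m,
                      stringsAsFactors = FALSE)

  list(mvalues = .set_domain(M, "mvalue"),
       beta = .set_domain(B, "beta"),
       intensities = list(m = mi, u = ui, alpha = alpha),
       detp = detp, sheet = sheet, annotation = annotation, truth = truth)
}

# Random annotation: feature classes (isoform multi-annotation allowed),
# island classes, gene symbols shared by neighbouring probes, SNP flags.
.simulate_annotation <- function(probes, frac_snp) {
  ns <- length(probes)
  feat_pool <- c("TSS200", "TSS1500", "5UTR", "1stExon", "Body", "3UTR",
                 "intergenic")
  feat_prob <- c(0.08, 0.10, 0.09, 0.05, 0.35, 0.05, 0.28)
  primary <- sample(feat_pool, ns, replace = TRUE, prob = feat_prob)
  second <- sample(feat_pool[1:6], ns, replace = TRUE)
  has_second <- stats::runif(ns) < 0.10 & primary != "intergenic" &
    second != primary
  fc <- vector("list", ns)
  for (i in seq_len(ns))
    fc[[i]] <- if (has_second[i]) c(primary[i], second[i]) else primary[i]
  island <- sample(.island_levels, ns, replace = TRUE,
                   prob = c(0.20, 0.12, 0.12, 0.05, 0.05, 0.46))
  # probes cluster into genes of ~15 consecutive sites; intergenic ones empty
  n_genes <- max(1L, ceiling(ns / 15))
  gene_names <- sprintf("GENE%05d", seq_len(n_genes))
  gene_of <- gene_names[ceiling(seq_len(ns) / 15)]
  genes <- vector("list", ns)
  extra <- stats::runif(ns) < 0.05
  for (i in seq_len(ns)) {
    if (primary[i] == "intergenic" && !has_second[i]) {
      genes[[i]] <- character(0)
    } else {
      genes[[i]] <- gene_of[i]
      if (extra[i] && i < ns) genes[[i]] <- unique(c(gene_of[i],
                                                     gene_of[min(ns, i + 15L)]))
    }
  }
  chrom <- sample(paste0("chr", c(1:22, "X")), ns, replace = TRUE)
  data.frame(probe_id = probes, chrom = chrom,
             pos = as.integer(sample.int(2e8, ns, replace = TRUE)),
             feature_class = I(fc), island_class = island,
             genes = I(genes),
             snp_overlap = stats::runif(ns) < frac_snp,
             stringsAsFactors = FALSE)
}

#' Confusion counts of calls against planted truth
#'
#' @param calls A site result table (e.g. from [call_dmps()] or
#'   [call_smps()]) containing `probe_id` and a logical call column
#'   (`is_dmp` or `is_smp`), or a character vector of called probe ids (in
#'   which case `universe` must be supplied).
#' @param truth The `truth` data frame from [simulate_dataset()].
#' @param positive Which planted class counts as a true positive: `"dmp"`
#'   or `"smp"`.
#' @param universe Probes actually tested; defaults to `calls$probe_id`.
#'   Must cover the same probe set as `truth` restricted to it.
#' @return A list with integer `tp`, `fp`, `fn`, `tn` and derived
#'   `sensitivity`, `specificity`, `fdr` (0 when nothing is called).
#' @export
truth_confusion <- function(calls, truth, positive = c("dmp", "smp"),
                            universe = NULL) {
  positive <- match.arg(positive)
  if (is.character(calls)) {
    if (is.null(universe))
      .stopf("universe must be given when calls is a probe-id vector")
    called <- calls
  } else {
    col <- paste0("is_", positive)
    if (!col %in% names(calls))
      .stopf("calls must contain a logical '%s' column", col)
    if (is.null(universe)) universe <- calls$probe_id
    called <- calls$probe_id[calls[[col]]]
  }
  if (!all(universe %in% truth$probe_id) || !all(called %in% universe))
    .stopf("probe-set mismatch between calls, universe and truth")
  truth_pos <- truth$probe_id[truth$class == positive]
  truth_pos <- intersect(truth_pos, universe)
  tp <- length(intersect(called, truth_pos))
  fp <- length(setdiff(called, truth_pos))
  fn <- length(setdiff(truth_pos, called))
  tn <- length(universe) - tp - fp - fn
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       fdr = if (tp + fp > 0) fp / (tp + fp) else 0)
}
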