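---
title: "Methods: matched-tissue methylation concordance"
author: "methmatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: matched-tissue methylation concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methmatch)
```

# The design and the two questions

`methmatch` analyses a *matched* two-tissue design: bone and blood (or any
two tissues) collected from the same subjects at the same time. Matching
is what makes the central statistic meaningful — with unmatched donors,
between-tissue correlation is confounded by between-person variation and
is systematically over-estimated. With `n` matched pairs the package asks,
per CpG site:

1. **Differential (DMP):** does mean methylation differ between the
   tissues? These sites cannot be read from a surrogate tissue.
2. **Similar (SMP):** does the blood value *track* the bone value within
   individuals? These sites are the useful part of a surrogate.

The two calls are mutually exclusive by construction: SMPs are searched
only among sites that failed to reach differential significance
(`candidate_sites()` keeps DMP-stage `q >= 0.05`), so no probe can carry
both labels.

# Measurement model

Methylation arrays report a methylated (`m`) and unmethylated (`u`)
intensity per site and sample. Two standard transforms are provided:

* `beta = m / (m + u + alpha)` — proportion-scale, biologically readable;
* `M = log2((m + alpha) / (u + alpha))` — unbounded, variance-stabilised,
  used for all modelling.

`alpha` (default 100, intensity units) guards against instability at low
signal. When only β-values are available, `beta_to_m()` applies the logit2
bridge `M = log2(beta / (1 - beta))`; this equals the intensity-based M
only in the `alpha = 0` limit. The gap is exactly `log2(1 + alpha/m)`, so
it vanishes as the methylated channel grows; below `m ≈ 700` (at
`alpha = 100`) it can exceed 0.2 M-units, which is why the package never
mixes the two M definitions within one analysis.

Probe-level QC follows the conventional chain: a probe is dropped if its
detection p-value exceeds 0.01 in *any* sample (the most conservative
aggregation of per-sample detection calls — with 24 samples a single
failure marks the probe unreliable), and if it overlaps a SNP (such probes
measure genotype, not methylation). Detection p-values are consumed, not
computed: computing them needs negative-control probes that are not part
of this data model, so the simulator (or the user's upstream software)
supplies them. Sample-level QC is reported only as per-sample median
intensities (`sample_medians()`); no automatic sample exclusion is
applied because no defensible universal threshold exists.

# Batch correction

`batch_correct()` implements a parametric location/scale empirical-Bayes
adjustment of the ComBat family. Per site, a model with batch indicators
and tissue (the protected biological covariate) is fit by least squares;
residuals are standardised by the pooled variance; per-batch locations and
scales are estimated and shrunk toward across-site priors — normal for
locations, inverse-gamma for scales, both moments-matched — in a single
pass (no joint iteration); the adjusted residuals are restored to the
original scale and model mean. Numerical parity with any particular
implementation of this idea is not claimed, but on simulated data the
output correlates with `sva::ComBat` beyond 0.999 (verified in the test
suite).

Two deliberate choices:

* **Exact mean preservation.** One-pass shrinkage leaves a per-site
  residual location of order `1/sqrt(n)`; a final re-centring restores
  each site's pre-correction mean exactly. This is a pure location shift,
  uniform over samples, so batch-mean *differences* and all downstream
  contrasts are unaffected.
* **Degenerate guards.** Zero pooled variance (noise-free input) and
  zero prior spread are floored at `1e-12`; a batch-constant shift is
  then absorbed exactly. A single batch returns the input unchanged;
  a batch with fewer than two samples is an error.

Why batch correction matters *specifically* here: a batch shift hits both
tissues of a co-batched subject, which induces spurious within-subject
cross-tissue correlation at every site — precisely the statistic the SMP
caller tests. Matched pairs must share a batch (the sample sheet and the
simulator both enforce it) so the shift cancels from paired differences,
and correction removes it from the correlation path.

# The DMP caller

Per site, ordinary least squares of M-values on tissue and age
(`fit_sitewise_model()`); the tissue contrast is bone − blood. Age enters
as a continuous adjustment covariate, never the contrast; a constant
covariate is dropped with a warning rather than breaking the fit.

`moderate_statistics()` shrinks the residual variances: the prior
`(d0, s0^2)` is estimated by matching the mean and variance of
`log s^2 − digamma(d/2) + log(d/2)` to the scaled-F form, inverting the
trigamma function by Newton iteration. Estimates of `d0` above `1e7` are
reported as infinite (at that point the posterior is numerically
indistinguishable from the equal-variance limit). The `prior_df = 0`
override reproduces ordinary t-statistics exactly, `prior_df = Inf` the
fully pooled limit; both limits are tested against their closed forms,
and the estimator against an independent reference implementation.

A site is a DMP iff `q < 0.05` (Benjamini–Hochberg over all analysed
sites) **and** the mean paired β-difference exceeds 0.2. The β filter
uses the *absolute value of the signed subject mean* — "average
difference" read literally — so opposite-direction pairs cancel and only
consistent tissue offsets survive. Direction (hypo/hyper in bone relative
to blood) is the sign of the mean M-difference. `paired_test_crosscheck()`
offers the classical paired-t route; with no age signal the two routes
call identical sets (an acceptance-tested property).

Two-sided p-values are used throughout; direction is reported separately
rather than folded into one-sided tests.

# The SMP caller

Within the candidates, `sitewise_pair_correlation()` computes per site
the Pearson correlation between the subject-ordered bone vector and blood
vector of M-values, and `correlation_test()` the standard transform
`t = r sqrt(n-2) / sqrt(1-r^2)` with `n − 2` df. Degenerate sites (zero
variance in either tissue) yield `NaN` and are excluded from testing with
a logged count; `|r| = 1` maps to `p = 0` by convention.

A site is an SMP iff its correlation `q < 0.05`, `r > 0`, and its paired
β-difference is below 0.2. Two conventions for that β screen are
implemented because the natural readings differ between the two callers:

* `"max"` (default): the largest per-pair `|β_bone − β_blood|` — the
  strictest reading of "no pair differs by more than 20%";
* `"mean"`: the subject-averaged difference, symmetric with the DMP rule.

The positive-`r` requirement is a design decision: a site whose tissues
anti-correlate strongly would pass a two-sided test but is not "similar"
in any usable sense. Observed correlation bounds among called sites (e.g.
a smallest passing `r` around 0.7 at `n = 12`) *emerge* from the q-cut
and are not input thresholds.

Sites are classed by overall mean β: hypo below 0.2, hyper above 0.8,
mid otherwise.

# The permutation null

`permutation_null()` breaks the pairing by permuting which subject's
blood column is matched to which bone column (bone fixed, uniform random
permutations, identity allowed — the standard exchangeability null; no
derangement constraint, since the null hypothesis is "pairing carries no
information", under which the identity is as likely as any other map).
Crucially, each iteration re-runs the *entire* selection — correlation,
BH adjustment *within the iteration*, and the β filter against the
permuted pairing — so the null distribution reflects the full procedure,
not just the per-site test. The empirical p-value is
`(1 + #{null ≥ observed}) / (iterations + 1)`, bounded away from zero as
an empirical p must be. Results are bit-reproducible under a fixed seed.

The per-iteration work is a single cross-product per site: row-standardised
matrices are precomputed once, which is valid because permuting a row's
entries changes neither its mean nor its SD. 10,000 iterations is the
conventional default; 500–1,000 are ample for the qualitative question
("is the observed count beyond all null counts?") and are what the tests
use.

# Enrichment reporting

`region_enrichment()` reports, per genomic-feature and CpG-island class,
called hits per array probe in that class. A probe with several feature
annotations (gene isoforms) counts once in each class, so feature hits
may sum to more than the number of calls — mirroring how array
annotations are conventionally tabulated. `locus_overlap()` counts calls
inside a user-supplied catalogue gene list by annotated symbol,
case-insensitively, with no coordinate-window extension: a locus is
"represented" if at least one called site annotates to it. Incidences are
counted by default (a site in two catalogue genes counts twice), with a
`unique_sites` switch. `hypergeom_enrichment()` is the plain
hypergeometric upper tail over a candidate-derived gene universe; no
correction for per-gene probe counts is applied (that correction is a
separate method in its own right), and the output is labelled
accordingly — raw over-representation p-values, no across-set adjustment.

# The synthetic-data generator

`simulate_dataset()` is first-class, tested code, and the basis of every
quantitative claim the package makes about itself. It simulates on the M
scale, where effects are additive, and maps to β by the logistic
relation, so all β values are automatically inside (0, 1).

* **Baselines** follow a three-part mixture — 35% hypo (Beta(2, 18)),
  45% mid (uniform on (0.2, 0.8)), 20% hyper (Beta(18, 2)) — chosen once
  to mimic the bimodal-with-middle shape of array methylation densities;
  real density plots constrain but do not identify this mixture, so it is
  self-defined and tunable, not fitted.
* **SMP sites** add a subject effect `u_j ~ N(0, smp_subject_sd^2)` to
  *both* tissues of subject `j`, plus per-sample noise
  `N(0, noise_sd^2)`; the induced within-subject correlation is the
  intraclass ratio `smp_subject_sd^2 / (smp_subject_sd^2 + noise_sd^2)`
  (≈ 0.94 at the defaults 1.0 and 0.25, in M-value units).
* **DMP sites** get a bone offset sized on the β scale at the site's
  baseline so the planted mean paired β difference equals
  `dmp_delta_beta` (default 0.4, direction random). Baselines for these
  sites are drawn from (0.05, 0.95 − Δβ) so the offset always fits; a
  configuration that leaves no such range is rejected as infeasible.
* **Null sites** carry independent noise only.
* **Technical structure:** subjects are split over batches as evenly as
  possible, pairs always co-batched; batch 2+ samples get a constant
  M shift (default 0.5); a small fraction of cells (default 1.5e-4) fail
  detection with p ~ U(0.011, 1) against U(0, 0.009) otherwise, so the
  0.01 threshold separates them deterministically; 3.4% of sites get SNP
  flags, independent of planted class; ages are uniform on 66–85 years
  with zero true effect by default (`age_slope_sd` plants per-site age
  slopes when covariate adjustment itself is under test). Intensities are
  synthesised as `m = T·β`, `u = T·(1 − β)` with total signal
  `T ~ LogNormal(log 3000, 0.3)`, so the intensity path recovers β up to
  the `alpha` offset.

Defaults mirror the matched bone–blood design that motivated the package:
12 subjects, two batches, ages 66–85. They are fixed study conditions,
not tuning knobs.

**What the generator does not emulate** — and hence what passing tests do
*not* establish about real arrays: probe type I/II chemistry differences,
dye bias, spatial chip artefacts, cell-type composition differences
between tissues, co-methylation blocks (sites are independent given the
planted structure), and genuine age effects. Recovery results on this
generator measure the statistical machinery, not array physics.

# Numerical choices and degenerate inputs

* BH adjustment delegates to the standard step-up implementation;
  NaN p-values propagate to NaN q-values with a warning and do not count
  toward the number of tests.
* Correlations are clamped to [−1, 1] after the vectorised cross-product
  to absorb rounding; `r = ±1` gives `p = 0`; zero-variance rows give
  NaN and are excluded from testing and from permutation counts.
* The trigamma inversion runs Newton steps to relative tolerance 1e-10;
  `d0` above 1e7 is reported as infinite.
* Zero residual variance in the paired t-test follows the `t = ±Inf`,
  `p = 0` convention with a logged count.
* Thresholds are validated to lie strictly inside (0, 1).
* Percentages in overlap reports are returned at full precision; any
  integer display is formatting, applied last.

# Problem sizes

The test suite and the acceptance script size their simulations to what
the statistics need rather than array scale: calibration uses 20
replicates of 5,000 all-null sites; recovery uses 5,000–20,000 sites with
10% planted SMPs and DMPs; the permutation checks use 1,000 iterations on
planted data and 500 under the null; hyperparameter recovery uses 50,000
chi-squared-generated variances. These sizes give Monte-Carlo error
comfortably below every asserted margin.

# Known limitations

* The β filters use uncorrected β values; since pairs share a batch, the
  paired differences are batch-robust up to logistic curvature, but β
  values themselves are not batch-corrected.
* The hypergeometric pathway test ignores per-gene probe counts; genes
  covered by many probes are more likely to be hit by chance, so its
  p-values are anti-conservative for such genes.
* No region-level (DMR) calling, no surrogate-variable estimation beyond
  the single batch factor, no cell-type deconvolution.
* The locus-overlap operation matches annotated gene symbols only; sites
  regulating a gene from outside its annotated structure are missed.
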