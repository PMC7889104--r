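# methmatch

Cross-tissue DNA methylation concordance analysis for matched samples.

## The problem

Many tissues of interest — bone above all — are hard to biopsy, so
epigenome-wide association studies are usually run on peripheral blood.
Whether blood is a usable surrogate depends on *which* CpG sites carry the
same methylation signal in both tissues. Given bone and blood collected
from the same subjects at the same time, `methmatch` answers two questions
site by site:

* **DMPs** — which positions are *differentially* methylated between the
  tissues (and therefore uninformative in a surrogate)?
* **SMPs** — which positions are *similarly* methylated, i.e. blood tracks
  bone within each individual?

The package covers the whole chain — intensity-level QC, β/M-value
computation, empirical-Bayes batch correction, the two callers, a
subject-label permutation null, and enrichment reporting — and ships a
synthetic-data generator that plants SMP/DMP/null sites with known truth,
so power, calibration and false-discovery behaviour can be measured
without any external data.

## The statistics

Per CpG site with methylated signal $m$ and unmethylated signal $u$
(offset $\alpha = 100$):

$$\beta = \frac{m}{m+u+\alpha}, \qquad M = \log_2\frac{m+\alpha}{u+\alpha}.$$

Probes failing detection ($p > 0.01$ in any sample) and probes overlapping
SNPs are removed; batch effects are adjusted by a parametric
location/scale empirical-Bayes correction with tissue protected as a
covariate.

**DMP calling (two-step).** A linear model $M \sim \text{tissue} +
\text{age}$ is fit per site; the tissue contrast is tested with a
moderated $t$-statistic whose posterior variance
$\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$ borrows strength across
sites ($d_0, s_0^2$ estimated by moment-matching $\log s^2$). After
Benjamini–Hochberg adjustment, a site is a DMP iff $q < 0.05$ **and** the
mean paired β-difference exceeds $\Delta\beta > 0.2$. A classical paired
$t$-test is provided as a cross-check; on data without age effects the two
routes call identical sites.

**SMP calling.** Among the non-differential candidates ($q \ge 0.05$ at
the DMP stage), each site's bone and blood M-values are correlated across
subjects (Pearson $r$, $t = r\sqrt{n-2}/\sqrt{1-r^2}$, $n-2$ df). A site
is an SMP iff its correlation $q < 0.05$, $r > 0$, and no pair differs by
more than $\Delta\beta < 0.2$ (a per-pair maximum by default; the
subject-mean rule is a switch).

**Permutation null.** Shuffling which subject's blood is paired with which
bone (10,000 iterations by default) and re-running the full SMP selection
per iteration yields the distribution of the passing count expected by
chance, and an empirical p-value for the observed count.

**Enrichment.** Called sites are profiled by genomic feature (TSS200,
TSS1500, 5′UTR, 1st exon, body, 3′UTR, intergenic) and CpG-island class
(island/shore/shelf/open sea) as hits per array probe in each region;
overlap with a user-supplied disease-locus gene list is counted by
annotated gene symbol; gene-set over-representation uses the plain
hypergeometric upper tail against the candidate-derived gene universe.

## Worked example

```r
library(methmatch)

sim <- simulate_dataset(sim_config(n_sites = 2000, seed = 42))
pp  <- preprocess_pipeline(m = sim$intensities$m, u = sim$intensities$u,
                           detp = sim$detp, annotation = sim$annotation,
                           sheet = sim$sheet)
#> pp$qc: 2000 probes in, 3 failed detection, 55 SNP-flagged, 1942 kept

M <- batch_correct(sim$mvalues[pp$probes, ], sim$sheet)
B <- sim$beta[pp$probes, ]
dmp <- dmp_analysis(M, B, sim$sheet)
smp <- smp_analysis(M, B, sim$sheet, dmp_q = setNames(dmp$q, dmp$probe_id))
sum(dmp$is_dmp); sum(smp$is_smp); nrow(smp)
#> 197 DMPs; 197 SMPs among 1741 candidate sites

head(smp[smp$is_smp, c("probe_id", "r", "p", "q", "max_pair_dbeta",
                       "beta_class")], 3)
#>     probe_id     r        p        q max_pair_dbeta beta_class
#> 15 cg0000016 0.953 1.67e-06 3.61e-05         0.0326      hyper
#> 23 cg0000024 0.968 2.49e-07 1.06e-05         0.0487       hypo
#> 31 cg0000033 0.889 1.09e-04 1.13e-03         0.0510      hyper

truth_confusion(smp$probe_id[smp$is_smp], sim$truth, positive = "smp",
                universe = smp$probe_id)
#> SMP sensitivity 0.98, FDR 0.025 against the planted truth

permutation_null(M[smp$probe_id, ], B[smp$probe_id, ], sim$sheet,
                 n_iterations = 500, seed = 1)
#> observed passing count: 197
#> null counts (n = 500): mean 0.04, max 6
#> empirical p = 0.001996
```

The observed SMP count (197) dwarfs anything seen under the shuffled
pairing (at most 6 in 500 shuffles): the within-subject similarity is far
beyond chance. The called set recovers 98% of the planted similar sites
with a 2.5% false-discovery proportion.

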