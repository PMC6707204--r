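---
title: "Statistical models for de novo and rare inherited variation in trio cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical models for de novo and rare inherited variation in trio cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triodnm)
```

# Scope

`triodnm` implements the statistical core of a family-based exome study of
autism and related neurodevelopmental disorders: burden testing of de novo
variants against a gene-level mutation-rate model, transmission
disequilibrium of rare founder singletons, two-branch detection of
postzygotic mosaic mutations, de novo TADA gene discovery, expression and
network enrichment with matched resampling nulls, and CNV consensus and
aneuploidy utilities. Every stage is driven by a synthetic trio-cohort
generator with recorded ground truth, so the whole pipeline is testable
without access to patient-level data.

# The mutation-rate model and burden tests

The unit of analysis is the expected number of de novo variants of a class
(synonymous, missense, nonsense, splice, frameshift) in a gene set. Each
gene carries a per-haploid-genome, per-generation mutation probability
$\mu_{g,c}$; a cohort of $N$ trios contributes $2N\mu_{g,c}$ expected events
for autosomal genes. Genes on chromosome X are scaled by the at-risk allele
count $2N_\mathrm{female} + N_\mathrm{male}$ instead — an allele-counting
convention we adopt because published descriptions of the female-to-male
adjustment do not give a formula; the choice is configurable through
`cohort_spec()`. The frameshift rate is tied to the nonsense rate by the
conventional factor 1.1.

Platform differences between cohorts are absorbed by a single multiplicative
calibration (`calibrate_to_silent()`): all rates are rescaled so the
exome-wide expected synonymous count matches the observed one. Synonymous
SNVs are used because they are the closest thing exome data offer to a
selectively neutral mutation readout. The calibration is exact and
idempotent by construction.

Observed counts are compared with expectations by a one-sided exact Poisson
tail, $P(X \ge x)$ computed through the regularized incomplete gamma
function (`poisson_upper_test()`); $x = 0$ returns exactly 1. We use the
upper tail only because the scientific question is an *excess* of damaging
variation; synonymous classes serve as the negative control within
`burden_table()`.

# Transmission disequilibrium of founder singletons

A variant seen in exactly one parent is transmitted to the child with
probability 1/2 under Mendelian segregation, regardless of ascertainment —
this makes singleton transmission a self-calibrating test. Genotypes first
pass QC (depth ≥ 10, GQ ≥ 30, allele-balance windows 0.3–0.7 for
heterozygous SNVs, 0.25–0.75 for heterozygous indels, treated as closed
intervals since their source states plain ranges), and sites missing in more
than 25% of founders are dropped.

Call artifacts depress the apparent transmission rate, so a variant-quality
(VQSLOD) threshold is calibrated per variant type: `calibrate_vqslod()`
scans the observed scores in descending order and returns the smallest
threshold at which neutral singletons (synonymous SNVs, nonframeshift
indels) are transmitted 50% of the time, within one binomial standard error
at the retained count, preferring the threshold that retains the most
variants. Two caveats follow from this design and are worth stating
plainly. First, the cumulative transmitted fraction is a random walk: even
on artifact-free data it exits a 1-SE band for about a third of datasets at
the full-retention end, in which case the calibrated threshold retreats and
some clean variants are discarded. This is conservative, never
anticonservative — held-out neutral transmission stays at 50% either way —
and the band width is exposed (`band_se`) for users who prefer a wider
tolerance. Second, when no threshold reaches the band the function returns
the minimizer of the deviation with a warning flag rather than failing.

The test itself (`transmission_test()`) is a two-sided exact binomial test
under the minimum-likelihood convention, which is what reproduces printed
two-sided p-values such as 0.038 for a 464:402 split; a one-sided reading
would halve them. Loss-of-function singletons additionally pass a
high-confidence transcript-fraction rule (> 60% of transcripts, strict).

# Mosaic mutation detection

Postzygotic mutations appear in a fraction of cells and show variant allele
fractions (VAF) below the heterozygous expectation of 0.5. Two parallel
branches are implemented.

The **filter/binomial-deviation branch** (`ohsu_classify()`) demands at
least 5 alt reads, a parental alt count of at most 4, and labels a site
mosaic when the exact two-sided binomial deviation from 0.5 (`phet()`) is at
most $10^{-3}$ *and* the upper bound of the 90% Clopper–Pearson interval on
the VAF (`vaf_ci_upper()`) is below 0.4. Clopper–Pearson is chosen because
it is exact at the small alt-read counts where mosaic calls live; the 90%
two-sided level places 0.05 in each tail. A published variant of this branch
also applies a candidate-level ceiling of 0.05 on the same upper bound,
which contradicts the 0.4 call criterion; we treat the 0.4 rule as operative
and expose the ceiling as a disabled-by-default option (`ci_filter_max`).
The branch's original logistic-regression score is a trained model we do not
reimplement; externally computed scores can be supplied and gated at their
published threshold.

The **empirical-Bayes branch** models alt reads at apparent de novo sites as
a two-component mixture of beta-binomials sharing an overdispersion
parameter $\rho$. The beta-binomial is parameterized throughout by its mean
$p$ and overdispersion $\rho \in [0, 1)$ with $\alpha = p(1-\rho)/\rho$,
$\beta = (1-p)(1-\rho)/\rho$, so that $\rho = 0$ degenerates exactly to the
binomial and $\mathrm{Var}(X) = Np(1-p)\,[1 + (N-1)\rho]$.
$\rho$ is estimated from inherited heterozygous sites (`estimate_theta()`)
by binning on depth (width-10 bins over 1–500; bins under 50 variants merge
into their nearest neighbour, since per-depth bins are too sparse in
realistic cohorts), maximizing the likelihood per bin with the mean fixed at
0.5, and averaging bins weighted by variant count. The germline component is
then $\mathrm{BB}(N, 0.5, \hat\rho)$ and the mosaic component the average of
$\mathrm{BB}(N, f, \hat\rho)$ over a grid of candidate mosaic VAFs —
by default 50 uniform points on (0.01, 0.50], a deliberately
uninformative prior since true mosaic VAF distributions are unknown.
EM (`em_mosaic()`) iterates responsibilities and the mixture weight
$\pi_m$ to a log-likelihood change below $10^{-8}$ (cap 1000 iterations,
non-convergence flagged); the log-likelihood is asserted non-decreasing on
every run. Per-site posterior odds are
$\pi_m L_m / ((1-\pi_m) L_g)$, and the q-value of a site is the mean
posterior germline probability among all sites at or above its odds — the
cumulative-mean Bayesian FDR convention. Sites with odds above 1 *and*
q ≤ 0.1 are labelled high-confidence mosaic; the union rule
(`union_mosaic_callset()`) keeps EM-branch calls, plus filter-branch calls
whose posterior odds exceed 1 even when the EM label was germline.

Parameter-recovery tests run the EM with the VAF grid matched to the
generator's mosaic prior (uniform on 0.03–0.35): recovery of $\pi_m$ is a
well-posed question only when the analysis model matches the generating
process. With the wide default grid the mosaic component overlaps the
germline component near 0.5 and $\pi_m$ absorbs a few percent of germline
sites — expected behaviour of a deliberately agnostic prior, not an
estimation defect. Under the study conditions (depth ≈ 80, $\rho = 0.05$,
mosaic VAFs up to 0.35) germline and mosaic VAF distributions genuinely
overlap, which caps the achievable rank correlation between responsibilities
and truth labels near 0.5; the package's tests assert recovery at that
Bayes-achievable level rather than an aspirational one.

# TADA gene discovery

For each gene and variant class the de novo count is Poisson with null mean
$\lambda_0 = 2N\mu$ (silent-calibrated) and alternative mean
$\lambda_0\gamma$ with $\gamma \sim \mathrm{Gamma}(\bar\gamma, 1)$. The
class Bayes factor has the closed form
$$\mathrm{BF} = \frac{\Gamma(x+\bar\gamma)}{\Gamma(\bar\gamma)}
\frac{e^{\lambda_0}}{(1+\lambda_0)^{\bar\gamma + x}},$$
computed in log space (`bf_class()`, general shape/rate). Defaults follow
the study's architecture: 5% of genes are risk genes, prior mean relative
risks 18 for LGD and 6 for damaging missense (CADD ≥ 25). Class Bayes
factors multiply; the posterior null probability
$(1-\pi)/((1-\pi)+\pi\,\mathrm{BF})$ is averaged down the BF ranking to give
Bayesian FDR q-values, with ties sharing the worst q of their block and
broken by gene id for reproducibility. Genes absent from the rate table are
excluded and reported rather than given infinite evidence. Only the de novo
arm is shipped; inherited/case-control extensions are hooks, not defaults.
Expected chrX counts inside TADA use the same allele-count scaling as the
burden module.

# Expression and network enrichment

Laminar specificity is a per-gene Welch $t$ comparing log2(RPKM+1) in one
layer against all others (Welch because layer sample sizes and variances
differ; the unequal-variance form costs nothing when they do not). Genes
with RPKM < 1 in at least 20% of samples are dropped first (inclusive
boundary). A gene set's score is its mean $t$, compared against null sets
drawn gene-for-gene from joint decile bins of transcript length and GC
content — 10,000 sets by default, drawn without replacement within bins;
bins too small to supply matches widen to neighbouring deciles with a
warning. Enrichment is reported both in null-SD units and as the
add-one empirical p-value $(1+\#\{\mathrm{null}\ge\mathrm{obs}\})/(n+1)$,
whose floor is $1/(n+1)$. Cell-type specificity is the mean expression in
one type over the sum of means across types, a row-stochastic index
invariant to global rescaling.

Network over-connectivity treats the observed edge list as a uniform draw
from all unordered gene pairs over the universe and asks whether the count
of edges spanning two sets is hypergeometrically surprising. The edge
universe (all pairs vs. a thresholded interactome) is the caller's choice
of `universe`; the test itself is exact.

# CNV consensus and aneuploidy

Calls from two pipelines merge when reciprocal overlap is at least 50% in
both directions or one call contains the other; the intersection is
reported. A call may also be matched cumulatively by several calls from the
other pipeline (summed overlap ≥ 50% both ways), in which case the per-pair
intersections are merged by union — one of several defensible readings of
cumulative matching, chosen and documented here. Thresholds ("at least
50%", "at least 75%") are inclusive. Coordinates are 0-based half-open
internally, matching BED. Calls with ≥ 75% of their length in segmental
duplications are excluded, as are de novo calls touching blocklisted genes
(copy-number-hypervariable regions). Inheritance labelling prefers any
parental match over de novo; matches in both parents are recorded as both,
never resolved arbitrarily.

The aneuploidy scan estimates per-chromosome copy number as twice the
depth ratio to chromosome 1 (unmultiplied for X and Y, following the
source convention of reporting sex chromosomes on the ratio scale) and
flags a chromosome only when the depth estimate and the heterozygous
allele-balance deviation (mean |VAF − 0.5|) are *both* outliers — the
dual-evidence rule that protects against batch depth artifacts. Default
outlier cutoffs (0.4 copies, 0.1 VAF deviation) sit midway between the
null and trisomy expectations (a 2:1 allelic ratio puts heterozygous VAFs
near 1/3, deviation ≈ 0.17).

# The synthetic cohort generator

`sim_config()` pins the generator to the study conditions: 465 trios with
89 female probands, an exome whose summed LGD mutation rate gives 48.3
expected de novo LGD events in that cohort, 5% risk genes with
Gamma(18,1)/Gamma(6,1) relative risks, beta-binomial read-depth
overdispersion $\rho = 0.05$, a 10% mosaic fraction among apparent de novo
SNVs with true VAFs uniform on (0.03, 0.35) — inside the band detectable
under the ≥ 5-alt-read and CI < 0.4 rules — negative-binomial depth of mean
80 capped at 500, and a transmission probability of 0.536 for
constrained-gene LGD singletons (the value matching a 464:402 split).
Values not fixed by the study are set once to field-typical levels:
synonymous and missense exome rates of 0.15 and 0.325 per haploid genome
(≈ 0.3 and 0.65 events per birth), 43.6% of missense rate mass damaging at
CADD ≥ 25, 4% of genes on chromosome X, ~22% of genes constrained,
VQSLOD scores from a two-component normal mixture with artifacts at 15%
prevalence transmitting at 0.25.

The generator produces annotated variant tables, not reads: it emulates
counts, depths, allele fractions, strand splits, scores and labels, but no
sequence context, no alignment artifacts, no caller disagreement, and no
relatedness structure. Tests passing on these data therefore validate the
statistical machinery — calibration, estimation, error control — and not
robustness to upstream bioinformatic failure modes, which is out of scope.
Every generator is deterministic given the configured seed; distinct seeds
offsets per generator keep the streams independent.

# Problem sizes and numerical choices

The test suite runs scaled-down but statistically meaningful sizes chosen as
the package's own verification budget: 10,000-site simulations across 20
seeds for overdispersion and mosaic-fraction recovery; 1,000 replicates for
type-I error of the burden test; 20 synthetic cohorts of 800 genes for TADA
FDR calibration; 1,000 random interval pairs for the CNV consensus oracle;
100 replicates of 200-iteration resampling for enrichment null calibration.
Exact-test routines (`phet`, `vaf_ci_upper`, `poisson_upper_test`,
`bf_class`) are verified against independent brute-force oracles
(pmf summation, root-finding on the binomial CDF, adaptive numerical
integration) at 1e-8 to 1e-12 tolerances. All mixture and Bayes-factor
arithmetic is in log space; `optimize()` bounds for $\rho$ are [0, 0.99]
with near-boundary estimates collapsed to 0.

# Known limitations

* The mosaic module covers SNVs only; mosaic indels and burden inference
  from mosaic calls are out of scope by design.
* The VQSLOD calibration band is a per-threshold criterion, not a
  simultaneous confidence band; see the caveat above.
* The hypergeometric edge-universe and the chrX allele-count convention are
  documented choices where the field's descriptions are silent; both are
  parameters, not constants.
* The generator's mosaic VAF prior is a stand-in. Nothing in the package
  should be read as an inference about the true cellular-fraction
  distribution of postzygotic mutations.
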