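---
title: "Methods: targeted bisulfite amplicon methylation analysis with methpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: targeted bisulfite amplicon methylation analysis with methpanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methpanel)
```

## Scope and model

`methpanel` analyses targeted bisulfite amplicon sequencing of a small gene
panel: short (130--260 bp) PCR amplicons, each covering a CpG island or
CpG-containing regulatory region, sequenced after sodium bisulfite
treatment. Unmethylated cytosines deaminate and read as T; 5-methylcytosines
stay C. A read therefore encodes the methylation state of every CpG it
covers, and the non-CpG cytosines act as an internal chemistry control:
they should essentially all read T, and their conversion fraction is the
read's *conversion rate*.

The packaged panel (`cf_panel()`) models a 14-amplicon design over CFTR and
13 cystic fibrosis lung-modifier genes on GRCh38, with 194 CpG sites in
total. Coordinates are 1-based and inclusive at both ends; each declared
amplicon size equals `end - start + 1`, which `validate_panel()` checks.
One published end coordinate (EDNRA) is truncated in its source table; the
package carries the unique completion consistent with the declared 260 bp.
The amplicon *sequences* are not published, so the packaged FASTA holds
synthetic sequences generated to match each declared length and CpG count
exactly; they support simulation and pipeline testing, not genomic lookup,
and are labelled synthetic in the file and its documentation.

## Calling pipeline

`call_methylation()` re-implements the four classic steps:

1. **Demultiplexing** by exact barcode prefix match (optionally after a
   fixed-length adaptor), trimming the barcode from retained reads.
2. **Amplicon assignment** by ungapped bisulfite-aware matching: a read and
   its reverse complement are compared against each amplicon's top- and
   bottom-strand bisulfite references; at reference cytosine positions both
   C and T are accepted (methylated or unconverted vs converted), everything
   else must match. The best amplicon wins; a best mismatch fraction above
   10% (configurable) leaves the read unassigned. Ungapped matching is a
   deliberate choice for 130--260 bp amplicons: reads with indels fail
   assignment rather than being realigned, which keeps the per-position
   call semantics exact.
3. **Conversion filtering**: the conversion rate is the fraction of
   informative non-CpG cytosine positions read as T (positions showing any
   other base are ignored). Reads with a rate below the minimal conversion
   rate 0.97 are discarded. The threshold is *inclusive* (0.97 is kept)
   because the rule is phrased as a minimal acceptable rate. Reads with
   zero informative positions are retained with a flag: the filter is about
   evidence of conversion failure, and every panel amplicon carries dozens
   of non-CpG cytosines, so the case is pathological.
4. **Calling and aggregation**: at each CpG, C is 1 (methylated), T is 0,
   anything else missing. Site fractions are methylated/total over retained
   reads; the region mean is the unweighted mean of site fractions over
   sites with at least one call. Bottom-strand and reverse reads are
   reoriented so all reports use top-strand 1-based site order.

### Coverage filter

A region-level measurement is retained when its depth makes the estimate
precise enough: with region mean $\hat p$ and $n$ retained reads, the
binomial standard deviation $\sqrt{\hat p(1-\hat p)/n}$ must satisfy
$\mathrm{SD}/\hat p < 5\%$ (coefficient of variation) *or*
$\mathrm{SD} \le 1\%$. The second branch exists because the CV condition is
unattainably stringent for very small methylation fractions. Both bounds are
closed-form in $\hat p$ and $n$; the test suite confirms the minimal
retaining depth against a brute-force scan. Two consequences are worth
knowing: $\hat p = 0$ or $1$ gives an SD estimate of 0 and automatic
retention (a degenerate but faithful reading of the rule), and at low
baseline methylation (2--10%) the rule demands roughly 250--300 reads, so
thin libraries lose many low-methylation measurements. The filter is applied
per region-level measurement; a per-site variant is available
(`filter_level = "site"`), since the granularity is not dictated by the
rule itself.

## Statistics

**Logit scale.** Mean methylation percentages are compared on the logit
scale $\ln(p/(1-p))$. Between-sample biological variation behaves
approximately log-odds-normally: on the raw scale its variance peaks at 50%
and vanishes at the boundaries, while the logit returns it to a common
scale. (For pure binomial sampling noise the transform does *not* change
the variance ratio across baselines -- the delta-method ratio is identical
-- so the homogenization argument, and our test of it, concern the
between-sample component.) Fractions are clamped to $[\varepsilon,
1-\varepsilon]$ with the depth-adaptive default $\varepsilon = 1/(2n)$,
half the smallest observable fraction, which keeps ordering and flags
clamped values.

**Repeatability.** Technical duplicate libraries give a pooled within-pair
standard deviation $\sqrt{\sum_i d_i^2 / 2k}$ over $k$ complete pairs, one
degree of freedom per pair, incomplete pairs dropped and counted. The
difference-based estimator is our choice among equivalent formulations; a
two-way model would be needed only if duplicates were crossed with batches.

**Group comparisons.** The test is selected from the data's own
diagnostics, all stored for reproducibility: Shapiro--Wilk normality per
group and median-centered Levene homoscedasticity across groups, both at
$\alpha = 0.05$ (configurable). Two groups: Student / Welch / Wilcoxon;
more: one-way ANOVA / Kruskal--Wallis. Groups too small for Shapiro--Wilk
(n < 3) count as non-normal, which degrades safely to the rank tests.

**Per-CpG tests.** Each site is tested with a two-sided Fisher exact test
on the 2x2 table of methylated/unmethylated read calls pooled within
case and control groups, with Bonferroni control of the family-wise error
rate at 5% over the sites tested per tissue (the per-tissue family mirrors
how differential sites are reported per tissue). The adjusted value
reported is $q = \min(1, m\,p)$. Pooling reads ignores between-sample
overdispersion, so on cohorts with real biological variability the test is
anticonservative -- the full-cohort demonstration in
`scripts/acceptance.R` makes this visible by flagging sites outside the
planted genes. This is a faithful property of the pooled-read construction
(the per-read 0/1 calls are exactly what the calling stage emits); a
per-sample summary alternative is the natural extension and is noted as an
option, while the calibration tests use common-p nulls where the test is
exact.

**Co-methylation networks.** Spearman correlations between all pairs of
(gene x tissue) mean-methylation variables over pairwise-complete
observations (at least 5 pairs), computed separately for the control and
case strata; edges are pairs significant under Bonferroni FWER 10%.
P-values are evaluated against the exact tie-free permutation null of the
Spearman coefficient, approximated by Monte Carlo with $B = 50{,}000$ draws
and the add-one estimator $(1 + \#\{|\rho^*| \ge |\rho|\})/(B+1)$, cached
per sample size under a fixed internal seed. We chose this over the usual
t and Edgeworth approximations because at $n \approx 24$--$48$ both are
anticonservative at the $0.10/378$ Bonferroni tail, which breaks the very
guarantee the procedure advertises; the add-one Monte Carlo p-value is
valid by construction, at the cost of a p-value floor of $1/(B+1)$ and
mild conservatism under ties.

**Genotype association.** Spearman correlation between 0/1/2 allele dosage
and methylation; negative means methylation falls with each allele copy.

## PLS discriminant classification

`fit_plsda()` is a hand-written NIPALS PLS1 regression of the class
response, coded -1 (control) / +1 (case), on autoscaled descriptors
(zero mean, unit variance; "normalization" is not further specified in
this field's usage, and autoscaling is the standard reading). Successive
scores are orthogonal and each component deflates the descriptor matrix;
with as many components as the matrix rank the fit reproduces ordinary
least squares, which the tests verify, and the implementation is
cross-checked against an independent PLS implementation. Two components
are the default because two score axes are what is conventionally
plotted and interpreted.

Classification thresholds the predicted response at zero. The default
sign mapping is the one consistent with the coding (positive estimate,
case class); the opposite mapping is available as a configuration because
descriptions of this construction in the literature sometimes state the
reverse convention. An exact zero is a tie: assigned to the control side
and flagged. Accuracy is reported as leave-one-out cross-validation by
default -- resubstitution is also reported, since published percent-correct
figures often do not say which was used -- and descriptor sets restricted
to blood, to the second tissue, or to both are evaluated under the
identical protocol. Missing descriptors (samples without one tissue) are
imputed with the class-agnostic descriptor mean by default, with a
drop-sample option; degenerate cross-validation folds fall back to fewer
components, and a completely uninformative fold predicts the training
majority class.

## Synthetic cohort generator

Because no sequencing data are deposited for the study design this package
targets, `cohort_design()` / `truth_model()` / `simulate_reads()` generate
a cohort with the statistical structure the analysis assumes, and every
planted parameter is returned in truth tables for recovery testing.

Defaults emulate the study conditions: 24 controls and 48 patients in
three severity strata (23/13/12), blood from all 72, nasal epithelial
cells missing for 9 patients, technical duplicates in both tissues for 4
patients; per-gene baselines with one near-fully methylated gene (~95%
blood / ~83% NEC), one intermediate (~38% / ~26%) and the rest below 20%;
read depth log-uniform on [9, 2704] (only the range is reported for the
original data; log-uniform reproduces its heavy spread); bisulfite
conversion failure 1% per cytosine (read-level threshold 0.97 is the only
published constraint; per-cytosine independence is our modelling choice);
substitution error 0.2%.

Between-sample variation is beta-distributed per CpG around a logit-scale
mean combining baseline, planted group offsets (uniform "case" shifts or
ordinal severity trends, so monotone and U-shaped severity profiles can
both be planted), a genotype-dosage slope (default -0.7 per allele at one
gene, giving Spearman correlations near -0.4 as reported for such loci),
and latent factors: a per-sample factor shared across tissues (inter-tissue
co-methylation, default loading 1.0 at the genotype gene) and optional
stratum- or tissue-restricted module factors. A per-(sample, tissue, gene)
random effect (SD 0.4 logit units) shared by the gene's sites gives
region-mean between-sample SDs of roughly 0.4--0.5 logit units, matching
the magnitude reported for such cohorts. The beta-binomial family itself
is an assumption -- the distributional family of between-sample methylation
variation is not published -- and is flagged as such.

Technical duplicates share their biological sample's latent methylation
probabilities, so duplicate disagreement reflects sequencing noise only;
real duplicate experiments add library-preparation variance the generator
does not model, and simulated repeatability SDs are accordingly smaller
than wet-lab ones. Other omissions: platform-specific homopolymer errors,
primer bias, and any dependence of depth on methylation. Passing tests
therefore demonstrate the pipeline's correctness and calibration under a
faithful statistical emulation, not performance on any real cohort.

All randomness flows from a single seed through fixed per-stage streams,
so stages can be re-run independently and the same seed yields
byte-identical FASTQ output.

## Problem sizes used in the checks

The test-suite and `scripts/acceptance.R` use these sizes, chosen to make
Monte-Carlo error small relative to each property being checked: calling
recovery on 5 samples x 2 tissues x 14 amplicons at depth 500 (1,940
site-level entries, 3-binomial-SD coverage >= 99%); conversion-filter
exactness on ~26,000 reads at the default 1% failure rate; type-I error of
test selection over 500--1000 null cohorts at the study's group sizes;
Fisher-vs-enumeration on all 2x2 tables with margins <= 30 (suite) or
2,000 random such tables (script); Fisher+Bonferroni family-wise error
over 400--1000 null cohorts of 194 sites with common per-site p;
planted-effect recovery (1-logit offsets at 6 CpGs of one gene, depth 300)
over 30--50 study-sized cohorts; network false-edge rate over 400--1000
null runs at the case-stratum size (n = 48, the stratum where
co-methylation modules are planted) with the estimate allowed its binomial
sampling error around the 10% guarantee; module recovery over 30--40
cohorts; PLS-DA chance-level calibration over 100--200 permuted balanced
cohorts. The bundled `demo_config()` scales the cohort to 20 samples with
depth 100--800 so the complete chain runs in well under a minute.

## Known limitations

* Pooled-read Fisher tests are anticonservative under between-sample
  overdispersion (see above); treat full-cohort per-CpG hit lists as
  screening output.
* The coverage filter at the published thresholds discards a large share
  of thin low-methylation measurements; retention percentages are logged
  at every run.
* Amplicon assignment is ungapped and panel sequences in the packaged
  demo are synthetic stand-ins.
* Multivariate adjustment for clinical covariates is out of scope; no
  model for it is specified in the source design.
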