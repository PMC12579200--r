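---
title: "Methods: trio-based de novo SNV discovery, burden and clinical association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trio-based de novo SNV discovery, burden and clinical association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triodnv)
```

# The problem

A de novo single-nucleotide variant (dnSNV) is present in a child but in
neither biological parent's germline. In trio whole-exome sequencing the raw
signal is a Mendelian violation — child heterozygous, both parents
homozygous reference — but that signal is contaminated by *missed
heterozygotes*: a parent who truly carries the variant is genotyped
homozygous reference (low depth at the site, allele dropout, reference-biased
calling), so an inherited variant masquerades as de novo. Small-cohort
studies of childhood-onset neuropsychiatric disorders in founder populations
depend on getting this discrimination right, because each proband carries
only about one coding dnSNV per generation.

`triodnv` implements the full analysis sequence: cohort quality control,
a programmatic candidate filter cascade (in place of manual read
inspection), mutation-rate and class-wise burden statistics, gene-overlap
and gene-set enrichment, and the clinical regression harness. A synthetic
trio-cohort generator with known ground truth makes every stage testable
without access to protected sequencing data.

# The synthetic cohort: what it emulates

`sim_config()` defaults are the study conditions: 36 trios, a
33,828,798 bp coding exome, a true dnSNV rate of 1.4e-8 per nucleotide per
generation, ~100x mean depth. Per trio the number of true dnSNVs is
Poisson(rate x exome x 2 gametes) ≈ Poisson(0.947); each is spiked as a
heterozygous proband call with alt-read fraction Binomial(depth, 1/2)/depth
and clean homozygous-reference parents. Around it the generator emits:

* **Inherited variation** obeying Mendelian transmission: a common tier
  (allele frequencies 0.05–0.95, shared cohort-wide; drives kinship and
  PCA) and a family-private rare tier (one het parent; the tier that could
  be mistaken for de novo).
* **Missed-heterozygote artifacts**: with probability `missed_het_rate`
  (default 0.002 of eligible parental-het transmissions), a transmission
  where the child is het, one parent het and the other homref is emitted
  with the carrier parent recoded homozygous reference but retaining a
  residual alt-read fraction drawn Uniform(0.06, 0.25). The lower bound
  sits just above the 5% parental-read threshold, so the artifact is
  *catchable by exactly the filter that exists to catch it*, and by nothing
  else: its annotation, frequency and proband support look de novo. The
  artifact parent keeps a confident (GQ 50) homref emission, emulating the
  reference-biased caller errors that motivate read-level inspection; a GQ
  computed naively from the read counts would mark the call dubious and the
  site would be removed as missing, which is precisely not how these errors
  present in practice.
* **X-chromosome sites** with hemizygous males (emitted as homozygous
  calls), for the sex-check F statistic.
* **Clinical covariates drawn under the null** (no dnSNV–severity or
  parental-age effect) unless effect sizes are supplied: parental ages
  Normal(30, 5) years, diagnosis age Normal(13, 2.48) truncated to
  childhood onset, CY-BOCS Uniform over 8–36 with one-sixth missing
  (mirroring the per-model sample sizes of 32/31/36/30), binary risk flags
  Bernoulli(0.2), 53% female probands.

Depths are negative binomial (mean 100, dispersion 10) because the study
conditions state thresholds, not distributions; GQ is derived
deterministically from the binomial genotype-likelihood margin. The
consequence-class mix (missense 0.60, nonsense 0.04, splice 0.05,
synonymous 0.31) gives the canonical ~2.23:1 non-synonymous:synonymous
expectation. What the simulator does **not** model — and what passing tests
therefore do not establish about real data — includes sequencing-error base
substitutions, alignment artifacts, linkage disequilibrium, capture-bias
depth structure along the exome, and real hg19 coordinates (variants live
on a toy gene map).

# Quality control

Genotype calls failing GQ ≥ 20 or DP ≥ 20 are set missing rather than
removing the site; a site then fails if cohort missingness reaches 10% or
it lies in a blacklist interval (BED, converted once at the boundary from
0-based half-open to the package's 1-based convention). This matches
genotype-level filtering semantics in standard toolchains and makes
`filter_variants()` idempotent.

Sex is imputed as F = 1 − observed/expected X heterozygosity (expectation
from Hardy–Weinberg at cohort allele frequencies), with the conventional
0.8/0.2 male/female cutoffs and an undetermined band between. Kinship uses
the KING-robust estimator
φ = (N~het,het~ − 2·N~opposite-hom~)/(N~het,i~ + N~het,j~) with the standard
classification bands at 2^−1.5^, 2^−2.5^, 2^−3.5^, 2^−4.5^; trio validation
requires both parent–child pairs first-degree and the parents unrelated.
Ancestry PCA standardizes each SNP by √(2p(1−p)) with p from the reference
panel, takes the SVD of the reference, projects the cohort onto those axes,
and flags a sample whose first five scores deviate more than six reference
SDs from the target-cluster centroid. The six-SD rule is this package's
choice of a concrete implementation of "tight clustering"; it is
deliberately loose enough that a homogeneous cohort is untouched and a
cross-cluster sample is unambiguous.

# The candidate filter cascade

`detect_mendelian_candidates()` emits one candidate per (proband, site)
with proband het and both parents homref, all three calls non-missing.
`apply_dnv_filters()` then records, per candidate, the outcome of seven
independent predicates: retained consequence class
(missense/nonsense/splice/synonymous); cohort singleton (the alt allele in
exactly one proband — parental carriers have already failed the Mendelian
step, so proband genotypes are what remain to count); population frequency
strictly below 1% *or* absent from the reference population ("absent" is
retained information, not zero, and passes); proband alt fraction ≥ 30%
(boundary kept); each parent's alt fraction ≤ 5% (above 5% removed);
minimum alt base quality ≥ Phred 20; and a Fisher exact strand-bias test
failing at phred-scaled 60 (the convention of standard callers). Alt
fractions are computed from AD, not DP, since DP may count other alleles.
A filter whose inputs are unavailable records `not-evaluable` and cannot
fail a candidate, so sparse annotations degrade conservatively. Because
the predicates are independent, the pass set is invariant to filter order;
the recorded trail is presentational.

The splice class includes `splice_region_variant`, not only canonical
donor/acceptor terms: the variants this pipeline must reproduce include
+3 and −4 positions, which a canonical-only mapping would misclassify.
Probands with more than 5 passing calls are flagged, not removed.
CADD PHRED > 20 (strictly) marks the top 1% deleteriousness tier.

# Burden statistics

The de novo mutation rate is (dnSNVs/proband) / (exome size x 2
gametogeneses). The default 95% CI is a normal approximation on the
per-proband counts (mean ± 1.96·sd/√n, rescaled); this is the method that
reproduces the reference interval to printed precision, and a
chi-square-based exact Poisson interval on the total count is available as
`method = "poisson-exact"` and labelled as such. The non-synonymous :
synonymous comparison is the standard two-count Poisson exact test
(conditional binomial given the total), cross-checked in the tests against
independent enumeration.

Class-wise enrichment follows the mutational-model convention: the
probability of a dnSNV per gene, class and gamete is summed over genes,
scaled by 2 x n~probands~ transmitting copies to an expected count, and
the observed count is compared by the Poisson upper tail P(X ≥ obs), with
BH-FDR across the tested classes. `build_probability_table()` constructs
such tables from gene models: every possible SNV over the CDS plus the
splice windows (8 intronic and 3 exonic bases from each exon/intron
boundary, mirroring the consequence mapping above) is enumerated,
classified by codon translation — splice taking precedence, stop-loss
grouped with missense so the classes partition the rate mass — and weighted
by a trinucleotide-context rate table supplied as data (a uniform toy table
ships for tests; the published human tables are external data, and a
per-class stand-in back-derived from reported observed/expected ratios is
packaged and labelled synthetic).

# Clinical models

CY-BOCS totals ≥ 24 are severe, < 24 mild-to-moderate, missing stays
missing and drops out of the severity model (listwise deletion throughout,
matching per-model sample sizes). `fit_linear()`/`fit_logistic()` report
per-predictor estimates, Wald 95% CIs, BH-FDR across each model's
predictors, Shapiro–Wilk residual normality, VIFs (flagged at 5 linear, 10
logistic), McFadden's R² with the > 0.4 flag, an events-per-variable flag
for small-cohort logistic fits, and a residual-vs-fitted table for visual
homoscedasticity assessment — no automated decision is made there.

Post hoc power uses the noncentral-F convention λ = f²(u + v + 1) with
u the number of non-intercept predictors and v = n − u − 1, solved by
bisection to |Δpower| < 1e-6. This convention was adopted because it is the
one under which all four cohort models' minimal detectable effects
(0.592, 0.618, 0.507, 0.900 at N = 32, 31, 36, 30 with 7, 7, 7, 11
predictors) are reproducible to three significant figures; the alternative
single-predictor numerator df is available by passing a different `u`.

# Numerical and testing choices

* Poisson goodness of fit for the simulator's dnSNV counts is tested by a
  chi-square test on the binned pmf rather than Kolmogorov–Smirnov, which
  is ill-calibrated for discrete counts with ties.
* BH-FDR is monotone in the raw p-values and deterministic; it is *not*
  idempotent (re-adjusting adjusted values can only increase them), and the
  tests assert exactly that.
* Hypergeometric enrichment is validated against brute-force tail
  enumeration and the one-sided Fisher exact test to 1e-10.
* The probability-table builder is validated against an independent
  re-enumeration oracle (plain loops, Biostrings translation with
  `no.init.codon = TRUE` — the default initiator-codon behaviour silently
  turns leucine starts into methionine and is a genuine trap).
* Problem sizes in the test suite (500-trio Poisson calibration, 200
  replicate cohorts for CI coverage, 500-replicate type-I error, 5000-SNP
  kinship simulations) were chosen as the smallest sizes at which the
  Monte-Carlo error is comfortably below each assertion's tolerance.

# Known limitations

Indels, CNVs and non-coding variants are out of scope; annotations are
consumed, not computed (no VEP/CADD re-implementation); the singleton rule
interprets "observed once in the cohort" over proband genotypes;
gene-symbol matching is exact after case-folding with no alias resolution;
and the regression harness performs no imputation — probands missing a
model's covariates are excluded from that model, as in the reference
analysis.
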