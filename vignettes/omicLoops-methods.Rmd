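---
title: "Methods: signed multi-omic association networks and coherent loops"
author: "omicLoops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signed multi-omic association networks and coherent loops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omicLoops)
```

# The problem

Childhood obesity emerges from an interplay of host genetics, the developing
gut microbiome, and circulating metabolites. Testing every variable of every
omic against every other is statistically hopeless at cohort scale, so
omicLoops implements a sequential, dimensionality-reducing design in three
phases of covariate-adjusted pairwise association testing, followed by a
network integration whose unit of evidence is not the single association but
the *sign-coherent loop*: a closed 3- or 4-node cycle of cross-omic
associations whose directions are mutually consistent.

All models are ordinary least squares adjusted for the same a priori
covariates (race, sex, study site), with listwise deletion and no
imputation anywhere.

# Phase 1: genotype, microbiome and BMI

**Targeted mGWAS.** Genotype dimensionality is reduced by restricting to a
candidate-gene SNP panel; microbiome dimensionality by summarising each
age's genus count table into per-sample features: richness (number of
genera observed), Shannon entropy (nats), and the first $k$ robust
Aitchison principal components (MCPCs, default $k = 2$). Each feature at
each age is regressed on the minor allele count (MAC, 0/1/2) of each panel
SNP. The Bonferroni family size $m$ is the number of tests actually
performed, so the significant tier is $p < \alpha/m$ with $\alpha = 0.05$;
a suggestive tier at $p < 10^{-5}$ is reported separately, since borderline
microbiome-genotype signals are conventionally carried forward for
cross-omic corroboration.

**Robust Aitchison PCA.** Genus counts are transformed by the robust
centred log-ratio: for each sample, $\log$ of each nonzero count minus the
mean $\log$ over that sample's *nonzero* genera; zeros become missing
values, not small numbers. The transform is invariant to per-sample scaling
(sequencing depth) by construction. The principal components are then
fitted on observed cells only, by iterative SVD matrix completion: missing
cells start at zero, and the algorithm alternates a column-centred
rank-$k$ SVD with refilling the missing cells from the reconstruction until
the relative Frobenius change of the reconstruction over observed cells
falls below `tol`. On dense data this reduces exactly to classical PCA
(tested to $10^{-8}$), which is the testable contract of the method; each
component's loading vector is oriented so its largest-magnitude loading is
positive. We use `tol = 1e-4` with a 500-iteration cap: on simulated
cohorts the convergence is geometric but slow in its tail, and scores at
`1e-4` agree with scores at `1e-6` to well under one percent, which is far
below the sampling noise of any downstream regression. Non-convergence is
flagged on the result, never silently ignored.

**Persistent BMI scan.** Transient genotype-phenotype associations in
childhood are noisy; the scan therefore requires persistence: a SNP-BMI
edge is emitted only when the per-age regression of a BMI measure
(percentile and ordinal category are scanned separately) on MAC stays below
$p = 0.01$ for at least 5 *consecutive* ages, with a consistent slope sign
across the run (the sign requirement is toggleable). The emitted edge
carries the smallest-p age's slope and records the run's age range. Under
independent ages the null rate of this run statistic is about
$3 \times 10^{-10}$ per SNP ($\approx 3 \cdot 0.01^5$), which is what makes
the scan stringent.

**Differential abundance.** Genus-level differential abundance against the
SNPs of interest uses a pinned multivariable recipe: prevalence filter
(default 10%), total-sum scaling to proportions, per-genus half-minimum
pseudocount on zeros, $\log$ transform, OLS on MAC with covariates, and
Benjamini-Hochberg correction *across genera within each (age, SNP)
family*, reporting edges at $q < 0.05$. The recipe is implemented in the
package (not delegated to an external tool) so that its options are fixed
and auditable.

# Phase 2: metabolites

The metabolome (measured at one cross-sectional age, default 3 years) joins
in two steps. First, every metabolite's log abundance is regressed on each
BMI measure; metabolites at $p < 0.01$ for either measure define the
*pathways of interest*. Second, every metabolite annotated to those
pathways is tested against each partner variable: the BMI measures, the
MACs of the SNPs of interest, and the TSS-log abundances of the genera of
interest. A metabolite is selected when it has $p < 0.01$ partners in at
least two distinct omic types; all significant edges of selected
metabolites enter the network. The regression orientation is fixed — the
metabolite is always the response — because "pairwise association" does not
pin an orientation and reproducibility requires one; the orientation is
provenance metadata, the network treats edges as undirected.

Whether metabolite abundances should be log-transformed is a modelling
choice; we adopt the log (with a per-metabolite half-minimum pseudocount
for exact zeros) since relative abundances are strictly positive and
right-skewed.

# Phase 3: network and loops

All stage edges are merged into one undirected, typed, signed network: at
most one edge per node pair (the smallest-p record wins; the provenance of
all merged stages is concatenated), and only cross-omic edges are
admissible. A *loop* is a simple cycle of 3 or 4 nodes; it is *meaningful*
when the product of its edge signs is $+1$. This is the unique
formalisation of "the directions are coherent": orienting any latent
variable the other way flips exactly two incident edge signs, leaving the
product invariant, so a triangle with two negative links and one positive
link is coherent while a single negative link is not.

Type distinctness: 3-node loops must span three distinct omic types; 4-node
loops may repeat at most one type, and the network construction already
guarantees the repeated pair is non-adjacent (same-omic edges do not
exist). This admits, e.g., a SNP–amino-acid–genus–amino-acid cycle. A flag
removes the constraint entirely.

`loopNullCount()` calibrates an observed meaningful-loop count: topology is
held fixed and every edge sign is redrawn independently and uniformly from
$\{+1,-1\}$; for a single triangle 4 of the 8 assignments are coherent, and
the function's permutation distribution reproduces that exactly in
expectation.

# Predictive cross-validation

The variables of the meaningful loops are materialised at the
cross-sectional age (MAC for SNPs, TSS-log abundance for genera, log
abundance for metabolites, the BMI measure named by the node). Samples are
split 70/30 (deterministically under a seed); one OLS model is fitted per
loop variable with all other loop variables as predictors — except members
of the response's correlated-SNP group (single-linkage over $|r| \ge 0.9$
of MAC), which tag the same signal and are excluded — plus the covariates.
On the test samples with complete data across all loop variables, each
variable is min-max normalised to $[0,1]$ using training-set bounds and the
mean squared error is reported $\times 100$ as a percent. Min-max
normalisation is the one convention that makes percent MSE dimensionless
and comparable across omics (genotype responses are kept numeric and
predictions are not rounded). The mean-predictor baseline under the same
normalisation is reported alongside; for a variable uniform on $[0,1]$
that baseline is $100 \cdot \mathrm{Var} = 100/12 \approx 8.3$.

# The synthetic cohort generator

The generator is first-class, tested code: it defines the study conditions
under which every pipeline property is demonstrated. Defaults describe a
multi-site longitudinal birth cohort: 676 children; a 60-SNP candidate-gene
panel (12 genes) with one SNP pair in tight linkage disequilibrium
($r = 0.95$, realised by copying a SNP and resampling a fraction $1-r$ of
genotypes); 100 genera at ages 0.5/1/3/4 years; 200 metabolites in 40
pathways over the five canonical super-pathways at age 3; BMI percentiles
and categories at ages 2–8; covariates race (4 levels), sex (2), site (3)
sampled uniformly.

The mechanics, per omic:

* **Genotype**: per-SNP binomial(2, MAF) minor allele counts.
* **Microbiome**: per age, a log-linear composition
  $\eta_{sg} = b_g + u_s L_g + \text{planted} + \varepsilon_{sg}$ with
  log-normal genus baselines $b_g \sim N(0, 1.5^2)$, a one-dimensional
  latent *community gradient* $u_s \sim N(0,1)$ with loadings
  $L_g \sim N(0, 0.6^2)$, and cell noise $\varepsilon \sim N(0, 0.4^2)$;
  counts are Dirichlet-multinomial (concentration 300) at Poisson depth
  (mean 10,000). The gradient is what the leading MCPC estimates, so a
  planted effect on it (reserved target id `".axis"`) is a planted effect
  on MCPC1. Compositionality is preserved throughout, so the rclr/TSS
  stages are exercised on genuinely compositional data with genuine zeros.
* **Metabolome**: log-normal, split into an intrinsic latent part
  (SD 0.7) — the scale on which planted chains act — plus measurement
  noise (SD 0.7).
* **BMI**: a latent per-sample trajectory, AR(1) across ages
  (autocorrelation 0.85 by default, a realistic tracking strength for
  childhood anthropometrics), mapped through the normal CDF to percentiles;
  categories use the standard pediatric cutpoints at the 5th/85th/95th
  percentiles (ordinal 0–3), since no other convention is established for
  this age range.

**Planted effects** are directed linear influences on the latent scale,
injected along the fixed generation order snp < genus < metabolite < bmi
(an effect stated against that order is canonicalised by swapping
endpoints — only the sign of the induced association is observable). For
SNP sources the raw MAC is used, so effect sizes read as SD per allele; for
other sources the standardised latent. `plantCoherentLoop()` realises a
requested 3- or 4-cycle as a chain plus its closing edge, which is possible
exactly when the sign product is $+1$ — incoherent sign patterns are
rejected, mirroring the detection rule.

**Missingness** is applied independently per omic (and per age), completely
at random: microbiome/metabolome samples are dropped from their tables,
genotype rows and BMI cells become `NA` — absence, never zeros. The default
fractions (genotype 2%, microbiome 25% per age, metabolome 25%, BMI 20%
per age) leave roughly 40–50% of samples with complete multi-omic data at
age 3, which is the regime the complete-case cross-validation is meant to
survive.

**Determinism.** All randomness derives from one global seed through named
substreams (one per stage and age), so identical configurations reproduce
cohorts bit for bit and adding a stage never perturbs another's draws.

What the generator does *not* emulate: population structure and kinship,
realistic taxon inventories or allele frequencies, depth-dependent
extraction biases, non-random (informative) missingness, and nonlinear or
interaction effects. Passing tests therefore demonstrate the pipeline's
statistical mechanics — calibration, recovery, coherence algebra,
reproducibility — not robustness to those real-data complications.

# Numerical and design choices

* **OLS engine**: QR least squares with explicit standard errors and
  two-sided t-tests, written in the package because the stages need a fast,
  auditable primitive (hundreds of thousands of fits in the calibration
  suites); it is cross-checked against `stats::lm` and the closed-form
  normal equations to $10^{-10}$ in the tests. Collinear covariate columns
  are dropped with a warning; a constant exposure or fewer than 10 complete
  rows yields a flagged degenerate fit that stages skip and log.
* **BH adjustment** delegates to `stats::p.adjust(method = "BH")`.
* **Matrix completion**: `tol = 1e-4`, `maxIter = 500` (see above);
  `k` up to `min(dim) - 1`, errors beyond.
* **Persistence runs**: an age with a degenerate fit breaks a run; ages are
  scanned in sorted order; multiple qualifying runs each emit an edge with
  their own age range.
* **Bonferroni family size** is computed from tests performed, not tests
  planned, so skipped ages or degenerate fits shrink $m$ honestly.
* **Edge ordering** everywhere is ascending p then node ids, making all
  written artifacts diffable; numeric TSV output carries 15 significant
  digits so round trips preserve 12.
* **BMI autocorrelation knob**: the run-statistic null-rate experiments use
  `bmiAutocorrelation = 0` because the nominal $3\times10^{-10}$ rate
  presumes independent ages; under the default 0.85 the run statistic's
  null rate is genuinely higher (neighbouring ages share sampling noise),
  which is a property of persistence scans on tracking phenotypes, not of
  this implementation.

# Problem sizes used by the test suite

The calibration and recovery experiments in the package's tests run at
sizes chosen to make Monte-Carlo bounds tight while keeping the suite
comfortably interactive: null calibration on one effect-free cohort of
n = 500 with 100 SNPs, 100 genera and 200 metabolites (about 10,000 raw
p-values across the five stages, each stage checked for KS-uniformity);
the persistent-run null rate over 200 replicate genotype+phenotype cohorts
(100 SNPs each, independent BMI ages); planted-loop recovery over 100
replicate cohorts of n = 600 (20-SNP panel, 30 genera, 60 metabolites,
single microbiome age, edge effects 0.5 SD), requiring the planted triangle
among the meaningful loops in at least 80% of replicates with all recovered
signs matching the planted ones.

# Limitations

Only pairwise linear, cross-sectional-per-age associations are modelled: no
mixed models or longitudinal random effects, no kinship correction, no
mediation or causal direction, no cycles longer than four nodes, and
species/strain resolution is out of scope at genus level. The loop-count
permutation null randomises signs only, conditioning on topology; it does
not calibrate the edge-detection stages themselves (their calibration is
tested separately under the generator's null).
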