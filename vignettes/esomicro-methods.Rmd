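---
title: "Models and methods in esomicro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in esomicro}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esomicro)
```

`esomicro` analyses amplicon feature tables sampled across esophageal
disease stages: healthy controls (HC), squamous intraepithelial neoplasia
(ESIN) and squamous cell carcinoma (ESCC), each lesion paired with
adjacent tissue (ESINA, ESCCA). This vignette explains the statistical
machinery, the tunable parameters and their defaults, the synthetic-data
generator used for validation, and the numerical and design decisions a
maintainer should know about. No empirical claims are made here beyond
what the package's tests and acceptance script themselves compute.

## Feature tables and filtering

A `feature_table` is a non-negative taxa-by-samples matrix with unique
identifiers, either read counts or per-sample proportions (columns summing
to one). Filtering follows conventional amplicon practice: a feature is
kept when it has at least `min_total_reads` (default 10) summed reads and
appears (≥ 1 read — the package's fixed detection threshold, since lower
is unobservable and higher is arbitrary) in at least `min_samples`
(default 2) samples. Sample retention uses per-kingdom sequencing-depth
floors, defaulting to 14,000 reads for bacterial 16S tables and 19,500
for fungal ITS tables, applied inclusively at the boundary. The depth
filter deliberately leaves all-zero taxon rows in place: dropping samples
and pruning taxa are separate, individually auditable steps.

When collapsing to a taxonomic rank, rows sharing the lineage prefix are
summed and taxa unnamed at that rank are pooled under
`unclassified_<deepest named ancestor>`, which keeps labels unique and
per-sample totals exactly conserved. Feature tables default to taxa-rows
orientation on disk; reading a samples-rows file requires saying so,
because silently guessing the orientation of an ambiguous TSV is a
classic source of wrong results.

The oral-microbiome fraction of a bacterial sample is the abundance share
of taxa flagged as oral-cavity residents. Whether the group summary
averages per-sample fractions (default) or pools reads within a group is
exposed as a flag: the two differ when depths vary strongly, and neither
convention is canonical.

## Diversity

Alpha diversity uses Hill numbers,
$^qD = (\sum_i p_i^q)^{1/(1-q)}$, the effective number of species at
order $q$: richness at $q = 0$, exponential Shannon entropy at $q = 1$,
inverse Simpson concentration at $q = 2$. The $q = 1$ case is computed by
the exact entropy limit rather than by plugging in $q = 1 - \varepsilon$;
zeros are excluded from all sums. Hill profiles are non-increasing in $q$,
a property the tests exercise on random compositions. Group contrasts use
two-sided Wilcoxon rank-sum tests with Benjamini–Hochberg adjustment
across the family of group pairs.

Beta diversity is Bray–Curtis dissimilarity on Hellinger-transformed data
(square root of relative abundance, so each sample has unit Euclidean
norm), ordinated by classical PCoA; negative eigenvalues of non-Euclidean
inputs are reported, never discarded. PERMANOVA and ANOSIM run through
`vegan` (`adonis2`, `anosim`), whose permutation p-values use the add-one
estimator $(1 + \#\{F^\ast \ge F\})/(1 + n_{perm})$ — the same floor of
$1/(n_{perm}+1)$ the package uses everywhere, which avoids reporting
p = 0 from a finite permutation set. Pairwise beta contrasts are computed
on the sub-distance-matrix of each group pair (a Bray–Curtis distance
between two samples does not depend on other samples, so nothing needs
recomputing) and BH-adjusted. Both the PERMANOVA R² and the ANOSIM R
statistic are available and the output labels which was run, since
published tables sometimes head an R² column with an "ANOSIM" caption and
the reader cannot tell which was meant; the package default is
`permanova_R2`.

## Spatial heterogeneity (Type-I Taylor power law)

Each sample contributes a point: $M$ the mean and $V$ the variance
(sample variance, $n-1$ denominator — a fixed convention recorded on the
fit) of its per-taxon abundances. Ordinary least squares of $\ln V$ on
$\ln M$ across a group's samples fits $V = a M^b$; the slope $b$ measures
community aggregation, with higher values indicating greater spatial
heterogeneity. Two conventions are unstated in parts of the literature
and therefore explicit flags here: zero counts are excluded from the
per-sample summary by default (the community is what is present;
including zeros shifts $b$ systematically and is available as
`include_zeros = TRUE`), and counts rather than proportions are the
default input (a relative-abundance mode exists). Degenerate points
($M = 0$ or $V = 0$) are excluded with a warning; a fit needs at least
three points and a non-constant $\ln M$.

Groups are compared by a permutation test: samples pooled, group labels
reassigned at the original sizes, both groups refitted, and the add-one
proportion of permuted $|\Delta b|$ reaching the observed one is the
p-value (likewise for $\ln a$). When fewer distinct reassignments than
`n_perm` exist the test enumerates them exactly. Pairwise contrast
matrices can be summarised by a compact letter display: groups share a
letter exactly when not significantly different, so a group differing
from all others gets a unique letter.

A power note: the $|\Delta b|$ permutation null widens when single
samples carry much of the log–log fit's leverage, which happens for small
taxon panels with heavy-tailed abundance and strong dispersion. The
package's power validation therefore runs at thirty samples per group
with a 500-taxon panel and low library-size noise, where per-sample
$(M, V)$ points are well determined; at the small CI-profile panel sizes
the same contrast has visibly lower power, which is a property of the
statistic, not a bug.

## Shared species and the A2 null

The observed shared count between two groups is the number of taxa with
at least one read in at least one sample of each. The null model ("A2")
reshuffles sample-to-group labels at fixed group sizes and recomputes the
count; the two-sided p-value is the add-one proportion of permuted counts
at least as far from the null mean as the observed one. The published
description of the read-permutation stage is one ambiguous sentence, so
the package provides both variants under explicit names: `labels`
(labels only, the default) and `reads` (labels, then each pseudo-group
sample redrawn from the pooled pseudo-group taxon profile by multinomial
resampling at its own depth). A caution for users and test writers: in a
dense regime where every taxon occurs in every sample the shared count is
constant and the test degenerates to p = 1; the statistic is informative
only when presence actually varies, which for calibration fixtures means
sparse, heavy-tailed tables.

## Biomarker screening and ROC

The effect-size screen follows the LEfSe recipe with the package's own
estimator (numeric parity with the original implementation is not
claimed; validation is recovery of planted truths). Stage one is a
Kruskal–Wallis test per taxon — reduced to the exact two-sided rank-sum
test when only two groups are present — plus, for multi-group runs, a
one-against-all consistency check: the candidate enriched group must rank
above every other group pairwise. One-against-all was chosen over
all-against-all because the study design it serves contrasts one stage
against the rest; the choice is recorded in the output. Stage two scales
abundances to one million per sample and, over 30 bootstrap rounds
drawing two thirds of each class, fits a two-class linear discriminant of
the enriched group against the rest with the pooled covariance shrunk 10%
toward its diagonal (the standard fallback for near-singular covariances
at these sample sizes). The per-taxon effect is the bootstrap mean of
$\tfrac12(|\Delta \text{raw means}| + |\Delta \text{projected means}|)$
and the reported score is $\log_{10}(1 + \text{effect})$, flagged at the
conventional threshold of 3.0.

AUC uses the Mann–Whitney identity (ties count one half), so it is exact,
fast and invariant under monotone score transforms. Two markers are
combined by a deterministic ridge-penalised logistic discriminant
(penalty $10^{-6}$ on standardized features, IRLS to $10^{-8}$). The tiny
ridge keeps the fit defined under perfect separation — where unpenalised
maximum likelihood diverges — while preserving the property that a
perfectly separating marker yields a combined AUC of 1; separation is
flagged in the result. Because an apparent (resubstitution) AUC of a
fitted combination is optimistic at small n, the result also carries a
stratified five-fold cross-validated AUC (per-fold AUCs averaged;
deterministic round-robin folds), which is the value to quote for
honesty about discrimination. A plain "sum of standardized ranks" rule is
available for combining markers without any fitting, and a multi-species
marker is simply the per-sample sum of relative abundances of the list.

## Co-occurrence networks

SparCC estimates correlations from compositional counts: per iteration,
fractions are drawn by Dirichlet smoothing (pseudocount 1; a
deterministic posterior-mean mode exists for oracle tests), log-ratio
variances $t_{ij} = \mathrm{Var}\,\ln(x_i/x_j)$ are formed, and basis
variances $\omega$ solve the sparsity-approximated system
$M\omega = t_{\cdot}$ with $M = J + (D-2)I$; correlations follow as
$\rho_{ij} = (\omega_i + \omega_j - t_{ij}) / (2\sqrt{\omega_i\omega_j})$,
clipped to $[-1, 1]$. Strongly correlated pairs (|ρ| above the exclusion
threshold, default 0.1 with at most $D-3$ exclusions per taxon — the
reference implementation's values) are excluded one at a time and the
system re-solved, so a few coupled pairs do not contaminate the sparse
basis. The final estimate is the entrywise median over iterations. At
$D = 3$ the basis has the closed form
$\omega_i = (t_{ij} + t_{ik} - t_{jk})/2$, which the tests use as an
exact oracle.

Edge significance permutes each taxon's sample vector independently
(destroying dependence, keeping margins) and re-estimates; the two-sided
p is the add-one exceedance fraction and q-values are BH across the upper
triangle. Bootstrap resampling of samples quantifies estimate stability
as a per-edge SD but does not enter the p-value. A practical FDR note:
with a permutation floor of $1/(n_{perm}+1)$ and $m = D(D-1)/2$ edges, no
edge can reach $q < \alpha$ unless $n_{perm} \gtrsim m/(\alpha\,k)$ for
$k$ true edges, so small panels need generous permutation counts
(study-scale practice is 1,000 permutations and 1,000 bootstraps).

Networks keep edges with $|\rho| > 0.4$ (strict) and $q < 0.05$; signs
are recorded and isolated nodes dropped; an empty network is a warning,
not an error, because sparse groups legitimately produce one. Dense cores
are found MCODE-style — vertices weighted by the highest k-core of their
closed neighbourhood times that core's density, then greedy expansion
from the best unvisited seed accepting neighbours within
`node_score_cutoff` (0.2) of the seed weight, clusters required to
contain a 2-core; all defaults are the familiar plug-in's, since no
better-informed set exists. Members are labelled `core`; non-members
adjacent to a core node are `peripheral`. The backbone is the maximum
spanning forest on $|\rho|$ per component (flag count = nodes −
components). The functional-group procedure takes three networks over a
shared namespace: pairs interacting in both the HC and ESIN networks
(edge sign ignored by default — a pair whose correlation flips sign
between stages still interacts; a sign-strict mode exists), endpoint
species collected, and those present in the ESCC network retained. Its
abundance marker is the per-sample summed relative abundance of the
retained species.

## Clinical statistics

Fisher's exact test for r×c tables is the Freeman–Halton two-sided
convention: the p-value sums the probabilities of all tables with the
observed margins whose probability does not exceed the observed table's
(implemented via `stats::fisher.test`; the test suite checks it against a
brute-force margin enumeration). One-way ANOVA accepts raw vectors or
per-group (n, mean, sd) summaries; the summary path uses
$SS_B = \sum n_i(\bar x_i - \bar x)^2$ and
$SS_W = \sum (n_i - 1) s_i^2$, an algebraic identity with the raw
computation, which is what lets a published table's test be reproduced
from its printed cells. The bundled `reference_cohort()` carries the
clinical profile of the 35-participant case-control cohort the package's
defaults emulate (13 HC, 10 ESIN, 12 ESCC); reproducing its tests from
the printed summaries agrees with full-precision computation to the
printed number of decimals, which is all rounded inputs can promise.

## The synthetic cohort generator

The generator exists so that every downstream stage has planted ground
truth. Counts for each kingdom arise from a latent log-normal model: a
per-taxon baseline $\beta_i \sim N(\mu_0, \sigma_0^2)$ (defaults 0 and
2 — a heavy-tailed community with a few dominants, as amplicon data
show); planted differential taxa add $\log 2 \cdot \text{log2fc}$ in
their groups; each sample adds a Gaussian perturbation with group
dispersion $\sigma_g$, correlated inside configured taxon blocks
(equicorrelated Cholesky factors; block PSD is validated) and truncated
at ±2.5 sd so no single draw hands one sample the whole heterogeneity
fit's leverage. Planted taxa (differential and block members) are pinned
to an upper-quantile baseline: truth buried below the detection floor
could never anchor a recovery test. Sequencing depth is proportional to
the sample's total latent biomass times log-normal noise (sd 0.3),
bounded below at 500 reads, and counts are multinomial at that depth.

Coupling depth to biomass is the deliberate mechanism behind the Taylor
exponent: samples whose dominant taxa blow up have both more biomass
(hence reads and mean $M$) and disproportionately more variance $V$, so
the fitted slope $b$ exceeds 2 and rises with $\sigma_g$ — verified as a
monotone trend over a dispersion grid in the tests. Group defaults give
the early-lesion group the largest dispersion (1.3) and the carcinoma
group the smallest (0.5), mirroring the stage pattern the package is
designed to interrogate; the response saturates near $\sigma_g \approx
1.2$–1.6, so dispersion grids for calibration should stay below that.

Clinical covariates hit their configured per-group yes-counts *exactly*
(which samples carry the "yes" is randomised by seed, the margins are
not), with defaults rescaled from the reference cohort's proportions to
whatever group sizes are configured; ages are normal draws from the
configured per-group mean/sd. Two profiles exist: `ci` (200 bacterial and
60 fungal taxa, five groups of ten — sized so the full suite runs in
minutes) and `full` (2,314 and 573 taxa at the reference cohort's group
sizes). All randomness flows from one integer seed through fixed
per-stage offsets, so any stage can be reproduced in isolation.

What the generator does **not** emulate: taxonomic misclassification,
chimeras, batch effects, phylogenetic structure, zero-inflation beyond
what multinomial sampling of a heavy-tailed composition produces, and any
real covariance between clinical covariates and microbial composition.
Passing recovery tests on these synthetics therefore demonstrates that
the estimators do what they claim under their own model assumptions — not
that real esophageal data satisfy those assumptions.

## Numerical conventions and degenerate inputs

All permutation p-values use the add-one estimator and never return 0.
All stochastic functions take an explicit seed; the pipeline derives
per-stage seeds from one master seed by fixed offsets, and identical
configurations reproduce outputs byte for byte. Relative tables must have
columns summing to 1 within $10^{-9}$; rank collapsing conserves totals
to the same tolerance. Degenerate cases are handled explicitly rather
than silently: all-zero distance matrices report R² = 0 with a warning,
empty networks warn, a zero-margin contingency table returns p = 1 with a
warning, constant taxa get p = 1 in the screen, and SparCC zeroes the
correlations of any taxon whose basis variance turns non-positive.

## Problem sizes used in validation

The shipped tests validate at deliberately modest scales: the CI
synthetic profile (groups of ten, 200 + 60 taxa), calibration suites of
150–500 replicates on 10–200-taxon fixtures, SparCC panels of 8–25 taxa
at 50–200 samples, and permutation counts of 99–1,500 chosen so each
check's resolution matches what it asserts (the FDR note above sets the
floor for edge tests). These sizes are the package's own validation
design; study-scale analyses simply raise the same knobs
(`n_perm = 999`–1,000, SparCC with 100 iterations and 1,000
permutations/bootstraps, the `full` synthetic profile).

## Known limitations

- SparCC inherits its sparsity assumption: when many taxa are mutually
  correlated the basis approximation biases estimates, and the exclusion
  heuristic only mitigates a few strong pairs.
- The LDA effect size is the package's own faithful-in-spirit estimator;
  scores are comparable within a run, not against other LEfSe
  implementations.
- The TPLE contrast has limited power at small taxon panels (see the
  power note above); users with few taxa should expect wide permutation
  nulls rather than treat non-significance as evidence of homogeneity.
- Clinical-table reproduction from printed summaries is limited by the
  printing precision of the inputs.
- The pipeline's default network stage restricts each group's SparCC run
  to the 40 most prevalent taxa to keep the basis system well posed at
  cohort-scale sample counts; genuinely rare-taxon interactions are out
  of its reach by construction.
- At cohort-scale group sizes (around ten samples) the SparCC permutation
  null is as wide as the estimates themselves, and after FDR correction
  no edge passes q < 0.05 — the demo pipeline's per-group networks are
  therefore expected to be empty, and that emptiness is the statistically
  honest answer at that n. Edge recovery is demonstrated at n = 200,
  where a planted latent correlation of 0.8 passes both filters (see the
  acceptance script).
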