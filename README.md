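# esomicro

Stage-resolved analytics for the esophageal microbiome.

`esomicro` implements the analysis stack used to characterise resident
bacterial (16S rRNA) and fungal (ITS) communities across the stages of
esophageal squamous cell carcinoma development — healthy controls (HC),
squamous intraepithelial neoplasia (ESIN) and carcinoma (ESCC), each lesion
with its adjacent-tissue counterpart (ESINA, ESCCA). It is aimed at
microbiome researchers who have amplicon feature tables (ASV counts),
taxonomy assignments and clinical metadata in hand and want the downstream
statistics as tested, seeded, reusable functions rather than a one-off
script pile.

## What it computes

- **Tables**: TSV feature-table I/O with validation; feature filtering
  (≥ 10 reads in ≥ 2 samples), per-kingdom sequencing-depth filters
  (defaults 14,000 for 16S, 19,500 for ITS), relative-abundance and
  Hellinger transforms, rank collapsing, oral-microbiome fractions.
- **Alpha diversity**: Hill numbers
  `qD = (Σ pᵢ^q)^(1/(1−q))` — richness at q = 0, exponential Shannon at
  q = 1, inverse Simpson at q = 2 — with pairwise Wilcoxon group contrasts.
- **Beta diversity**: Bray–Curtis on Hellinger-transformed data, PCoA,
  PERMANOVA and ANOSIM (omnibus and BH-adjusted pairwise contrasts).
- **Spatial heterogeneity**: Type-I Taylor power-law extension. Per sample,
  the mean M and variance V of taxon abundances give one point; ordinary
  least squares of ln V on ln M across a group's samples yields
  `V = a M^b`, and the slope *b* indexes community aggregation — higher
  *b*, more heterogeneous. Groups are compared by permutation tests on
  |Δb|, summarised with compact letter displays.
- **Shared species**: observed shared-ASV counts between groups against a
  permutation null (the A2 scheme: labels reshuffled at fixed group sizes,
  optionally with read reallocation inside pseudo-groups).
- **Biomarkers**: LEfSe-style screen — Kruskal–Wallis (exact rank-sum for
  two groups), one-against-all consistency, then bootstrapped two-class
  LDA effect sizes on per-million scaled abundances; taxa with
  LDA score ≥ 3.0 flagged.
- **Networks**: SparCC correlations for compositional counts (log-ratio
  variances, sparsity-approximated basis system, iterative strong-pair
  exclusion, median over Dirichlet resamples), permutation p-values with
  BH correction, edges kept at |ρ| > 0.4 and q < 0.05, MCODE-style dense
  cores with core/peripheral roles, maximum-spanning-forest backbones, and
  the cross-network functional-group rule (species interacting in both the
  HC and ESIN networks and present in the ESCC network).
- **Markers & ROC**: AUC by the Mann–Whitney identity, two-marker logistic
  combination with cross-validated AUC.
- **Clinical tables**: Freeman–Halton Fisher exact tests for r×c
  contingency rows, one-way ANOVA from raw data or printed
  mean (sd) summaries, and a cohort-description table renderer.
- **Synthetic cohorts**: a seeded generator emitting five-group bacterial
  and fungal tables with planted differential taxa, latent correlation
  blocks, group-specific dispersion (which controls the Taylor exponent)
  and clinical covariates with exact contingency margins — so the entire
  pipeline is testable without any sequencing data.

## Worked example

```r
library(esomicro)

cfg <- synthetic_config(seed = 42)      # 5 groups x 10 samples, 200 + 60 taxa
dat <- generate_tables(cfg)
dat$bacteria
#> <feature_table> 200 taxa x 50 samples (counts)

g <- group_vector(dat$metadata)
d <- bray_curtis(hellinger(dat$bacteria))
pm <- permanova(d, g[sample_ids(dat$bacteria)], n_perm = 999, seed = 42)
sprintf("PERMANOVA: R2 = %.3f, p = %.3f", pm$R2, pm$p)
#> "PERMANOVA: R2 = 0.144, p = 0.001"

fits <- tple_by_group(dat$bacteria, dat$metadata)
fits$ESIN
#> Type-I TPLE fit [ESIN]: b = 2.887, ln(a) = -2.019, R = 0.989, p = 6.52e-08, n = 10
fits$HC
#> Type-I TPLE fit [HC]: b = 1.980, ln(a) = 2.065, R = 0.923, p = 0.000139, n = 10
```

The PERMANOVA says the five groups occupy distinct regions of
Bray–Curtis space (R² is the fraction of squared dissimilarity explained
by group membership; p is an add-one permutation p-value). The Taylor
slopes recover the planted heterogeneity ordering: the ESIN group was
generated with the largest per-sample dispersion and fits the steepest
mean–variance scaling (b = 2.89 vs 1.98 in controls).

Clinical rows reproduce their published-style tests from printed counts
alone:

```r
ref <- reference_cohort()
yes <- unlist(ref$categorical[ref$categorical$covariate == "family_history_cancer",
                              c("HC", "ESIN", "ESCC")])
fisher_exact_rc(rbind(yes = yes, no = ref$n - yes))$p
#> 0.0183 (prints as 0.018)
```

The full pipeline (filter → diversity → heterogeneity → shared species →
biomarkers → networks → clinical) runs from one config:

```r
cfg <- pipeline_config(synthetic = synthetic_config(seed = 1),
                       output_dir = "run1", seed = 1,
                       depth_thresholds = c(bacteria = 1000, fungi = 1000))
run_pipeline(cfg)   # writes per-stage TSVs plus manifest.json
```

A thin command-line wrapper lives at `inst/scripts/esomicro-pipeline.R`.

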