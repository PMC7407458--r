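---
title: "Models and design choices in polynet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in polynet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`polynet` compares weighted gene coexpression networks built from
homoeolog-resolved RNA-seq counts in an allopolyploid: a *joint* network over
summed homoeolog pairs, a *homoeologous* network over the individual copies,
and condition-specific (wild vs. domesticated) networks, plus the
differential-expression, module-preservation, homoeolog-bias,
differential-correlation and enrichment layers needed to contrast them. This
vignette records the statistical models, the parameters that matter, and the
design decisions that were genuinely open, so that a user can judge what the
package's validation does and does not establish.

## Counts, filters and normalization

The raw substrate is an integer genes × samples count matrix whose gene ids
carry `_A`/`_D` suffixes, plus a sample table (accession, group ∈ {wild,
domesticated}, stage in days post-anthesis). The motivating design is 2
groups × 4 stages × 3 accessions = 24 libraries.

Two expression filters are used, matching their different downstream roles:

* **joint**: a pair is expressed if its mean raw summed count over all
  samples is strictly greater than 1. The boundary is read literally, so a
  gene averaging exactly 1.0 is dropped.
* **homoeolog**: a pair is kept only when *both* copies have a count of at
  least 1 in at least `ceiling(n/2)` of the n libraries. The per-pair (rather
  than per-gene) reading is deliberate: the A-vs-D bias contrast is only
  well defined when both members are observed, and the pairwise rule keeps
  the tested universe identical for both copies.

Normalization is median-of-ratios: per sample, the median over
all-positive-count genes of `count / geometric mean across samples`, followed
by `log2(count/sf + 1)`. This is a transparent stand-in for regularized-log
transforms whose empirical-Bayes shrinkage we deliberately do not
re-implement: the network layer only needs a monotone variance-damping
log-scale transform, and every downstream claim is validated on synthetic
recovery rather than on bit-equivalence with any particular transform. The
median is taken on the ratio scale (not the log scale), which matters only
for even gene counts.

## Negative-binomial differential expression

Each gene is modelled as `y_s ~ NB(mu_s, phi)` with
`log mu_s = log sf_s + x_s' beta` (treatment coding; reference levels wild,
the earliest stage, and subgenome A, so coefficient signs are unambiguous).
Fitting is standard IRLS (`stats::glm` with the fixed-theta negative
binomial family), with per-gene convergence flags; non-convergent genes get
`NA` P-values and are excluded from the Benjamini-Hochberg denominator.

The dispersion `phi` (variance `mu + phi mu^2`) is a **Pearson-moment
plug-in**: per gene, solve

    sum_s (y_s - mu_s)^2 / (mu_s + phi mu_s^2) = n - p

where `mu_s` are the design-cell means of normalized counts and `p` is the
number of cells. This is a method-of-moments estimator with no
empirical-Bayes shrinkage — the estimator stays self-contained and
transparent — floored at 1e-8 and shared between the full and reduced fits
of a likelihood-ratio test.

**Small-sample reference distributions.** With only three replicates per
design cell, the plug-in dispersion is noisy, and referring the LRT to its
asymptotic chi-square is anti-conservative (genes whose dispersion happens
to be underestimated produce inflated statistics). We therefore refer
`LRT/df1` to `F(df1, n - p_full)` by default and Wald statistics to
`t(n - p)` — the quasi-likelihood convention for plug-in dispersions. The
asymptotic chi-square/normal references remain available via the
`reference` argument. The package's own calibration checks (2,000-gene null
simulations at the study design) are run by the test suite and the
acceptance script, not quoted here.

Homoeolog bias doubles the count matrix (each pair becomes one row over
2n columns, `subgenome` added to the metadata), fits
`~ subgenome + group + stage`, and classifies each pair A-biased, D-biased
or unbiased from the A-vs-D Wald contrast at BH-adjusted P < 0.05.

## Network construction

Pearson correlations between all gene pairs (zero-variance genes are an
error, not a silent drop), unsigned soft-threshold adjacency
`a_ij = |r_ij|^beta` with `beta = 12` — the conventional default, with the
scale-free fit index (signed R² of the binned log-log degree regression)
exposed so users can verify a fit above 0.8 or pick the smallest adequate
power — and the topological overlap matrix

    TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij),
    l_ij = sum_{u != i,j} a_iu a_uj .

Modules come from average-linkage clustering of `1 - TOM` in three steps:

1. **static cut** at `cut_height_frac` (default 0.99) of the maximum merge
   height, with clusters below `min_module_size` (default 30) unassigned
   (label 0). This replaces the full dynamic tree-cut heuristic; on planted
   data it reproduces the modular outcome, and it is deterministic.
2. **eigengene merging**: modules whose eigengene dissimilarity `1 - cor` is
   below `merge_height` (default 0.15) are merged iteratively, closest pair
   first.
3. **kME membership curation**: every gene is assigned to the module whose
   eigengene it correlates with most strongly *in magnitude*, provided
   `|kME| > 0.7`, and is otherwise unassigned; the minimum-size filter is
   re-applied. This step exists because average linkage chains weakly
   attached genes onto a cluster well below the static cut; requiring
   individual membership strength prunes them (the analogue of WGCNA's PAM
   stage / `minKMEtoStay`). The magnitude is what counts because the
   network is unsigned: a member anti-correlated with the eigengene is
   still a member.

Module eigengenes are the unit-norm first right singular vector of the
module's gene-standardized expression, oriented so the mean correlation
with member genes is positive; kME is the gene × eigengene correlation
matrix. Labels are renumbered by decreasing size, ties broken by original
label, so output is deterministic; permuting gene order permutes labels
identically. Module–condition association uses `ME ~ group + stage` ANOVA
F-tests per factor.

## Module preservation

For a reference labelling evaluated in test data, four per-module
statistics: `meanCor` (mean off-diagonal intramodule correlation),
`meanAdj` (mean intramodule adjacency), `cor_kIM` (correlation of members'
intramodular connectivity between reference and test) and `cor_cor`
(correlation of the vectorized intramodule correlation matrices). A
permutation null shuffles the label vector over all genes (module sizes
preserved; label 0 participates in the pool but is never a tested module);
`Z = (obs - null mean)/null sd`, `Zdensity` and `Zconnectivity` are the
medians of their two Zs, and `Zsummary` is their mean, with the published
interpretation thresholds (> 10 strong, 2–10 moderate — both boundaries
assigned to moderate — and < 2 none). `medianRank` is the median across the
four statistics of the module's rank (1 = most preserved, average ranks on
ties). Defaults: `n_perm = 100`, seed-deterministic.

Using four statistics rather than the full published set of ~7 is a
deliberate reduction: these four are computable from expression alone and
are the drivers of the density/connectivity medians.

**Known limitation.** On small datasets the connectivity statistics are
conservative: a permuted null "module" mixes members of different true
modules with background, and that membership contrast is itself
reproducible between reference and test data, so null `cor_kIM`/`cor_cor`
run high. Density statistics are unaffected and dominate on planted
fixtures of a few hundred genes; at realistic network sizes (tens of
thousands of genes, dozens of modules) the null is far less structured.

## Differential correlation

For each unordered gene pair, Fisher's z-test on the two within-group
correlations:

    stat = (atanh r1 - atanh r2) / sqrt(1/(n1-3) + 1/(n2-3)),

with `n` the number of samples in each group (12 in the emulated design —
the number of libraries, not accessions, since those are the units entering
the correlation). Correlations of exactly ±1 are clipped to `1 - 1e-12` and
flagged. Significance is assessed by local FDR (the default, matching
published practice) or BH. The local FDR uses the theoretical N(0,1) null:
`lfdr(z) = pi0 f0(z)/f(z)` with `f` a kernel density estimate, `pi0`
estimated from the count of z-scores in `[-1, 1]` against the null
expectation, isotonic monotonisation in `|z|`, and clipping to `[0, 1]`;
below 100 tests the density is unstable and the method falls back to BH
with a warning.

A gene with `k` significant pairs among its `n` tested pairs is scored
against `Binomial(n, p0)` with `p0` the global significant-pair fraction
(upper tail, BH across genes). `n` is the gene's full partner count — all
pairs are tested once. Note the inherent symmetry: a rewired gene's
unflipped partners also accumulate significant edges, so DC-gene lists
contain both sides of a rewiring event.

## Enrichment

kME-ranked GSEA uses the classic weighted running sum (hit increments
`|kME| / sum of member |kME|`, miss decrements `1/(N - |S|)`, ES = maximum
deviation; ties in the ranking broken by gene id). The null is `n_perm`
random same-size gene sets — the only null available for pre-ranked input —
with `NES = ES / mean(|null ES| of the same sign)` and a one-sided
permutation P with a +1 pseudocount; FDR is BH over the tested sets.
Hypergeometric term enrichment is the classic one-sided upper-tail test on
the flat term → gene annotation (no ontology-graph decorrelation à la
topGO's elim/weight — a documented reduction), BH-corrected.

## The synthetic-data generator

The generator is the package's evidence base, so its design is worth
stating precisely. For `n_pairs` homoeolog pairs over the 2 × 4 × 3 design:

* **Module latents.** Each planted module has a 4-point developmental shape
  (N(0, 1.2) per stage, log2 units) shared by both groups, plus a per-group
  offset N(0, 0.6). Offsets move expression level without
  touching within-group correlations, so domestication DE exists while
  `rewire_fraction = 0` remains a true differential-correlation null.
  Profiles are drawn sequentially with rejection until each is distinct
  from the accepted ones (pairwise |cor| ≤ 0.4 — an unsigned network cannot
  separate strongly correlated or anti-correlated profiles) and non-flat
  (profile sd ≥ 0.9 log2 units).
* **Loadings.** One loading per pair, magnitude Uniform(0.6, 1), with a
  random sign. Sign-mixing makes planted modules bipolar (as unsigned-network
  modules genuinely are) and keeps the per-sample count distribution
  balanced, so median-of-ratios size factors are not distorted by module
  activity — with 60% of genes in four coherently moving modules, an
  all-positive design measurably corrupts the size factors and the shared
  error component becomes a spurious correlation among weak genes.
* **Background pairs** get weak independent developmental shapes (sd 0.2)
  and no group offset. Both choices are forced by the low-dimensional
  condition space: with only four stages, high-amplitude "independent"
  background profiles correlate by chance and would be clustered, and a
  shared domestication step across many background genes would itself
  constitute a module.
* **Bias**: `bias_fraction` of pairs (half A, half D) shift the two copies
  by ±`bias_lfc`/2 on the log2 scale, so the pair sum is bias-invariant and
  bias detection is decoupled from module detection.
* **Divergence and rewiring**: exactly `floor(split_fraction × n_pairs)`
  pairs have the D copy reassigned to a different module; rewired genes
  (drawn per module, `floor(rewire_fraction × member count)` each, because
  flipping a background gene changes no correlation) have their loading
  sign flipped in domesticated samples — a maximal, countable correlation
  change. Their domesticated-truth label is recorded as 0: the flipped copy
  is no longer a positively co-regulated member, though an unsigned
  clustering may still attach it.
* **Counts**: `mu = 2^(base + loading·latent + bias/2 + noise) × lib`,
  `base ~ Uniform(5, 9)` log2 units (≈ 32–512 reads), library factors
  Uniform(0.7, 1.3), latent-scale noise sd 0.1, and `y ~ NB(mu, phi)` with
  `phi = 0.05` by default; `phi = 0` yields deterministic rounded means. A
  single seeded RNG stream with fixed draw order makes output bit-identical
  under the seed.

**What the generator does not emulate**: read-level artefacts (mapping
bias, homoeolog misassignment), dispersion trends over expression,
correlated replicates, batch structure, and latent spaces richer than the
4-stage × 2-group grid. Recovery results on this generator therefore
demonstrate internal consistency of the pipeline under its own model — a
necessary check, not evidence about any particular real dataset.

## Problem sizes used in validation

The test suite and acceptance script validate at desk scale, chosen to
exercise every code path with comfortable statistical margins: planted-module
recovery on 1,000 pairs (4 × 150-pair modules, `noise_sd` 0.1, `phi` 0.05),
preservation calibration on 600-gene universes with 50 permutations, DE
calibration on 2,000-gene null and 500-gene power simulations, and
differential correlation on 100–150-pair designs. The published-table
reproductions (percentages, per-module chi-square P-values) are exact
arithmetic on the printed counts.

## Degenerate inputs and conventions

Zero-variance genes are an explicit error in correlation; modules with
fewer than 3 genes in test data give `NA` preservation statistics with a
warning; a zero null standard deviation yields an infinite Z and a
degeneracy flag; `chi_square_balance(0, 0)` is `NA`; `p0 = 0` in the DC
binomial model gives all-1 P-values; constant eigengenes give `NA` ANOVA
P-values. Pairs with either copy unassigned are excluded from the default
co-module denominator ("assigned"), with "expressed" and "all" available —
the distinction matters because published co-module fractions are quoted
against the full annotation. All orderings (module numbering, tie-breaks,
rankings) are deterministic.
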