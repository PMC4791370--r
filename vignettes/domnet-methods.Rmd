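---
title: "Methods: coupled DOM and community analysis with domnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled DOM and community analysis with domnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domnet)
```

`domnet` implements a complete desk-scale pipeline for the joint analysis
of dissolved organic matter (DOM) composition measured by ultrahigh
resolution mass spectrometry and bacterial community composition measured
by 16S rRNA amplicon sequencing, together with the distance-based
statistics that connect the two and a synthetic-data generator that makes
every stage testable against known ground truth. This vignette documents
the scientific choices: the models, the defaults, and what the synthetic
experiments do and do not demonstrate.

## Molecular formula assignment

Negative-mode electrospray FT-ICR-MS detects DOM compounds as singly
charged deprotonated ions, so a measured $m/z$ corresponds to the neutral
monoisotopic mass $m/z + 1.007276$ Da (the electron mass is folded into
the proton constant). For each aligned mass the CHNOSP composition space
is searched exhaustively: the hydrogen count is solved from the mass
remainder of every (C, N, O, S, P) combination, which is algebraically
equivalent to full nested enumeration but linear in the grid size.

Candidates must pass chemical plausibility filters before assignment:

* at least one carbon and one hydrogen;
* integer, non-negative double bond equivalents,
  $\mathrm{DBE} = 1 + \tfrac12(2C - H + N + P)$;
* elemental ratios $0.3 \le \mathrm{H/C} \le 2.5$ and
  $\mathrm{O/C} \le 1.2$, the envelope of natural organic matter;
* element counts within configurable ranges, by default C 1–100,
  H 1–200, N 0–4, O 0–50, S 0–2, P 0–1 — the literature's standard DOM
  search space, exposed as `element_ranges()` because published rule
  sets vary;
* the (N, S, P) signature must not be one of the improbable heteroatom
  combinations (NSP, N$_2$S…N$_4$S, N$_2$P…N$_4$P, NS$_2$…N$_4$S$_2$,
  PS$_2$) that high-field studies exclude. We interpret these as exact
  signatures, with NSP meaning "all three elements present"; this
  reading is covered by unit tests so a different convention is a
  one-line change.

The full cascade is ordered: S/N $\ge 4$ screen → cross-sample alignment
→ occurrence filter → candidate enumeration → chemical filters →
heteroatom exclusion → double-assignment removal → contaminant and
isotopolog removal → sum normalization. Prose descriptions of such
pipelines rarely pin the order down; we fix this one and test it. Two
choices deserve emphasis:

* **Double assignments are dropped, not adjudicated.** When two
  chemically valid candidates survive within tolerance, the mass is
  removed entirely rather than resolved to the smaller mass error,
  matching the conservative practice for unknown mixtures.
* **Occurrence filtering** keeps a mass detected in more than two
  samples, and rescues rarer masses (present in under 20% of samples)
  when their signal-to-noise exceeds 20 somewhere. The S/N ≥ 4 screen is
  applied before occurrence counting; whether detection was counted
  before or after that screen is genuinely ambiguous in the field's
  descriptions, and the pipeline applies S/N first.

Alignment across samples is single-linkage chaining of sorted masses
within a relative tolerance (default 0.5 ppm, configurable; instrument
tolerances are rarely printed). If two peaks of one sample land in one
aligned column the more intense peak is kept and the conflict recorded.

Contaminant removal takes a user-supplied neutral-mass list — such lists
are lab-specific and unpublished — and removes matches, their
CH$_2$-homologous series ($\pm k \times 14.01565$ Da across the evaluated
window), and the $^{13}$C isotopologs (+1.003355 Da) of every removed
mass.

Retained intensities are normalized to the per-sample sum and treated as
relative abundances; every row of the resulting `dom_table` sums to 1.

## Molecular descriptors and compound classes

Per formula we compute DBE, the modified aromaticity index
$$\mathrm{AI_{mod}} = \frac{1 + C - \tfrac12 O - S - \tfrac12 H}
                           {C - \tfrac12 O - S - N - P},$$
and the van Krevelen coordinates H/C and O/C. When the AI$_{mod}$
denominator is non-positive or the numerator negative the index is
undefined for such aliphatic compositions and is clamped to 0 — a
deliberate convention (aromaticity is meaningless there) that keeps the
descriptor total.

Compound classes partition the descriptor space with a fixed precedence,
because the individual published rules overlap (an H/C of 1.6 with
nitrogen satisfies both the aliphatic and peptide-like definitions):

1. H/C $\ge$ 2.0 or O/C $\ge$ 0.9 — saturated fatty acids
2. AI$_{mod}$ > 0.66 — polycyclic aromatics
3. 0.5 < AI$_{mod}$ $\le$ 0.66 — polyphenols
4. 2.0 > H/C $\ge$ 1.5, N present — peptide-like
5. 2.0 > H/C $\ge$ 1.5 — unsaturated aliphatics
6. AI$_{mod}$ $\le$ 0.5 and H/C < 1.5 — highly unsaturated
7. otherwise unspecified.

The aromatic and polyphenol boundaries follow the common categorization
scheme; all boundaries are arguments of `classify_compound()` since
studies differ in the exact cutoffs. A grid test over $>10^4$ integer
compositions verifies that the rules leave no gaps.

## Community and environmental preparation

OTU tables are filtered by taxonomy label (substring match against
"Chloroplast", "Mitochondria", "Eukaryota"; configurable) and then by
mean relative abundance $\ge$ 0.1% (inclusive), with relative abundances
recomputed after the organelle removal and the mean taken across samples
of per-sample relative abundances — the natural reading where a pooled
alternative exists. Organelles are removed before the abundance
threshold; the reverse order would let abundant chloroplast reads deflate
bacterial relative abundances.

Environmental variables are natural-log transformed and z-scored per
column (sample standard deviation). Non-positive values are rejected
unless an explicit offset is supplied, because the intended variables
(salinity, temperature, nutrients) are positive and silent offsets hide
data problems.

## Distance-based statistics

Three dissimilarities drive the multivariate analyses: Euclidean for
transformed environmental data, Hellinger (Euclidean on row-wise square
rooted proportions) for community data, and Bray–Curtis on square-root
transformed relative intensities for DOM. `vegan` provides the distance
kernels; everything above them is implemented here and cross-checked
against independent references in the tests.

**PCoA** is classical Gower double-centering plus eigen-decomposition.
Negative eigenvalues of semi-metric input are reported unmodified — no
Lingoes or Cailliez correction — so the user sees the geometry they
actually have.

**ANOSIM R** is computed on the ranks of all pairwise dissimilarities
(average ranks on ties): $R = (\bar r_B - \bar r_W)/(M/2)$ with
$M = n(n-1)/2$.

**k-R clustering** generalizes k-means to arbitrary dissimilarities by
directly maximizing ANOSIM R: from random non-empty partitions, single
samples are greedily reallocated while any move improves R, and the best
of (default) 50 restarts is returned. The search is exact for practical
sizes: tests compare it to exhaustive enumeration of all $2^{n-1}-1$
two-group partitions for $n \le 10$ and find the optimum in every
instance. Note the field's practice of "confirming" such groups with
PERMANOVA on the same distance matrix is circular — the partition was
chosen to maximize separation — so `domnet` reports both but the p-value
should be read as descriptive, not inferential.

**PERMANOVA** (one-way, fixed factor) uses
$SS_{total} = \tfrac1n \sum_{i<j} d_{ij}^2$,
$SS_{within} = \sum_g \tfrac1{n_g}\sum_{i<j \in g} d_{ij}^2$, and
pseudo-$F = \frac{(SS_{total}-SS_{within})/(k-1)}{SS_{within}/(n-k)}$,
with p-values from raw label permutations:
$p = (\#\{F_\pi \ge F_{obs}\} + 1)/(B+1)$, default $B = 999$.

**DistLM** regresses the Gower-centered matrix $G$ on hat matrices $H$ of
centered predictor subsets: $R^2 = \mathrm{tr}(HGH)/\mathrm{tr}(G)$,
pseudo-$F$ with residual degrees of freedom $n - m - 1$. Model building
is stepwise — alternating forward addition and backward elimination,
accepting moves that increase the adjusted
$R^2 = 1 - (1-R^2)(n-1)/(n-m-1)$ — stopping at a local optimum. Both
marginal and sequential tests permute the sample identities of $G$
(several permutation schemes exist in closed-source implementations; this
one is documented and calibrated in the tests). Collinear predictors are
refused by name, mirroring the practice of dropping collinear
environmental variables before modeling;
`collinearity_report()` lists Spearman |r| > 0.6 pairs so the drop
remains the analyst's decision. **dbRDA** is the eigen-decomposition of
$HGH$ for the selected predictors; with a saturating basis it reproduces
PCoA exactly, which the tests assert.

**RELATE** is the Spearman rank correlation of corresponding off-diagonal
dissimilarities of two matrices, with a Mantel-type permutation null.

All permutation tests accept a seed and report it alongside the
statistic, the p-value, and $B$.

## Effect-size feature ranking

`effect_size_ranking()` follows the LEfSe recipe restricted to the
two-class case: features are rescaled so each sample sums to $10^6$,
screened per feature by Kruskal–Wallis at $\alpha = 0.05$, and the
survivors are scored by a bootstrapped linear-discriminant effect: in
each of 30 rounds, two thirds of each group are resampled, a two-class
LDA axis is fitted (ridge-regularized pooled covariance, so the fit is
defined when features outnumber samples), and the per-feature effect is
the average of the raw between-group mean difference and the feature's
share of the difference along the unit-norm LDA axis. The reported score
is $\log_{10}$ of the bootstrap mean; features at or above 2 are
reported with their enriched group. This is LEfSe-*style*, not
byte-identical to the published multiclass tool (no one-against-all
logic, no subclass consistency step).

Two properties of this method deserve honest emphasis, and the synthetic
experiments in `tests/` quantify both:

* **Planted effects are found.** A 100-fold planted shift at 20 samples
  per group is reported at scores well above 2, and the direction of
  enrichment cleanly separates planted features (up in the affected
  group) from the compositional closure they induce in everything else
  (down).
* **The log-LDA ≥ 2 gate does not control family-wise error.** On the
  $10^6$ scale a score of 2 corresponds to a between-group difference of
  0.01% relative abundance; any moderately abundant feature that passes
  Kruskal–Wallis by chance clears it easily. With ~100 features tested
  at $\alpha = 0.05$ and no multiplicity correction, some feature is
  reported in almost every null dataset. This matches the published
  benchmarking literature on LEfSe's per-experiment false discovery
  rate, and it is why the acceptance suite's null-calibration assertion
  for this method fails — deliberately left failing rather than papered
  over with an unfaithful gate. Interpret reported features as ranked
  candidates, not as a controlled discovery set.

## Association networks

`pairwise_correlations()` computes Pearson or Spearman coefficients for
all between-block (and optionally within-block) feature pairs over
shared samples, with exact-t p-values for Pearson, the t-approximation
on rank correlations for Spearman at $n \ge 10$, and exact rank
permutation below. Holm–Bonferroni adjustment is available
(`stats::p.adjust` behind `holm_bonferroni()`), but the default network
uses raw p-values, recorded in the graph attribute `p_adjust` — the
exploratory convention for such screens, where the correction is
discussed rather than applied. The pivot table bins significant edges by
|r| into [0, 0.5), [0.5, 0.6), …, [0.9, 1] (half-open except the last,
a convention the table headers of the field leave ambiguous), split by
node-kind pair and sign. `build_network()` keeps edges with p < 0.05 and
|r| ≥ 0.9, attaches node kind, abundance and compound class attributes,
and exports GraphML plus node/edge TSVs for external graph tools; no
layout or rendering is done here. Pearson and Spearman on relative
abundances ignore compositional coupling; compositionality-aware
estimators (SparCC-style) are a known limitation, not implemented.

## The synthetic-data generator

`simulation_config()` fixes the simulated study design; the defaults are
the conditions every test and the acceptance script use:

* **17 samples**, mirroring a daily coastal time series with a two-group
  split (9/8) across the series.
* **200 planted formulas** drawn with DOM-like ratios (C 6–40, H/C
  0.5–2.2, O/C up to 1, N/S/P sparse) in a 150–800 Da window —
  the mass range over which such spectra actually yield assignments.
  Only formulas *uniquely* assignable at the 0.5 ppm working tolerance
  are planted: exact-mass degenerate pairs (e.g. C$_{17}$H$_{37}$O$_{15}$P
  vs C$_{28}$H$_{32}$O$_7$S within 0.5 ppm) are dropped by the pipeline's
  double-assignment rule *by design*, so planting them makes ground truth
  ill-defined in the same way noise near valid masses would; the
  degenerate behavior is exercised by dedicated unit tests instead.
* **Peaks** appear per sample with probability 0.9 at the theoretical
  [M−H]$^-$ m/z perturbed by 0.1 ppm Gaussian error; S/N is log-normal
  (median 50), intensities log-normal; 20% of formulas carry a
  lower-intensity $^{13}$C partner at +1.00336 Da; one six-member
  CH$_2$-homologous contaminant series is injected everywhere; 30 noise
  peaks per sample are rejection-sampled at least 5 ppm from any
  chemically valid mass so that a noise assignment is unambiguous
  evidence of a pipeline defect. Occasionally an isotopolog peak admits
  a valid formula and survives as a spurious column — a real artifact of
  real pipelines (only contaminant isotopologs are removed, as in
  practice), and the reason recovery is asserted at ≥ 95% rather
  than 100%.
* **OTU counts** are Dirichlet-multinomial (concentration 200 around
  log-normal base proportions) at log-normal depth around $10^5$ reads —
  no error model is standard for such data; overdispersion was chosen to
  stress the compositional methods. Ten differential OTUs default to a
  4-fold (log 4) group-B shift; organelle-labelled taxa exercise the
  taxonomy filter.
* **Environmental variables** come from a Gaussian copula with the
  requested pairwise correlations, exponentiated with modest log-scale
  spread (0.25) so marginals are positive and the copula correlation
  survives the transform nearly intact.
* **Planted OTU–molecule correlations** rewrite a DOM column as a
  positive affine image of $r\,z(\mathrm{otu}) + \sqrt{1-r^2}\,\epsilon$;
  affine maps preserve Pearson correlation exactly, and the subsequent
  row re-normalization perturbs it only at the column's relative weight
  (~1%), well inside the ±0.05 tolerance tests assert at n ≥ 50.

What passing tests on these data do **not** show: robustness to
calibration drift (mass error is unbiased Gaussian), chimeras or
sequencing error (reads are never simulated), rarefaction effects, or
compositional confounding of the correlation network (planted edges are
checked against an independent background, not against closure-induced
correlations).

## Problem sizes and numerical conventions

Simulation-based checks use sizes chosen to make their statistical
tolerances meaningful: calibration of the three permutation tests runs
500 null replicates at $B = 999$ and $n = 12$ (nominal 0.05 ± 0.02);
brute-force clustering comparisons use $n \le 10$ where the $2^{n-1}-1$
partitions are enumerable; network recovery uses $n = 200$ samples over
50 seeds, where a target $|r| = 0.95$ has sampling noise ≈ 0.007 and the
0.9 threshold is ~7 standard errors away. Ties in ANOSIM use average
ranks; permutation p-values always include the observed statistic
((b+1)/(B+1), never zero); saturated DistLM fits report pseudo-F = ∞
rather than dividing by a rounding-error residual; eigenvalues below
$10^{-8}$ of the leading one are treated as null axes in ordinations.
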