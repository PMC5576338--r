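---
title: "Factorial differential expression and pathway interpretation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Factorial differential expression and pathway interpretation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(factorex)
library(dplyr)
```

factorex analyses genes-by-samples expression matrices from 2x2 factorial
designs. The motivating setting is the neonatal hyperoxia model of
bronchopulmonary dysplasia (BPD): wild-type and SphK1-knockout mouse pups
exposed to room air or 75% oxygen, three lungs per group, profiled on an
expression array summarized to one log2 value per gene and sample. Everything
below applies unchanged to any two-factor, two-level design.

## The statistical model

For each gene the package fits the two-way fixed-effects ANOVA

$$y_{ijk} = \mu + \alpha_i + \beta_j + (\alpha\beta)_{ij} + \varepsilon_{ijk},
\qquad \varepsilon_{ijk} \sim N(0, \sigma^2),$$

where $\alpha$ is genotype (WT/KO), $\beta$ is oxygen (RA/HO), and $k$ indexes
replicates. Three F tests are reported per gene: both main effects and the
interaction, each on 1 numerator degree of freedom and $N - 4$ residual
degrees of freedom. For balanced cells the sums of squares are computed with
the closed-form factorial (moment) decomposition, which coincides exactly
with least squares; this is what makes the gene-wise stage a handful of
matrix operations over the whole matrix rather than thousands of model fits.
Unbalanced designs fall back to Type-II least-squares sums of squares
computed through projection matrices shared across genes. The balanced path
is verified against an independent `lm()`/`anova()` oracle, the unbalanced
path against `car::Anova(type = 2)`.

Direction and magnitude of change come from Fisher's LSD contrasts on the
pooled residual mean square:
$t = (\bar y_u - \bar y_v)/\sqrt{MS_E (1/n_u + 1/n_v)}$ with $df_E$ degrees
of freedom, and fold change $2^{\bar y_u - \bar y_v}$ since the analysis
scale is log2. All six group pairs are reported; the three contrasts against
WT-RA are the ones compared with qPCR.

Multiplicity is controlled per effect family with Benjamini-Hochberg
(`stats::p.adjust`); pooling all three families into one is available as an
option since published methods sections rarely say which was used. Genes
with zero residual variance have undefined F statistics; they are flagged
and excluded from the BH family size rather than given an arbitrary p-value.

Significant genes (default q < 0.05) are partitioned into the seven disjoint
regions of the genotype/oxygen/interaction Venn diagram. A "circle total"
for an effect is the sum of the four regions containing it; the identity is
checked two ways (region sums vs direct flag counts) on every synthetic
instance.

## Enrichment and mega pathways

Over-representation uses the exact hypergeometric upper tail
$P(X \ge k)$ for overlap $k$ between the query list and each set, within a
universe defined as all genes tested in the ANOVA (not the union of the
collection — the array, not the ontology, defines what could have been
seen). The default query is the interaction circle, configurable to any
effect, because "genes responding to oxygen depending on genotype" is the
scientific question the interaction term answers. Results are ranked by p
with deterministic lexicographic tie-breaks, BH-adjusted across the
collection, and cut to the top 50 by default.

Curated pathway ontologies are redundant: many entries are sub-segments of
the same biology. The package collapses the top enriched pathways into
"mega pathways" by agglomerative complete-linkage clustering on the Jaccard
distance $d = 1 - |A \cap B| / |A \cup B|$ between the *complete* gene sets
(not just their differential members), cutting the dendrogram so clusters
are the maximal groups with merge height at most 0.6. The threshold is
closed ($\le$ 0.6) — the boundary case is deliberately merged — and ties in
merge distance are broken by the lexicographically smallest pair of cluster
labels, so output is identical across platforms. Each mega pathway pools the
union of its members' genes intersected with the differential flags; that
pooled list drives the heatmap export.

Heatmaps show per-gene z-scores, $(x - \bar x)/s$ with the sample ($n-1$)
standard deviation. Constant rows map to zero with a warning. The familiar
±2 color bound is applied only to rendered fills, never to exported
numbers — it is a display convention, not a transform. Because published
figures rarely say whether they show per-sample or per-group-mean z-scores,
both tables are exported.

## qPCR validation

Relative expression uses the standard $2^{-\Delta\Delta Ct}$ method:
$\Delta Ct$ = target minus reference-gene Ct within a sample,
$\Delta\Delta Ct$ = $\Delta Ct$ minus the reference-group mean, group fold
change $2^{-\overline{\Delta\Delta Ct}}$ (the geometric mean of per-sample
ratios, the natural choice on a log-scale assay). Any per-sample additive
shift applied to all Ct values cancels — that is what reference
normalization buys. Platform agreement is "vectorial": a (gene, group) pair
is concordant when both platforms call the same direction, with a
configurable no-change band of half-width $\delta$ log2 units (default 0).
The band is a parameter rather than a constant because published
concordance counts rarely state their exact rule; on the bundled 24-gene
example panel the strict $\delta = 0$ rule yields 23/24 concordant genes in
the WT-HO column. Paired t tests between groups use the classical closed
form, with zero-variance differences handled explicitly (t = 0, p = 1 when
all differences are zero; infinite t, p = 0, flagged, when they are
constant but non-zero).

## The synthetic study

`simulate_expression()` generates
$x_{gs} = \mu_g + \beta_G\,[KO] + \beta_O\,[HO] + \beta_I\,[KO \wedge HO]
+ \varepsilon$, with $\mu_g \sim N(7, 1.5^2)$ (log2 units, typical of
RMA-style summaries), $\varepsilon \sim N(0, 0.5^2)$, and each effect term
present only for genes of its class. Classes are disjoint random subsets in
configured fractions (defaults 5% genotype, 10% oxygen, 5% interaction);
the default design is 3 replicates per group, the usual per-group lung
count in this literature. One global seed drives all three sub-generators
through a fixed splitting scheme, so an entire synthetic study is
reproducible from a single integer.

Default effect sizes are $\beta_G = \beta_O = 2$ (4-fold) and
$\beta_I = 4$. The asymmetry is deliberate: the interaction term enters
only the KO-hyperoxia cell, so its interaction contrast
$(\bar y_{11} - \bar y_{12} - \bar y_{21} + \bar y_{22})$ carries
noncentrality $n\beta^2/(4\sigma^2)$ — a quarter of what an
equal-magnitude main effect gets. At $n = 3$ and $\sigma = 0.5$, a
detectable interaction therefore needs roughly twice the log2 magnitude of
a main effect; $\beta_I = 4$ puts its noncentrality at 48, comparable to
the main effects. Cell-specific inductions of this size are well within
what hyperoxia stress genes show.

`simulate_pathways()` plants half the collection on effect classes: a
planted set draws a fraction $\rho$ (default 0.8) of members from its
class and the rest uniformly from the not-yet-chosen remainder, so
$\rho = 0$ degenerates exactly to a null set. A fraction of planted
pathways (default 0.2) also emits a redundant sub-segment companion
sharing ~70% of its parent's genes, emulating the ontology redundancy that
makes mega-pathway clustering worthwhile. `simulate_ct()` derives Ct
values linearly from the expression matrix (one cycle per log2 unit), so
with zero Ct noise the $2^{-\Delta\Delta Ct}$ group fold change equals
$2^{\text{group mean log2 difference}}$ exactly — a closed form the tests
assert to 1e-9.

What the generator does *not* emulate: probe-level effects, batch or
spatial artifacts, heteroscedastic or heavy-tailed noise,
correlated genes, and amplification-efficiency deviations in qPCR. Passing
tests therefore demonstrate correctness of the computations and
calibration under the generative model, not robustness to every failure
mode of real arrays.

## Normalization in the demo

`quantile_normalize()` forces every sample onto the per-rank mean
distribution, with ties receiving the mean of their ranks' targets; it is
idempotent and matches limma's reference implementation. It is on by
default for real ingests, mirroring standard array processing. The
self-contained demo (`make_demo()`) runs with it *off*: the simulator
emulates an already-summarized matrix with no technical column effects,
and when 20% of genes shift in one direction, re-normalizing redistributes
part of that planted signal onto null genes — the well-known quantile
normalization bias under asymmetric change. The choice is about what the
generator emulates, not about making numbers look better; both settings
are one flag apart.

## Numerical and design choices

- Gene identifiers are matched case-insensitively (uppercased) across the
  matrix, gene sets and Ct tables; original casing is preserved for
  display, since mouse and human symbol conventions differ only by case.
- Duplicate gene rows keep the highest-mean row (deterministic, common
  array practice); rows with any missing value are dropped and counted.
- Fold changes are $2^{\Delta}$ of log2-scale group mean differences;
  reciprocal pairs multiply to 1 by construction.
- BH is applied to the step-up definition via `stats::p.adjust`; a
  brute-force implementation of the definition is kept in the test suite
  as an independent oracle, exhaustively for all short p-vectors.
- Degenerate inputs are contractual, not accidental: zero residual
  variance with unequal means gives infinite statistics with p = 0 and a
  flag; all-identical data gives zero sums of squares and a flag.
- The problem sizes exercised by the test suite (2,000-gene simulations,
  20 seeds for the calibration studies, exhaustive hypergeometric sweeps
  to N = 12, 500 clustering instances) were chosen as the smallest sizes
  at which the calibration quantities stabilize.

## Known limitations

- The mega-pathway stage reproduces the clustering rule, not any
  particular published cluster structure, which depends on a proprietary
  ontology's gene sets; users supply their own GMT.
- No empirical-Bayes variance moderation: with 3 replicates per group the
  plain ANOVA is noisy per gene, which is faithful to the analysis the
  pipeline mirrors, not an endorsement. limma-style moderation would be
  the natural extension.
- Single-cell interaction effects of modest size (log2 magnitude ~2 at
  $\sigma = 0.5$, n = 3) are essentially undetectable at FDR 0.05 — the
  noncentrality argument above quantifies this — so interaction screens at
  this design size only see large cell-specific changes.
- The annotation join from array transcript ids to gene symbols is left to
  a user-supplied mapping; the package does not ship vendor annotation.
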