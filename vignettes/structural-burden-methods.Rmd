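---
title: "Structural burden analysis and the per-residue pathogenic 3D feature index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural burden analysis and the per-residue pathogenic 3D feature index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Missense variants substitute a single amino acid, and whether a given
substitution is pathogenic depends heavily on *where* in the folded protein
it lands. This package characterizes that dependence with a catalog of 40
binary residue-level "3D features" in seven categories — secondary
structure (the eight DSSP classes), solvent exposure (five relative-
accessibility bins), the physicochemical class of the reference amino acid,
bond participation (hydrogen bonds, salt bridges, disulfides; intra- vs
inter-molecular), PTM site type, spatial proximity (< 10 Å) to PTM sites of
six types, and UniProt-style functional annotations.

For each feature $j$ and each gene group $g$ (the pooled all-genes set, or
one protein functional class), variants labelled *pathogenic* and
*population* are cross-tabulated against feature presence at the altered
position:

$$\mathrm{OR} = \frac{a\,d}{b\,c}, \qquad
a = \text{pathogenic with feature}, \; b = \text{without}, \;
c,d = \text{the same for population variants}.$$

Significance comes from the two-sided Fisher exact test under the
probability-ordering ("minlike") rule, and p values are corrected
multiplicatively, $q = \min(1, p \cdot m)$. A feature with
$\mathrm{OR} > 1$ and $q < 0.05$ is *pathogenic-associated* in that group;
$\mathrm{OR} < 1$ and $q < 0.05$ makes it *population-associated*. The two
per-group sets are disjoint by construction.

The per-residue **pathogenic 3D feature index (P3DFi)** counts, for the
reference amino acid at a position, how many of its set features fall in
the context group's pathogenic set ($\mathrm{3DF_{PATH}}$) and population
set ($\mathrm{3DF_{POP}}$):

$$\mathrm{P3DFi} = \mathrm{3DF_{PATH}} - \mathrm{3DF_{POP}}.$$

A positive index marks a 3D mutational hotspot. Indices are binned
($< -2, -2, \dots, 2, > 2$); strictly beyond $\pm 2$ they support
high-confidence pathogenic-like / benign-like calls. Downstream, the index
joins SIFT-, PolyPhen2- and CADD-like predictor scores in a bagged
decision-tree ensemble (2,000 Gini trees of depth ≤ 10 by default, scores
$> 0.5$ called pathogenic).

## Tunable parameters

| Parameter | Default | Units / rationale |
|---|---|---|
| PTM proximity cutoff | 10 Å, strict `<` | Cα–Cα; the published "near (<10 Å)" convention |
| Distance convention | Cα–Cα | consistent with the 6.8 Å printed for an i, i+4 pair; min-heavy-atom is a config option |
| Exposure bin edges | 5 / 25 / 50 / 75 % RSA | the first two edges are published; the upper bins continue them at equal width |
| MaxASA table | Tien et al. (2013), theoretical | the normalisation is not stated in the source material; any named table can be passed |
| Correction multiplier | number of tests run | `correction = "fixed", m = 1000` reproduces the historical fixed multiplier (40 features × 25 groups); the default avoids silently keeping 1,000 when the catalog or grouping changes |
| OR point estimate | sample `ad/bc` | reproduces exact zeros; conditional-MLE available for cross-checks |
| CI method | Woolf logit, Haldane–Anscombe +0.5 on zero cells | transparent closed form; the correction affects the interval only, never the point estimate |
| Ensemble | 2,000 trees, Gini, depth 10, threshold 0.5 | the published configuration; score = mean per-tree class probability, vote fraction by flag |

Amino-acid group membership: `special = {C, G, P}` and
`aromatic = {F, W, Y}` are fixed; the default split of the remaining
residues into aliphatic / charged / polar / neutral groups is an editable
map (`aa_group_map()`), since only the two fixed groups are published.

## Consolidation across structures

A UniProt position mapped to several structure residues takes a feature if
it is present in **at least one** of them (maximising sensitivity; a
position exposed in one structure and core in another carries both
exposure bits). Positions with no mapped structure get only their
physicochemical and functional bits, are flagged `unresolved`, and are
excluded from burden tables. Bond features (PDBsum-style) arrive as input
flags and are not recomputed from geometry.

## What the synthetic generator emulates — and what it does not

The source study mined real variant, structure and annotation databases
and states no generative model, so the cohort generator is a synthetic
stand-in whose defaults were fixed once:

* ~1:5 pathogenic:population mix (baseline log-odds $\log(1/5) = -1.61$),
  matching the real cohort's 32,923 / 164,915 proportions;
* one secondary-structure class and one exposure bin per residue
  (multinomial, with weights near observed proteome frequencies); the
  remaining features Bernoulli, conditionally independent given the gene's
  class; physicochemical bits derived from the sampled reference amino
  acid (a pure function of it);
* labels Bernoulli with
  $P(\text{pathogenic} \mid f) = \operatorname{logit}^{-1}(\beta_0 +
  \sum_j \beta_j f_j)$, where $\beta_j$ are *planted* log odds ratios;
* label-conditional Beta scores for the bounded predictors and Gamma for
  the unbounded one; and fitness
  $= -\alpha \cdot \mathrm{P3DFi} + \varepsilon$,
  $\varepsilon \sim N(0, \sigma^2)$.

Not modelled: real allele frequencies, mutational signatures, structure
coverage bias (the study's 61% vs 33% mapping rates), feature
correlations (available only as a config extension so that OR recovery
stays analytically checkable), and alt-allele preference (alt is uniform
over the 19 other residues). Passing tests therefore demonstrate that the
*machinery* is correct under a known truth, not that real cohorts satisfy
the generator's assumptions.

Two deliberate consequences of the design:

* **Parameter recovery plants one effect at a time.** With several nonzero
  $\beta_j$ the collapsed 2×2 odds ratio is attenuated relative to the
  conditional logistic coefficient (non-collapsibility), so exact recovery
  of $e^{\beta_j}$ holds only for a single planted effect.
* **Benign labels.** The generator emits pathogenic/population labels;
  validation-style analyses treat the population stratum as benign, since
  the study's separate benign set came from later database releases.
* **Multi-class genes** resolve per-feature prevalences and planted
  coefficients by averaging over their member classes.

## Numerical choices

* `fisher_two_sided()` enumerates the hypergeometric support directly and
  sums probabilities $\le$ the observed one within a relative tolerance of
  $1 + 10^{-7}$ (the convention of the mainstream implementations, which
  serve as the independent oracle in the tests — the suite sweeps every
  margin-positive table with $n \le 30$).
* The Mann–Whitney test uses midranks; its exact branch enumerates all
  $\binom{n_1+n_2}{n_1}$ splits (feasible up to 50,000 splits) and is
  exact under ties; beyond that, the normal approximation with tie
  correction (no continuity correction) takes over. All values identical
  gives $p = 1$.
* OR sentinels: $0$ when $ad = 0 < bc$, $\infty$ when $bc = 0 < ad$,
  undefined (`NaN`) for $0/0$; untestable tables (an empty margin) are
  reported, flagged, and carry association `none`.
* MCC with a zero denominator is 0 by convention; single-class truths give
  `NA` for the undefined metrics.
* Ties at the decision threshold (score exactly 0.5) are called benign —
  the threshold rule is strict `>`.
* The index convention is fixed so that **positive = hotspot** (the
  worked example's +6); one sentence of the source text conflicts
  typographically with its own parallel sentence, and the worked example
  resolves it.
* Per-variant index = index of the reference residue at the variant
  position; uncapped counting within categories (no per-category cap is
  stated anywhere).
* A gene with multiple classes gets one index per class context plus the
  all-genes context; nothing is auto-aggregated.

## The worked example

`brct_worked_example()` rebuilds the published F1704 illustration from
scratch: a synthetic BRCT-like structure fixture (DSSP + Cα-only PDB,
positions 1696–1712 of chain X) encodes the printed properties of the real
residue — 0 Å² accessible surface area, β-strand context, an idealised
helical Cα trace whose pitch places the phosphosite four residues away at
exactly 6.8 Å — inside invented coordinates. The annotation pipeline sets
six bits (modular domain, core, β-strand, aromatic, intramolecular
hydrogen bond, phosphorylation proximity); all six lie in the
reconstructed nucleic-acid-binding pathogenic set and none in the
population set, so the index is $6 - 0 = 6$. The printed account lists
five annotations explicitly; the sixth encoded bit is the hydrogen bond, a
standard PDBsum-style flag for a core β-strand residue, and hydrogen-bond
sites are pathogenic-associated in this class per the published
class-level results. The shipped association table
(`extdata/associations_nucleic_acid_binding_reconstruction.tsv`) is a
reconstruction and is labelled as such.

## Problem sizes used by the experiments

Chosen once as the package's study conditions: parameter recovery uses 100
replicate cohorts of 50,000 variants with a planted fourfold OR at
prevalence 0.3 (coverage of the Woolf CI ≥ 90% expected at its nominal
95%); null calibration pools ≥ 1,000 feature tests from 30 all-null
cohorts of 2,000 variants (the exact test is slightly conservative on
discrete tables, so the rejection rate sits just under 5%); the ensemble
ordering replication runs 25 cohorts of 4,500 variants with weakly
informative predictor scores and strong planted structural effects, 300
trees per forest (the published 2,000 trees are unnecessary for an
ordering question and would only slow the replication).

## Known limitations

* The catalog's exact 40 identities are a reconstruction (`v1`); only the
  category structure and a subset of names are published. Swap in your own
  catalog data frame to change it.
* DSSP output is an *input*: accessible surface areas are never recomputed
  from coordinates, and mmCIF/homology models are out of scope.
* The fine-grained 25-feature functional re-analysis is expressible
  through a custom catalog but ships with no default support.
* Published headline numbers that require licensed or full-scale variant
  databases (the real ORs, validation fractions, Table-style metric
  values) are out of reach by design; the package replaces them with
  planted-truth replications.
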