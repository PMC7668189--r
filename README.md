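# p3dfi — structural burden analysis and the pathogenic 3D feature index

Most missense variants found by clinical sequencing are of uncertain
significance. Whether an amino-acid substitution damages a protein depends
on *where* it lands in the folded structure: a buried core residue, a
disulfide-bonded cysteine, or a position next to a phosphorylation site
tolerates substitution very differently from a solvent-exposed loop
residue. `p3dfi` is an R package for quantifying that dependence and
turning it into a per-residue score. It is written for computational
biologists working on variant interpretation who want a transparent,
testable alternative to black-box pathogenicity predictors.

## What it computes

Residues are annotated with a configurable catalog of **40 binary 3D
features** in seven categories (DSSP secondary-structure classes,
relative-solvent-accessibility bins, physicochemical groups, bond
participation, PTM sites, PTM spatial proximity within 10 Å, functional
regions). For each feature and each gene group (all genes pooled, or one
protein functional class), pathogenic and population variants are
cross-tabulated against feature presence:

    OR = (a·d)/(b·c)        a = pathogenic with feature, b = without,
                            c, d = the same for population variants

with a two-sided Fisher exact p value, Woolf 95% CI, multiplicative
correction `q = min(1, p·m)`, and the relative risk as a concordance
check. Features with `OR > 1, q < 0.05` form a group's
*pathogenic-associated* set; `OR < 1, q < 0.05` the *population-associated*
set. The **pathogenic 3D feature index** of a residue is

    P3DFi = 3DF_PATH − 3DF_POP

— the number of its features in the pathogenic set minus the number in the
population set; positive values mark 3D mutational hotspots. The index can
be binned, used for high-confidence calls beyond ±2, correlated with
saturation-mutagenesis fitness data, and fed with SIFT/PolyPhen2/CADD-like
scores into a bagged decision-tree ensemble (2,000 Gini trees, depth ≤ 10).

A synthetic-cohort generator with *planted* per-feature log odds ratios
makes every stage testable without any external database: planted effects
must be recovered, null cohorts must stay quiet, and the index-bearing
ensemble must match or beat the index-free one.

## Worked example

The package ships a fully synthetic BRCT-domain fixture that encodes the
printed structural properties of BRCA1 residue F1704 (0 Å² accessible
surface area, β-strand context, a phosphosite four residues away at
6.8 Å). Running the whole annotation pipeline on it and scoring against
the reconstructed nucleic-acid-binding association sets:

```r
library(p3dfi)
ex <- brct_worked_example()
ex$vector
#> <residue BRCA1 F1704> 6/40 features set
#>   ss_strand, exp_core, aa_aromatic, bond_hbond_intra,
#>   ptm_near_phosphorylation, func_modular_domain
ex$score
#> <P3DFi BRCA1 F1704 | nucleic_acid_binding> path 6 - pop 0 = +6  [3D mutational hotspot]
```

All six features of F1704 are pathogenic-associated in nucleic-acid-binding
proteins and none is population-associated, so the index is +6: the residue
is predicted intolerant to substitution — matching the mutagenesis
experiments in which every substitution of this position is loss of
function.

## The analysis workflow

`analysis/` holds five numbered drivers that run the pipeline end to end on
a simulated cohort and write their tables under `results/`:

1. `01_simulate_cohort.R` — 50 genes, 7,500 variants (~1:5
   pathogenic:population), eight planted structural effects; writes the
   cohort TSVs plus miniature DSSP/PDB fixtures.
2. `02_annotate_worked_example.R` — the annotation pipeline on the BRCT
   fixture (prints the F1704 table above).
3. `03_burden_analysis.R` — the full burden analysis. On the demonstration
   cohort it recovers the planted signals (e.g. modular domain OR 2.9,
   q ≈ 9e-87; core OR 2.7; exposed OR 0.34) with an RR–OR log-scale
   concordance of r² ≈ 0.98, 90% CI coverage in the planted-OR-4 recovery
   replicates, and a 4.5% null rejection rate.
4. `04_p3dfi_validation.R` — per-variant index distributions by label
   (Mann–Whitney p ≈ 4e-162 on the demonstration cohort), high-confidence
   calls, and the fitness correlation (r² ≈ 0.43 at the default 1:1-ish
   signal:noise).
5. `05_ensemble_models.R` — the three-ensemble comparison on a common
   split (with class index / with all-genes index / without) plus ROC
   points; the index-bearing model matched or beat the index-free one in
   all ordering replicates (mean MCC 0.44 vs 0.36).

Run them in order from the repository root after installing the package:

```sh
Rscript analysis/01_simulate_cohort.R   # ... through 05
```

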