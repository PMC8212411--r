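# cytocrosstalk

Discovery of condition-specific cytokine–receptor cross-talk axes between
tumours and bone-marrow hematopoietic stem and progenitor cells (HSPCs),
from single-cell expression counts and a tumour-secretome array.

## The problem

Tumours of high metastatic potential remodel the bone-marrow compartment:
the composition of sorted LSK (Lin− Sca1+ Kit+) progenitors shifts between
hosts bearing low- versus high-metastatic tumours, and individual
progenitor populations — notably monocyte-dendritic progenitors (MDPs) —
change receptor expression in response to tumour-secreted cytokines.
Given (a) a gene × cell count matrix with a per-cell condition label
(`low` / `high`), (b) a reference expression compendium of sorted cell
types, (c) a two-condition secreted-factor densitometry table, and (d) a
ligand–receptor pair table, `cytocrosstalk` produces a ranked list of
(ligand, receptor, cell type) axes that could mediate the tumour-to-marrow
cross-talk — the analysis pattern that singles out IL-6 → Il6ra on MDPs.

## Methods at the core

* **QC / normalization** — cells with < 1000 detected genes, genes seen in
  < 3 cells, and cells with > 5 % mitochondrial counts are removed (in a
  fixed, documented order); values are log-normalized,
  `log(1 + c/C · 10⁴)`; variable genes are ranked by binned standardized
  dispersion.
* **Annotation** — each cell is assigned the reference type maximising the
  Spearman correlation ρ(cell, type) over the variable genes; confidence
  uses a χ²₁ outlier statistic
  `T = ((max − median(others)) / (1.4826·MAD(others)))²`, and cells with
  `p ≥ 0.05` (or tied scores) are pruned.
* **Composition shifts** — per type, the difference of proportions
  `θ = p_high − p_low` is tested with the bias-corrected and accelerated
  (BCa) bootstrap for two independent samples, one-sided:
  `z₀ = Φ⁻¹(#{θ* < θ̂}/B)` (ties counted half), acceleration
  `a = Σd³ / (6(Σd²)^{3/2})` from delete-one jackknife, p-value by
  inversion of the one-sided BCa bound (bisection, tolerance 10⁻⁴,
  floor 1/B).
* **Differential expression** — per cell type, genes detected in ≥ 10 % of
  cells in either condition and showing ≥ 1.2-fold difference (either
  direction, on de-logged means with unit pseudocount) are tested with the
  Wilcoxon rank-sum test (exact for small tie-free samples, tie-corrected
  normal approximation otherwise) and BH-adjusted across the tested set.
* **Pairing / ranking** — array ratios (high/low densitometry) are joined
  to receptors via the pair table; axes with ligand ratio > 1 and a
  significantly up-regulated receptor (FC > 1, adjusted p < 0.05) are
  ranked by ligand ratio, then receptor fold change, then adjusted p.

A fully deterministic synthetic-data generator plants a known ground truth
(composition shift, a ~1.2-fold receptor effect confined to one type in
one condition, an elevated secretome ratio for the matching ligand), so
the whole pipeline is testable offline. See the methods vignette
(`vignettes/crosstalk-methods.Rmd`) for model details and design choices.

## Worked example

```r
library(cytocrosstalk)

cfg <- pipeline_config(truth = simulation_truth(seed = 1), seed = 1)
res <- discover_axes(cfg)

subset(res$proportion_tests, cell_type %in% c("MDP", "GMP"),
       select = c(cell_type, p_low, p_high, diff, ci_low, ci_high,
                  p_value, direction))
#>  cell_type p_low p_high   diff  ci_low ci_high p_value direction
#>        GMP 0.227 0.0935 -0.134 -0.1856 -0.0845   1e-04      less
#>        MDP 0.124 0.2545  0.131  0.0761  0.1850   1e-04   greater

res$ranking
#>  ligand receptor cell_type ligand_ratio receptor_fold    p_adj rank
#>     IL6    Il6ra       MDP        2.317         1.336 0.008865    1
```

The simulated experiment planted an MDP enrichment (10 % → 25 %) against a
GMP depletion, a 1.21-fold `Il6ra` up-regulation confined to
high-condition MDPs, and a 2.5× IL-6 secretome ratio. The output shows
exactly that story: MDP is significantly enriched and GMP depleted in the
high-metastatic condition (one-sided BCa p at the 10⁻⁴ floor for both,
B = 10,000), and the one axis passing every gate — IL-6 signalling into
`Il6ra` on MDPs — is ranked first, with the observed ligand ratio (2.32),
the recovered receptor fold change (1.34 at this seed and group size) and
its adjusted p-value.

To write all artifacts (MTX counts, annotations, proportion tests, DE
records, the ranking and a reproducibility manifest) to disk instead, use
`run_pipeline(pipeline_config(out_dir = "out", seed = 1))`.

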