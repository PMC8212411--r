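---
title: "Methods: discovering tumour-to-progenitor cytokine cross-talk axes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering tumour-to-progenitor cytokine cross-talk axes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytocrosstalk)
```

## The scientific question

Highly metastatic tumours remodel the bone-marrow compartment: the
composition of hematopoietic stem and progenitor cells (HSPCs, sorted as
Lin- Sca1+ Kit+ "LSK" cells) shifts between hosts bearing tumours of low
versus high metastatic potential, and individual progenitor populations can
change their receptor expression in response to tumour-secreted factors.
`cytocrosstalk` implements the computational path from (i) a single-cell
expression count matrix of LSK cells carrying a per-cell condition label
(`low` / `high` metastatic potential) and (ii) a two-condition secreted-factor
densitometry table, to a ranked list of condition-specific
cytokine-receptor cross-talk axes — the kind of analysis that singles out
IL-6 signalling into its receptor `Il6ra` on monocyte-dendritic progenitors
(MDPs).

The pipeline has five analysis stages, each exposed as ordinary R
functions, plus a synthetic-data generator that plants a known ground truth
so that every stage is testable without any external download:

1. **QC and normalization** (`filter_matrix`, `log_normalize`,
   `select_variable_genes`)
2. **Reference-based cell-type annotation** (`score_cells`, `outlier_test`,
   `annotate`)
3. **Composition shift testing** (`celltype_proportions`, `bca_test`,
   `test_all_proportions`)
4. **Per-type differential expression** (`wilcoxon_rank_sum`,
   `fold_change`, `bh_adjust`, `differential_expression`)
5. **Ligand-receptor pairing and ranking** (`array_ratios`,
   `pair_and_rank`)

`discover_axes()` chains them in memory; `run_pipeline()` additionally
writes every artifact plus a JSON manifest sufficient to reproduce the run
bit-identically.

## The synthetic-data generator

The generator (`simulation_truth`, `simulate_counts`, `generate_reference`,
`simulate_secretome`, `make_lr_table`) encodes the statistical structure
the real experiment exhibits, with every effect planted explicitly:

* **Cell types and markers.** Ten progenitor types (LT-HSC, ST-HSC, MPP,
  MLP, CLP, CMP, GMP, MDP, CDP, MEP) each own a disjoint program of 30
  marker genes expressed at `marker_fold = 8` times the baseline rate.
  A 2,000-gene universe with ~15% marker genes keeps annotation realistic
  while staying fast.
* **Composition shift.** By default MDP rises from 10% (`low`) to 25%
  (`high`) while GMP falls from 25% to 10%; the remaining eight types share
  the rest evenly. 400 cells are drawn per condition, comparable to the
  cell count of a filtered two-plate sorting experiment.
* **Receptor effect.** The planted receptor (`Il6ra` by default) has its
  expression rate multiplied by `receptor_fold = 1.21` only in cells of the
  target type in the `high` condition — a deliberately subtle effect of the
  size reported for real receptor shifts.
* **Count model.** Counts are negative binomial with a single dispersion
  parameter (`dropout_dispersion = 0.15`; `0` gives exact Poisson, useful
  for closed-form checks). Per-cell library sizes are log-normal around
  `library_size_mean = 10000` (sdlog 0.2), typical of deeply sequenced
  plate-based data. The generator does **not** model batch effects,
  doublets, cell-cycle structure or UMI chemistry; passing tests therefore
  demonstrate correctness of the statistics, not robustness to those
  artefacts.
* **Mitochondrial fraction.** Thirteen genes named `mt-*` receive a
  per-cell count share drawn from a Beta distribution with mean
  `mito_fraction_mean = 0.02` and concentration 100, so a small but
  non-trivial tail of cells exceeds the 5% QC threshold and the filter is
  genuinely exercised.
* **Secretome.** Densitometry readings for both conditions carry
  multiplicative log-normal noise (sd 0.1 on the log scale); the planted
  ligand's high/low ratio is centred on `ligand_ratio = 2.5`, all others
  on 1.
* **Determinism.** One master seed; every stage (per-condition sampling,
  secretome, bootstraps) draws from a sub-stream derived by fixed offsets,
  so identical `SimulationTruth` objects give bit-identical outputs and
  sub-experiments are independently reproducible.

## QC and normalization

`filter_matrix` applies four filters in one fixed pass, in this order:
drop listed non-coding genes; drop cells with fewer than 1,000 detected
genes (strictly "less than"); drop genes detected in fewer than 3 of the
surviving cells; drop cells whose mitochondrial **count fraction** exceeds
5%. The order matters and is deliberately fixed (genes are filtered against
the cells that survived the complexity filter); there is no iteration to a
fixpoint, and on well-behaved data a second application removes nothing — a
property the tests assert. The mitochondrial fraction is defined as
mitochondrial counts over total counts, the standard QC meaning; genes are
recognised by the `mt-` prefix unless an explicit list is supplied. A
non-coding gene list must be user-supplied because no annotation source is
bundled; when absent the step is skipped with a warning.

Normalization is `log(1 + count/total * 10000)` in natural log — zeros stay
zero, cell totals are equalised, and doubling every count of a cell changes
nothing.

`select_variable_genes` ranks genes by a binned standardized dispersion:
per-gene dispersion (variance/mean of de-logged expression) is log-scaled
and z-scored within 20 equal-count bins of mean expression, removing the
mean-variance trend without a curve fit; ties break lexicographically so
the selection is deterministic. One degeneracy is worth knowing about: the
generator's two-level rate structure (baseline vs marker_fold) can place
marker genes into *pure* mean bins where within-bin standardization is
uninformative. Real data has a continuum of means, where binning behaves
as intended; the test suite exercises the regime where bins mix marker and
background genes. With the default configuration all genes are retained
anyway (2,000 variable genes of a 2,000-gene universe), so annotation does
not depend on this statistic.

## Annotation

Each cell is Spearman-correlated (midranks for ties) with one reference
profile per type, over the variable genes shared with the reference; the
best-scoring type wins. This reproduces the *role* of reference-based
annotators while simplifying their internals (no per-type quantile
aggregation over replicate reference samples, no iterative fine-tuning):
the downstream statistics need labels, not a specific third-party
implementation, and an accuracy gate (>= 95% on unpruned cells under the
default marker strength) protects the simplification.

Confidence in the top match uses a chi-squared outlier construction:

> T = ((best - median(others)) / (1.4826 * MAD(others)))^2,  p = P(chi2_1 > T)

Cells are *pruned* — excluded from proportions and differential
expression — when `p >= 0.05`, when best and second scores tie (broken
lexicographically by type name so results are deterministic), or when the
correlation is undefined (a constant expression vector). When the MAD of
the non-top scores is zero their standard deviation substitutes; if that is
also zero the statistic degenerates and we resolve it by construction: a
top score strictly above the (constant) rest is a perfect outlier (p = 0),
all-equal scores give p = 1. Spearman scoring makes the whole stage
invariant to monotone transforms of a cell's expression, and permuting
reference rows never changes an assignment.

## The BCa proportion test

For each cell type the per-condition membership indicators of unpruned
cells form two independent binary samples; the statistic is the difference
in proportions, theta = p_high - p_low. Cells are resampled with
replacement within each condition; for binary data this is exactly a
binomial draw, which is how the replicates are generated (O(B) rather than
O(B n), distributionally identical). The bias correction is

> z0 = Phi^-1( (#{theta* < theta} + 0.5 #{theta* = theta}) / B )

with the half-count tie convention needed for discrete proportions. The
acceleration is the standard jackknife skewness over delete-one replicates
of both samples, a = sum(d^3) / (6 (sum(d^2))^{3/2}); for binary data the
leave-one-out statistic takes at most four distinct values, so it is
computed in closed form. Interval endpoints are the BCa-adjusted
percentiles of the sorted replicates (order statistic at `ceiling(p*B)`,
with a 1e-9 guard so exact grid points do not fall victim to floating
point). Forcing `z0 = 0, a = 0` reduces the interval exactly to the
percentile bootstrap — an oracle equivalence the tests assert.

The one-sided p-value inverts the confidence bound: it is the smallest
level alpha' at which the one-sided BCa bound excludes zero, found by
bisection to 1e-4 over [1/B, 0.5]. When even the 50% bound fails to
exclude zero the p-value is reported as 1 (the search range cannot resolve
(0.5, 1), and no decision at conventional levels is affected). A
degenerate bootstrap (all replicates identical) floors the p-value at 1/B
when the observed difference has the tested sign and sets it to 1
otherwise, with a flag recorded. With B = 10,000 (the default) the
attainable floor is 1e-4, which is the resolution at which strong shifts
such as the planted MDP enrichment are reported. Each type is tested
marginally with no cross-type correction, matching per-population
reporting conventions; a BH column is available but off by default.

Monte-Carlo checks in the acceptance suite hold the one-sided type-I error
of this construction within [0.03, 0.07] at nominal 0.05 (500 null
simulations, n = 300 per condition, B = 2,000) and show >= 90% power for a
0.10 vs 0.25 shift at the same sizes.

## Differential expression and the fold-change convention

Within one annotated type, genes are first restricted to those detected in
at least 10% of cells in either condition *and* showing at least a 1.2-fold
difference in either direction; only the surviving genes are tested
(Wilcoxon rank-sum) and BH adjustment runs across that surviving set only.
This filter-then-test order is deliberate and matches the convention the
pipeline reproduces. Its statistical price is worth stating: because the
fold-change prefilter selects genes with extreme observed differences, the
subsequent test on the *same* cells is anti-conservative when groups are
small (tens of cells), and spurious "significant" genes appear. With ~300
cells per group the 1.2-fold threshold sits several standard errors from
the null and the effect vanishes — which is why the axis-recovery checks
run at that size, and why small-group DE output should be read as a
candidate list rather than an inferential claim.

The fold change is computed on de-logged normalized means with a unit
pseudocount, FC = (mean(expm1(high)) + 1) / (mean(expm1(low)) + 1) — the
convention of the standard single-cell toolchain; "at least 1.2-fold" is
read two-sided (FC >= 1.2 or <= 1/1.2). The pseudocount guards empty
denominators and shrinks fold changes of weakly expressed genes toward 1,
so planted effects are recovered slightly conservatively.

`wilcoxon_rank_sum` uses the exact null distribution of the Mann-Whitney U
statistic when the pooled sample has at most 12 observations without ties
(two-sided p as twice the smaller tail, capped at 1), and otherwise a
normal approximation with tie-corrected variance and continuity
correction. The exact branch is verified against brute-force enumeration
of all rank splits; the normal branch holds its size within
[0.035, 0.065] at n = 40 per group in simulation. `bh_adjust` validates
its input and applies the standard step-up rule; it is checked against a
hand-rolled implementation on random vectors.

## Pairing and ranking

Secretome ratios (high/low densitometry, recomputed and sorted) are joined
to receptors through an explicit ligand-receptor table — naming lives only
in that table, never in string heuristics; receptor symbols match
case-insensitively. An axis (ligand, receptor, cell type) is emitted when
the ligand ratio strictly exceeds 1, the pair is listed, and the receptor
is significantly *up* (FC > 1, BH-adjusted p < 0.05) in that cell type.
The receptor gate is one-sided on purpose — the search is for up-regulated
ligands meeting up-regulated receptors — while the DE prefilter remains
two-sided.

Ranking is lexicographic over the three reported keys in their reported
order: descending ligand ratio, then descending receptor fold change, then
ascending adjusted p. A single composite score was the main open design
alternative; lexicographic ordering was chosen because it is parameter-free
and reproduces a reading of "ranked by A, B and C" that needs no weights.
Remaining ties break on ligand, receptor and cell-type names, making ranks
a deterministic permutation.

## Problem sizes, test design and limitations

The test suite runs entirely on generated data. Unit tests use a compact
configuration (4 types, 300 genes, 150 cells per condition) chosen to keep
the full suite around a few minutes on one core; the statistical
acceptance checks use the sizes stated with each check (500/200 bootstrap
calibration simulations, 50 axis-recovery seeds at ~300 cells per type per
condition with `receptor_fold = 1.5`, and a null arm with all effects at 1
that must produce an empty ranking in >= 90% of seeds). The two checks
that replay the QC and MDP differential-expression path on the original
study's own expression matrix require that matrix locally (under
`inst/extdata/study_lsk/`); it is not redistributed with the package, so
those checks report failure with instructions until it is supplied.

Known limitations: the annotation stage assumes one reference profile per
type on a comparable normalized scale; compositional effects (one type's
enrichment necessarily depleting others) are tested marginally, not
jointly; the generator's two-level rate structure is a simplification of
real expression continua; and a third (`naive`) condition is supported by
the schema and the generator but not exercised by any acceptance check.
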