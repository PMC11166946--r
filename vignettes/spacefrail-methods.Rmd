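---
title: "Methods: frailty, sarcopenia and metabolic flux screening in spaceflight omics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: frailty, sarcopenia and metabolic flux screening in spaceflight omics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spacefrail)
```

`spacefrail` re-implements, as a reusable and tested pipeline, a family of
analyses that screen spaceflight transcriptomics for signatures of aging,
frailty and sarcopenia: biomarker-level differential-expression filtering
with cross-species translation, frailty-pathway gene-set enrichment, a
sarcopenia-predictor discovery procedure, a context-specific metabolic flux
simulation, and time-course / single-cell summaries of a frailty gene panel.
This vignette documents the models, the tunable parameters, the numerical
choices, and what the bundled synthetic data can and cannot show.

## Frailty biomarkers, ortholog translation and overlap partitions

The package bundles a curated frailty biomarker table (human and mouse
symbols with Ensembl identifiers; `frailty_biomarkers()`). Ortholog
translation (`map_orthologs()`) is an exact, case-sensitive symbol lookup in
that table — deliberately static: no live database queries, so results are
reproducible offline.

`filter_frailty_degs()` retains differential-expression records whose gene
is a biomarker for the record's species and whose adjusted p-value is
*strictly* below the cutoff. The default cutoff is 0.5 — a deliberately
permissive screen for biomarker-level exploration rather than a genome-wide
discovery threshold. Duplicate gene records within a dataset keep the
smallest adjusted p, which is deterministic and favors the strongest
evidence.

`overlap_partition()` enumerates the disjoint compartments of any family of
named gene sets (the cells of a Venn/upset plot), and
`partition_percentages()` converts compartment counts to integer
percentages. Two numerical choices matter here:

* the **denominator** is the sum of the disjoint compartment counts (the
  size of the union). A nominal total stated elsewhere can be recorded via
  `nominal_total` and is echoed in the output attributes but never used: on
  the reference partition of 22 shared / 43 mouse-only / 4 human-only genes,
  the printed percentages (32/62/6) are consistent with denominator 69, not
  with the nominal 73, so the discrepancy is surfaced rather than resolved;
* rounding is **half-up** to whole percent, which reproduces all three
  reference values exactly.

## Gene-set enrichment

`gsea_enrichment()` scores a gene set on a ranked list (genes sorted by a
signed statistic such as the per-gene t-score, ties broken by symbol so the
ranking is deterministic; `rank_genes()`). The enrichment score (ES) is the
signed maximum-magnitude deviation of a weighted running sum: set members
increment it by $|s|^w / \sum_{set} |s|^w$, non-members decrement it by
$1/(N-k)$. Only positions adjacent to set members can be the extremum, so
the score is computed from the $k$ hit positions directly. On an exact tie
between the positive and negative extremum the positive one is reported.

The null is a *gene-label permutation*: per permutation, $k$ genes are drawn
uniformly without replacement and rescored. This matches tools that operate
on a single pre-ranked list (sample-label permutation would require the
expression matrix, which this stage deliberately does not consume). The
normalized score is $NES = ES / \mathrm{mean}(|ES_{perm}|)$ over
*same-sign* permutations, and
$p = (1 + \#\{\text{same-sign } |ES_{perm}| \ge |ES|\}) / (1 + \#\text{same-sign})$.
When no same-sign permutation exists, NES and p are reported missing and
excluded from the Benjamini-Hochberg adjustment — mirroring missing-value
cells in cross-dataset summaries rather than fabricating a score. The
permutation count and the weighting exponent are free choices (defaults:
`n_perm` as requested, `weight = 1`); one permutation pool is shared per
distinct set size, which is standard and makes 500-set runs cheap.

The leading edge is reported positionally: members at or before the maximum
for positive ES, at or after the minimum for negative ES, so it is always a
subset of the set's ranked members on the side that drives the signal.

Pathway collections are filtered by `select_frailty_pathways()`: a set
qualifies as a putative frailty pathway when it contains at least two
biomarker genes (`min_hits = 2`) — one shared gene is weak evidence of a
phenotype link; two or more genes that can interact within one pathway is
the operational criterion. Direction summaries (`direction_summary()`) use a
reporting cut of adjusted p < 0.3 by default, the exploratory threshold used
for heatmap-level reporting; it is configurable.

## The sarcopenia-predictor screen

Four stages, each exposed separately:

1. **`mwu_screen()`** — per-gene two-sided Mann-Whitney U tests. With
   $n_1 + n_2 \le 16$ and no ties the p-value is exact (full enumeration of
   the U null); otherwise the tie-corrected normal approximation with
   continuity correction is used. The DEG call uses unadjusted p < 0.05 by
   default (BH-adjusted values are always reported alongside so users can
   tighten).
2. **`mas_score()`** — the Mean Accuracy Score: repeated stratified
   cross-validation (defaults k = 5 neighbors, 5 folds, 20 repeats) of a
   one-dimensional k-nearest-neighbor classifier on a single gene,
   neighbors by absolute difference of the gene value. Distance ties break
   toward the smaller training index and vote ties toward the training-fold
   majority class (then the lexicographically smaller label), so the score
   is fully deterministic given a seed. The score is exactly invariant
   under positive affine transforms of the gene; it is *not* invariant
   under arbitrary monotone transforms — no metric 1-D classifier is,
   because a nonlinear monotone map can change which side of a query is
   metrically closer. We treat the affine property as the testable
   invariance and document the general case as a known limitation.
3. **`detect_modules()`** — a deliberately simplified weighted-correlation
   workflow: dissimilarity $1 - |r|^{power}$ (default power 6),
   average-linkage hierarchical clustering cut at a fixed height (default
   0.9 in dissimilarity units), clusters below `min_module_size` pooled as
   "unassigned". With power 6, a planted module at within-module correlation
   0.8 sits at dissimilarity ~0.74 while noise pairs sit near 1.0, so the
   fixed cut separates them robustly. The module eigengene is the first
   right singular vector of the per-gene standardized submatrix (zero mean
   by construction), sign-oriented to correlate positively with mean module
   expression, and is correlated with the trait by Pearson correlation.
   Full dynamic tree cutting and topological-overlap matrices are out of
   scope: the fixed-cut variant is deterministic, testable, and sufficient
   for the procedure's role — selecting the most trait-correlated module.
4. **`overrepresentation_curate()`** — one-sided hypergeometric
   over-representation of the candidate genes per term (terms restricted to
   the screened universe), BH adjustment, and a panel defined as the
   conjunction of (a) membership in at least one enriched term and (b)
   MAS strictly above 0.65. The two filters compose; their order is
   irrelevant.

## Context-specific metabolic flux simulation

The flux module runs per sample:

1. **`reaction_expression()`** evaluates each reaction's gene-reaction rule
   with AND = minimum and OR = maximum of the operand expression levels.
   Genes missing from the expression vector score 0 and reactions without a
   rule receive the median of the scored reactions, so unannotated
   reactions are neither promoted nor demoted.
2. **`assign_confidence_tiers()`** ranks reactions by score (ties broken by
   reaction id) and splits them by a fraction triple $(f_3, f_2, f_1)$ —
   half-up rounding, so $(0.55, 0.25, 0.20)$ over 20 reactions gives tier
   sizes $(11, 5, 4)$. Reactions tagged with an essential pathway
   (`essential_pathways()`: glycolysis/gluconeogenesis, CoA synthesis and
   catabolism, NAD metabolism, fatty-acid synthesis and oxidation, biomass
   and maintenance) are promoted to tier 3 afterwards for model stability.
   Oxidative phosphorylation and the citric-acid cycle are deliberately
   *not* essential, so mitochondrial dysregulation can express itself in
   the comparisons.
3. **`extract_context_model()`** is a simplified, deterministic
   tier-driven extraction (a documented variant, not a re-implementation of
   published dependency-assessment algorithms): the retained set starts
   from tier-3 plus all exchange reactions; each retained non-exchange
   reaction is maximized over the *full* model and every lower-tier
   reaction carrying flux above `epsilon` (default 1e-6) in that optimum
   joins the set; passes repeat to closure. Because the support LPs are
   solved on the full model, each reaction's support set is a fixed
   property of the model and is cached. Enlarging tier 3 can only enlarge
   the retained set (monotonicity). Retained tier-3 reactions that cannot
   carry flux in the final submodel are reported as blocked.
4. **`compute_flux_levels()`** adds a sink draining `nad_c` when absent,
   maximizes it first (the NAD optimum), then constrains the sink to at
   least 90% of that optimum and maximizes every reaction in turn; each
   reaction's flux level is its own maximum (a flux-variability maximum,
   which resolves alternate optima deterministically). The 0.9 factor — a
   configurable `sink_factor` — keeps the model strictly feasible under
   solver tolerance rather than pinning the sink exactly at its optimum.
   Every LP solution is asserted to satisfy steady state within 1e-6.
5. **`select_confidence_fractions()`** runs the whole per-sample pipeline
   per candidate triple and picks the one minimizing the summed
   within-group standard deviation of flux levels (over reactions present
   in all samples of a group); ties go to the larger tier-3 fraction. The
   default grid holds the two published working points, (0.55, 0.25, 0.20)
   and (0.45, 0.40, 0.15).
6. **`compare_flux_groups()`** applies the Van der Waerden normal-scores
   test per reaction — average ranks on ties,
   $A_i = \Phi^{-1}(R_i/(N+1))$, $T = \sum_j n_j \bar A_j^2 / s^2$ against
   $\chi^2_{g-1}$ — chosen because neither normality nor equal variance can
   be assumed between flight and ground flux levels. Significance classes
   at p < 0.05 and 0.05 ≤ p < 0.1 follow the reporting convention of the
   heatmaps this feeds; flux rows are also standardized to z-scores
   (constant rows map to zero).

Tiering uses each sample's own expression (per-sample context models); the
group-level variability criterion then acts across samples. This is one of
two defensible readings of the procedure and is surfaced as the documented
behavior; the alternative (per-condition tiering) can be emulated by
passing group-averaged expression.

Linear programming is done by a small dense bounded-variable two-phase
primal simplex written for this package (Bland's rule, hence cycling-free
and fully deterministic). Problems here are tens of variables, where a dense
deterministic solver is preferable to an external dependency; any solver
returning certified optimal basic solutions could be substituted, and every
returned solution is checked against steady state and bounds at 1e-6.

## Time-course and single-cell summaries

`summarize_timecourse()` averages expression across subjects per timepoint
and pools the three pre-flight timepoints into one baseline column (changes
leading up to launch are treated as part of the baseline).
`classify_trajectories()` turns the qualitative notions "reduced during
spaceflight", "increased after re-entry" and "did not return to baseline"
into operational calls with a relative threshold `delta` (default 0.2):
in-flight and post-flight directions compare phase means against
$baseline(1 \pm \delta)$, and return-to-baseline checks only the *final*
post-flight value against $\delta \cdot baseline$. When a baseline is not
positive the same `delta` applies as an absolute difference. At `delta = 0`
any nonzero deviation is called; as `delta` grows everything becomes
stable/returned.

`summarize_singlecell()` normalizes each cell to the median library size,
applies log1p, and reports per (gene, cell type, timepoint) the mean
normalized expression and the percentage of expressing cells. The first
post-return timepoint (R+1) is treated as the spaceflight condition; later
post-flight timepoints are summarized but not classed. A gene is classed
increased/decreased per cell type when the log2 fold change of the
normalized means (with a pseudocount of 1) clears ±0.25 and the gene is
expressed in at least 10% of cells in either condition — the usual dot-plot
gates, both configurable. Panel and background class percentages are
computed so they sum to exactly 100.

## Synthetic data: what it emulates, and what it does not

All pipeline inputs can be generated with known planted truth; generators
are pure functions of their parameters and a seed (the caller's RNG state
is untouched, identical calls are bit-identical).

* `generate_bulk()` — Gaussian log-scale expression with a planted
  group-mean shift for a chosen fraction of genes. Gaussian noise is
  appropriate because every in-scope stage consumes normalized or
  aggregated values, not raw counts; rank tests and correlations stay
  well-behaved.
* `generate_sarcopenia_cohort()` — a latent-factor module (unit loadings,
  noise variance $(1-\rho)/\rho$ so the expected within-module correlation
  equals the target exactly), a continuous trait tracking the factor,
  balanced trait classes and planted single-gene predictors. Defaults are
  a 118-sample cohort (59 per class), mirroring the scale of the sarcopenia
  cohort this procedure was designed around.
* `generate_toy_metabolic_experiment()` — the fixed 17-metabolite,
  25-reaction network of `toy_metabolic_model()` (its NAD route capacity
  equals the uptake bound of 10, so the sink optimum is hand-checkable),
  with per-group expression over its 21 genes. In `tier-driven` mode the
  gene of a dedicated pyruvate secretion branch is high in flight and low
  in ground; the branch was placed outside the support closure of the
  always-retained core precisely so its retention is decided by tier
  assignment alone, making `PYRWASTE`/`EX_waste` the designed
  differential reactions. The model is small by design so hand-derived LP
  optima remain valid fixtures.
* `generate_timecourse_and_singlecell()` — six astronauts, three
  pre-flight/three in-flight/three post-flight timepoints, and per-gene
  trajectory classes (down-then-recovered, down-throughout, stable,
  persistent post-flight offset); plus over-dispersed negative-binomial
  single-cell counts (fixed dispersion 0.5 — a minimal over-dispersion
  model, adequate for percent-expressing and mean summaries) across four
  cell types with a planted post-flight shift in a quarter of genes.

These generators do **not** emulate read-level noise, batch effects,
doublets or ambient RNA, cell-type annotation uncertainty, or the
dependence structure of real regulatory networks. Passing recovery tests
therefore demonstrates that each procedure recovers the structure it is
designed to detect under its stated noise model — not that the procedure is
robust to every artifact of real spaceflight omics.

## Problem sizes and calibration checks

The suite and the acceptance script run everything at desk scale, chosen so
each check is statistically meaningful: 1000-gene cohorts with 20 samples
per group for type-I/power checks of the screen; 200-gene / 118-sample
cohorts for module recovery; 500 null sets at 500 permutations for
enrichment p-value uniformity (Kolmogorov-Smirnov distance below 0.1); 200
seeded replicates of the null toy flux experiment for the Van der Waerden
level (measured over reactions whose pooled flux levels actually vary —
constant rows give T = 0, p = 1 by definition and carry no information
about the test's level); and 50 seeded replicates for planted flux-shift
power. Null-level bands use the binomial noise implied by those counts.

## Known limitations

* The biomarker mapping covers the bundled curated table only; symbols
  absent from it are reported unmapped rather than guessed.
* Tier extraction is a simplified deterministic variant; it preserves the
  role of confidence-driven context subsetting but not the stochastic
  internals of published dependency-assessment algorithms.
* Flux levels are per-reaction maxima under the NAD-sink constraint;
  quantities such as flux distributions over alternate optima, loopless
  constraints, or thermodynamic feasibility are out of scope.
* The single-cell classification is a threshold rule on normalized means,
  not a differential-expression model; it is intended for dot-plot-level
  panel summaries. The pseudocount of 1 in the fold change compresses
  signals for weakly expressed genes — at small library sizes a planted
  two-fold shift in a gene with mean well below one count can fall under
  the 0.25 log2 gate, so recall of planted shifts is systematically lower
  for the least-expressed panel members.
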