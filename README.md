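# spacefrail

Spaceflight compresses several hallmarks of aging into weeks: muscle
wasting, immune dysregulation, altered metabolism. `spacefrail` is an R
package for screening transcriptomic data — rodent and human, bulk,
cell-free RNA time courses and single-cell — for signatures of **frailty**
(a geriatric syndrome of depleted physiological reserve, proxied by a
curated biomarker gene list) and **sarcopenia** (age-related loss of muscle
mass and quality). It is written for researchers who analyze spaceflight
omics repositories and want the full analysis chain as reusable, tested
functions with synthetic data for every input.

## What it computes

* **Biomarker overlap** — filter differential-expression tables to frailty
  biomarkers under a strict adjusted-p cutoff (`padj < 0.5`), translate
  symbols between human and mouse with a bundled static ortholog table, and
  partition gene sets into disjoint Venn/upset compartments with integer
  percentages (`filter_frailty_degs()`, `map_orthologs()`,
  `overlap_partition()`, `partition_percentages()`).
* **Gene-set enrichment** — weighted running-sum enrichment scores on a
  t-score-ranked gene list; gene-label permutation null; normalized scores
  `NES = ES / mean(|same-sign permuted ES|)`; BH adjustment; leading-edge
  genes; frailty-pathway selection by a two-biomarker membership rule
  (`rank_genes()`, `gsea_enrichment()`, `select_frailty_pathways()`).
* **Sarcopenia screen** — per-gene Mann–Whitney U tests (exact by
  enumeration for small tie-free samples), single-gene k-nearest-neighbor
  Mean Accuracy Scores under repeated stratified cross-validation,
  co-expression modules with eigengene–trait correlation, and a curated
  panel by hypergeometric over-representation plus `MAS > 0.65`
  (`mwu_screen()`, `mas_score()`, `detect_modules()`,
  `overrepresentation_curate()`).
* **Metabolic flux simulation** — a context-specific constraint-based
  workflow: gene-reaction rules (AND = min, OR = max) score reactions from
  each sample's expression; reactions are split into confidence tiers 3/2/1
  by fraction triples such as (55%, 25%, 20%); essential pathways are always
  activated; a context model is extracted by deterministic support passes;
  an NAD sink is optimized first and every reaction is then maximized in
  turn; groups are compared with the Van der Waerden normal-scores test,
  `T = Σ n_j·Ā_j² / s²` with `A_i = Φ⁻¹(R_i/(N+1))`, against chi-square
  (`run_flux_pipeline()`, `compare_flux_groups()`,
  `select_confidence_fractions()`).
* **Time-course and single-cell summaries** — astronaut series averaged per
  timepoint with a pooled three-timepoint pre-flight baseline, trajectory
  calls (down in flight, recovered after re-entry, persistent offsets), and
  per-cell-type increased/decreased/stable percentages of a gene panel at
  R+1 versus pre-flight (`summarize_timecourse()`,
  `classify_trajectories()`, `summarize_singlecell()`).
* **Synthetic data** — generators with planted truth for every input:
  two-group bulk cohorts, a sarcopenia cohort with a latent-factor module,
  a fixed 25-reaction toy metabolic network with a designed flight/ground
  flux difference, astronaut time courses and over-dispersed single-cell
  counts (`generate_*()`, `toy_metabolic_model()`).

## Worked example

Cross-species overlap percentages from a printed partition (22 genes shared
between mice and humans, 43 mouse-only, 4 human-only):

```r
library(spacefrail)
partition_percentages(c(shared = 22, mouse_only = 43, human_only = 4),
                      nominal_total = 73)
#>     shared mouse_only human_only
#>         32         62          6
#> attr(,"denominator")
#> [1] 69
#> attr(,"nominal_total")
#> [1] 73
```

A third of the differentially expressed frailty genes are shared across
species; the percentages are computed over the 69 genes in the disjoint
compartments (the externally stated total of 73 is echoed, not used).

Flux simulation on the toy network with a planted flight/ground difference:

```r
ex <- generate_toy_metabolic_experiment(n_per_group = 5,
                                        flux_shift_mode = "tier-driven",
                                        seed = 1)
profile <- run_flux_pipeline(ex$model, ex$expression, ex$group_labels)
cmp <- compare_flux_groups(profile)
head(cmp$table[order(cmp$table$pvalue), c("reaction", "vdw_statistic",
                                          "pvalue", "class")], 3)
#>    reaction vdw_statistic      pvalue  class
#> 21 EX_waste    9.00000000 0.002699796 p<0.05
#> 9    EX_cit    1.03981485 0.307864538     ns
#> 10     ATPM    0.03999146 0.841497276     ns
```

The planted secretion branch is retained in flight (its gene is highly
expressed there) and removed from the ground context models, so its exchange
reaction carries flux 2 in flight and 0 on ground — the Van der Waerden test
flags exactly that reaction at p < 0.05.

The whole pipeline — synthetic inputs through every stage — runs from one
config and is byte-identical across runs with the same seed:

```r
run_pipeline(default_pipeline_config(seed = 1), "out/")
```

A command-line wrapper with subcommands (`simulate`, `overlap`, `gsea`,
`sarcopenia`, `flux`, `timecourse`, `sc-summary`, `pipeline`) is installed at
`inst/scripts/spacefrail`.

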