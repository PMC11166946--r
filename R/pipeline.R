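# End-to-end orchestration: synthetic inputs -> overlap -> enrichment ->
# sarcopenia screen -> flux simulation -> time-course / single-cell
# summaries, driven by one YAML config and one seed.

#' Differential-expression table from a two-group cohort
#'
#' Per gene: log2 fold change of group means, Mann-Whitney p-value, BH
#' adjusted p, and the Welch t statistic as the ranking t-score.
#'
#' @param cohort A `bulk_cohort` (or any list with `expression` and
#'   `group_labels`).
#' @param dataset,species,tissue Tags recorded on each record.
#' @return A DEG data frame (see [read_de_table()]).
#' @export
cohort_de_table <- function(cohort, dataset = "synthetic", species = "human",
                            tissue = "synthetic") {
  expr <- cohort$expression
  g <- as.factor(cohort$group_labels)
  assert_that(nlevels(g) == 2, "cohort must have two groups")
  a <- g == levels(g)[1]; b <- g == levels(g)[2]
  screen <- mwu_screen(expr, cohort$group_labels)
  tscore <- vapply(rownames(expr), function(gn) {
    unname(stats::t.test(expr[gn, b], expr[gn, a])$statistic)
  }, numeric(1))
  data.frame(gene = rownames(expr),
             log2fc = rowMeans(expr[, b, drop = FALSE]) -
               rowMeans(expr[, a, drop = FALSE]),
             pvalue = screen$pvalue,
             padj = screen$padj,
             tscore = tscore,
             dataset = dataset, species = species, tissue = tissue,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Random gene-set collection over a universe; a requested number of sets is
# guaranteed to contain >= 2 symbols from `anchor` (used to emulate frailty
# pathway collections).
random_gene_sets <- function(universe, n_sets = 20, size_range = c(10, 40),
                            anchor = character(0), n_anchored = 5, seed = 1) {
  with_seed(seed, {
    sets <- lapply(seq_len(n_sets), function(i) {
      size <- sample(seq(size_range[1], size_range[2]), 1)
      s <- sample(universe, size)
      if (i <= n_anchored && length(anchor) >= 2) {
        s <- unique(c(sample(anchor, 2), s))
      }
      s
    })
    names(sets) <- sprintf("PATHWAY_%02d", seq_len(n_sets))
    class(sets) <- "gene_set_collection"
    sets
  })
}

#' Default pipeline configuration
#'
#' @param seed Integer seed recorded in the config.
#' @return Nested list mirroring the YAML config schema of
#'   [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1) {
  list(
    seed = seed,
    simulate = list(
      bulk = list(n_genes = 300, n_per_group = 10, de_fraction = 0.1,
                  effect = 2, noise_sd = 1),
      sarcopenia = list(n_genes = 120, n_per_group = 20, module_size = 25,
                        module_cor = 0.8, n_predictors = 4,
                        predictor_shift = 2),
      metabolic = list(n_per_group = 5, flux_shift_mode = "tier-driven"),
      timecourse_singlecell = list(n_genes = 24, n_astronauts = 6,
                                   n_cells_per_type = 60, shift_log2fc = 1)
    ),
    overlap = list(padj_cutoff = 0.5),
    gsea = list(n_perm = 500, weight = 1, min_hits = 2, padj_cut = 0.3),
    sarcopenia = list(k = 5, folds = 5, repeats = 5, mas_threshold = 0.65,
                      power = 6, cut_height = 0.9, min_module_size = 10),
    flux = list(fractions = c(0.55, 0.25, 0.20), sink_factor = 0.9,
                nad_id = "nad_c"),
    timecourse = list(delta = 0.2),
    sc_summary = list(lfc_threshold = 0.25, min_pct = 10)
  )
}

#' Run the full pipeline from one config
#'
#' Generates every synthetic input, then runs overlap filtering, gene-set
#' enrichment, the sarcopenia screen, the flux simulation and the
#' time-course / single-cell summaries, writing delimited-text outputs to
#' `outdir`. Fully deterministic in (config, seed): two runs with the same
#' config produce byte-identical files.
#'
#' @param config Config list (see [default_pipeline_config()]) or path to a
#'   YAML file with the same structure.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = default_pipeline_config(), outdir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(outdir, ...)
  num <- function(x) format(x, digits = 12, scientific = FALSE, trim = TRUE)

  bm <- frailty_biomarkers()

  # -- simulate ----------------------------------------------------------
  sim <- config$simulate
  bulk_h <- do.call(generate_bulk, c(sim$bulk, list(seed = child_seed(seed, 1))))
  bulk_m <- do.call(generate_bulk, c(sim$bulk, list(seed = child_seed(seed, 2))))
  # overlay biomarker symbols on the leading genes of each cohort so the
  # biomarker filter has material to work with
  rownames(bulk_h$expression)[seq_len(nrow(bm))] <- bm$human_symbol
  bulk_h$truth_de_genes <- rownames(bulk_h$expression)[
    match(bulk_h$truth_de_genes, sprintf("gene%04d", seq_len(nrow(bulk_h$expression))))]
  rownames(bulk_m$expression)[seq_len(nrow(bm))] <- bm$mouse_symbol
  bulk_m$truth_de_genes <- rownames(bulk_m$expression)[
    match(bulk_m$truth_de_genes, sprintf("gene%04d", seq_len(nrow(bulk_m$expression))))]
  sarco <- do.call(generate_sarcopenia_cohort,
                   c(sim$sarcopenia, list(seed = child_seed(seed, 3))))
  metab <- do.call(generate_toy_metabolic_experiment,
                   c(sim$metabolic, list(seed = child_seed(seed, 4))))
  tcsc <- do.call(generate_timecourse_and_singlecell,
                  c(sim$timecourse_singlecell,
                    list(seed = child_seed(seed, 5))))

  de_h <- cohort_de_table(bulk_h, dataset = "synthetic_human", species = "human")
  de_m <- cohort_de_table(bulk_m, dataset = "synthetic_mouse", species = "mouse")
  write_de_table(de_h, out("de_human.tsv"))
  write_de_table(de_m, out("de_mouse.tsv"))
  write_expression_matrix(sarco$expression, out("sarcopenia_expression.tsv"))
  write_model_json(metab$model, out("toy_model.json"))
  write_expression_matrix(metab$expression, out("metabolic_expression.tsv"))

  # -- overlap -----------------------------------------------------------
  padj_cutoff <- config$overlap$padj_cutoff %||% 0.5
  deg_h <- filter_frailty_degs(de_h, bm, padj_cutoff = padj_cutoff)
  deg_m <- filter_frailty_degs(de_m, bm, padj_cutoff = padj_cutoff)
  mouse_as_human <- map_orthologs(deg_m$gene, bm, "mouse_to_human")$mapped
  partition <- overlap_partition(list(human = deg_h$gene,
                                      mouse = mouse_as_human))
  pct <- partition_percentages(partition)
  overlap_tab <- data.frame(compartment = names(partition$counts),
                            count = as.integer(partition$counts),
                            percent = as.integer(pct),
                            stringsAsFactors = FALSE)
  utils::write.table(overlap_tab, out("overlap_partition.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # -- gsea --------------------------------------------------------------
  gcfg <- config$gsea
  ranked <- rank_genes(de_h$gene, de_h$tscore)
  sets <- random_gene_sets(de_h$gene, anchor = bm$human_symbol,
                           seed = child_seed(seed, 6))
  write_gmt(sets, out("gene_sets.gmt"))
  frailty_sets <- select_frailty_pathways(sets, bm$human_symbol,
                                          min_hits = gcfg$min_hits %||% 2)
  gsea <- gsea_enrichment(ranked, frailty_sets, weight = gcfg$weight %||% 1,
                          n_perm = gcfg$n_perm %||% 500,
                          seed = child_seed(seed, 7))
  gsea_out <- gsea[, c("set", "size", "es", "nes", "pvalue", "padj")]
  gsea_out$leading_edge <- vapply(gsea$leading_edge, paste, character(1),
                                  collapse = ",")
  for (cl in c("es", "nes", "pvalue", "padj")) gsea_out[[cl]] <- num(gsea_out[[cl]])
  utils::write.table(gsea_out, out("gsea_results.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  dirsum <- direction_summary(gsea, padj_cut = gcfg$padj_cut %||% 0.3)

  # -- sarcopenia screen -------------------------------------------------
  scfg <- config$sarcopenia
  screen <- mwu_screen(sarco$expression, sarco$group_labels)
  deg_genes <- screen$gene[screen$is_deg]
  modules <- detect_modules(sarco$expression[deg_genes, , drop = FALSE],
                            power = scfg$power %||% 6,
                            min_module_size = scfg$min_module_size %||% 10,
                            cut_height = scfg$cut_height %||% 0.9,
                            trait = sarco$trait)
  real_modules <- Filter(function(m) !m$unassigned, modules)
  best_module <- if (length(real_modules) > 0) {
    real_modules[[which.max(vapply(real_modules,
                                   function(m) abs(m$trait_cor), numeric(1)))]]
  } else NULL
  candidates <- if (is.null(best_module)) deg_genes else best_module$genes
  mas <- vapply(candidates, function(gn) {
    mas_score(sarco$expression[gn, ], sarco$group_labels,
              k = scfg$k %||% 5, folds = scfg$folds %||% 5,
              repeats = scfg$repeats %||% 5,
              seed = child_seed(seed, 8))$mas
  }, numeric(1))
  terms <- random_gene_sets(rownames(sarco$expression), n_sets = 10,
                            size_range = c(8, 25),
                            anchor = candidates,
                            n_anchored = 4, seed = child_seed(seed, 9))
  names(terms) <- sprintf("GO_TERM_%02d", seq_along(terms))
  curation <- overrepresentation_curate(
    candidates, rownames(sarco$expression), terms, mas,
    mas_threshold = scfg$mas_threshold %||% 0.65)
  screen_out <- screen
  for (cl in c("u_statistic", "pvalue", "padj")) screen_out[[cl]] <- num(screen_out[[cl]])
  utils::write.table(screen_out, out("sarcopenia_screen.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  mas_tab <- data.frame(gene = names(mas), mas = num(mas),
                        stringsAsFactors = FALSE)
  utils::write.table(mas_tab, out("sarcopenia_mas.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  panel_tab <- data.frame(gene = curation$panel, stringsAsFactors = FALSE)
  utils::write.table(panel_tab, out("sarcopenia_panel.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # -- flux --------------------------------------------------------------
  fcfg <- config$flux
  profile <- run_flux_pipeline(metab$model, metab$expression,
                               metab$group_labels,
                               fractions = unlist(fcfg$fractions %||%
                                                    c(0.55, 0.25, 0.20)),
                               nad_metabolite = fcfg$nad_id %||% "nad_c",
                               sink_factor = fcfg$sink_factor %||% 0.9)
  comparison <- compare_flux_groups(profile)
  flux_mat <- profile$flux_levels
  flux_df <- data.frame(reaction = rownames(flux_mat),
                        apply(flux_mat, 2, num),
                        check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(flux_df, out("flux_levels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cmp_out <- comparison$table
  cmp_out$vdw_statistic <- num(cmp_out$vdw_statistic)
  cmp_out$pvalue <- num(cmp_out$pvalue)
  utils::write.table(cmp_out, out("flux_comparison.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  z_df <- data.frame(reaction = rownames(comparison$zscores),
                     apply(comparison$zscores, 2, num),
                     check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(z_df, out("flux_zscores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # -- timecourse / single cell -----------------------------------------
  tc <- summarize_timecourse(tcsc$timecourse$values, tcsc$timecourse$labels)
  calls <- classify_trajectories(tc, delta = config$timecourse$delta %||% 0.2)
  tc_df <- data.frame(gene = rownames(tc$values), apply(tc$values, 2, num),
                      check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tc_df, out("timecourse_matrix.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(calls, out("timecourse_calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sc <- tcsc$singlecell
  panel <- sc$truth_shifted_genes
  scs <- summarize_singlecell(sc$counts, sc$cell_type, sc$timepoint,
                              panel = panel,
                              lfc_threshold = config$sc_summary$lfc_threshold %||% 0.25,
                              min_pct = config$sc_summary$min_pct %||% 10)
  per_tp <- scs$per_timepoint
  per_tp$mean_expression <- num(per_tp$mean_expression)
  per_tp$pct_expressing <- num(per_tp$pct_expressing)
  utils::write.table(per_tp, out("sc_per_timepoint.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cls <- scs$classes
  cls$log2fc <- num(cls$log2fc)
  utils::write.table(cls, out("sc_classes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pcts <- scs$percentages
  for (cl in c("increased", "decreased", "stable")) pcts[[cl]] <- num(pcts[[cl]])
  utils::write.table(pcts, out("sc_percentages.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  invisible(list(de_human = de_h, de_mouse = de_m, partition = partition,
                 percentages = pct, gsea = gsea, direction = dirsum,
                 screen = screen, modules = modules, mas = mas,
                 curation = curation, flux_profile = profile,
                 flux_comparison = comparison, timecourse = tc,
                 trajectory_calls = calls, sc_summary = scs))
}
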