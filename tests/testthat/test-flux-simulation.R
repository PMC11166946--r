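test_that("tier assignment honors fractions, ranking and promotions", {
  scores <- stats::setNames(seq(20, 1), sprintf("R%02d", 1:20))
  asg <- assign_confidence_tiers(scores, c(0.55, 0.25, 0.20))
  expect_equal(as.vector(table(asg$tier)[c("3", "2", "1")]), c(11L, 5L, 4L))
  expect_true(all(asg$tier[sprintf("R%02d", 1:11)] == 3))
  # all mass on tier 3
  asg2 <- assign_confidence_tiers(scores, c(1, 0, 0))
  expect_true(all(asg2$tier == 3))
  # essential-pathway promotion lifts a bottom-scored reaction
  pathways <- stats::setNames(rep("other", 20), names(scores))
  pathways[["R20"]] <- "Glycolysis/Gluconeogenesis"
  asg3 <- assign_confidence_tiers(scores, c(0.55, 0.25, 0.20),
                                  pathways = pathways)
  expect_equal(unname(asg3$tier[["R20"]]), 3L)
  expect_identical(asg3$promoted, "R20")
  expect_error(assign_confidence_tiers(scores, c(0.5, 0.2, 0.2)), "sum to 1")
  # ties break by reaction id ascending
  tied <- stats::setNames(rep(1, 4), c("B", "A", "D", "C"))
  asg4 <- assign_confidence_tiers(tied, c(0.5, 0.25, 0.25))
  expect_equal(unname(asg4$tier[c("A", "B")]), c(3L, 3L))
})

test_that("context extraction keeps support chains and drops dead branches", {
  m <- toy_metabolic_model()
  scores <- reaction_expression(
    m, stats::setNames(rep(5, length(m$genes)), m$genes))
  # all reactions tier 3 -> submodel is the full model
  asg_all <- assign_confidence_tiers(scores, c(1, 0, 0))
  ctx_all <- extract_context_model(m, asg_all)
  expect_setequal(ctx_all$reactions, m$reactions)
  expect_length(attr(ctx_all, "blocked"), 0)
  # a tier-1 sole producer feeding a tier-3 consumer is retained:
  # G6PDPPP (tier 1 by score) is the only route into the essential NAD chain
  expr <- stats::setNames(rep(5, length(m$genes)), m$genes)
  expr[["g12"]] <- 0   # G6PDPPP's gene at the bottom of the ranking
  asg <- assign_confidence_tiers(reaction_expression(m, expr),
                                 c(0.55, 0.25, 0.20),
                                 pathways = m$pathway)
  expect_equal(unname(asg$tier[["G6PDPPP"]]), 1L)
  ctx <- extract_context_model(m, asg)
  expect_true("G6PDPPP" %in% ctx$reactions)
  # the dedicated secretion branch is dropped when tier-1: no tier-3
  # optimum routes through it
  expr2 <- stats::setNames(rep(5, length(m$genes)), m$genes)
  expr2[["g21"]] <- 0
  asg2 <- assign_confidence_tiers(reaction_expression(m, expr2),
                                  c(0.55, 0.25, 0.20),
                                  pathways = m$pathway)
  ctx2 <- extract_context_model(m, asg2)
  expect_false("PYRWASTE" %in% ctx2$reactions)
})

test_that("context extraction is monotone in the tier-3 set", {
  m <- toy_metabolic_model()
  set.seed(12)
  expr <- stats::setNames(runif(length(m$genes), 1, 9), m$genes)
  scores <- reaction_expression(m, expr)
  small <- extract_context_model(
    m, assign_confidence_tiers(scores, c(0.3, 0.3, 0.4),
                               pathways = m$pathway))
  big <- extract_context_model(
    m, assign_confidence_tiers(scores, c(0.7, 0.2, 0.1),
                               pathways = m$pathway))
  expect_true(all(small$reactions %in% big$reactions))
})

test_that("flux levels satisfy steady state, bounds and the chain closed form", {
  chain <- toy_linear_chain(n_steps = 3, uptake_bound = 10)
  levels <- compute_flux_levels(chain)
  expect_equal(attr(levels, "nad_optimum"), 10)
  for (r in c("UPTAKE", "STEP1", "STEP2", "STEP3")) {
    expect_equal(unname(levels[[r]]), 10, label = r)
  }
  m <- toy_metabolic_model()
  lv <- compute_flux_levels(m)
  expect_equal(attr(lv, "nad_optimum"), 10)
  expect_true(all(lv >= 0 - 1e-6))
  expect_true(all(lv[setdiff(names(lv), "DM_nad_c")] <= m$ub + 1e-6))
  # reactions outside the context model are absent from output
  sub <- spacefrail:::subset_model(m, setdiff(m$reactions, "PYRWASTE"))
  lv2 <- compute_flux_levels(sub)
  expect_false("PYRWASTE" %in% names(lv2))
})

test_that("flux levels are invariant to reaction column order", {
  m <- toy_metabolic_model()
  lv <- compute_flux_levels(m)
  set.seed(5)
  perm <- sample(length(m$reactions))
  m2 <- spacefrail:::subset_model(m, m$reactions[perm])
  lv2 <- compute_flux_levels(m2)
  expect_equal(lv2[names(lv)], lv[names(lv)], ignore_attr = TRUE)
})

test_that("the default fraction grid carries both published working points", {
  grid <- eval(formals(select_confidence_fractions)$candidates)
  expect_true(any(vapply(grid, function(x)
    isTRUE(all.equal(x, c(0.55, 0.25, 0.20))), logical(1))))
  expect_true(any(vapply(grid, function(x)
    isTRUE(all.equal(x, c(0.45, 0.40, 0.15))), logical(1))))
})

test_that("fraction selection minimizes within-group flux variability", {
  ex <- generate_toy_metabolic_experiment(3, "tier-driven", seed = 3)
  sel <- select_confidence_fractions(ex$model, ex$expression, ex$group_labels,
                                     candidates = list(c(0.55, 0.25, 0.20),
                                                       c(0.45, 0.40, 0.15)))
  expect_length(sel$objective, 2)
  expect_equal(sel$best, list(c(0.55, 0.25, 0.20),
                              c(0.45, 0.40, 0.15))[[sel$best_index]])
  expect_lte(sel$objective[sel$best_index], min(sel$objective) + 1e-12)
  # a single candidate is returned with its objective
  sel1 <- select_confidence_fractions(ex$model, ex$expression,
                                      ex$group_labels,
                                      candidates = list(c(0.55, 0.25, 0.20)))
  expect_equal(sel1$best, c(0.55, 0.25, 0.20))
  expect_error(select_confidence_fractions(ex$model, ex$expression,
                                           ex$group_labels,
                                           candidates = list()),
               "candidate")
})

test_that("Van der Waerden matches the closed form and its edge cases", {
  oracle <- oracle_vdw(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  got <- vdw_test(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(got$statistic, oracle$statistic, tolerance = 1e-12)
  expect_equal(got$p.value, oracle$p.value, tolerance = 1e-12)
  # all-identical values: every normal score is qnorm(0.5) = 0
  flat <- vdw_test(rep(2, 6), rep(c("a", "b"), each = 3))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p.value, 1)
})

test_that("row z-scores standardize rows and zero out constant ones", {
  z <- row_zscores(rbind(a = c(1, 2, 3), b = c(5, 5, 5)))
  expect_equal(unname(z["a", ]), c(-1, 0, 1))
  expect_equal(unname(z["b", ]), c(0, 0, 0))
})

test_that("group comparison skips incomplete reactions and classes p-values", {
  ex <- generate_toy_metabolic_experiment(5, "tier-driven", seed = 2)
  prof <- run_flux_pipeline(ex$model, ex$expression, ex$group_labels)
  expect_warning(cmp <- compare_flux_groups(prof), "skipped")
  expect_true(all(cmp$table$pvalue >= 0 & cmp$table$pvalue <= 1))
  expect_true(all(cmp$table$class %in% c("p<0.05", "0.05<=p<0.1", "ns")))
  expect_equal(rownames(cmp$zscores), cmp$table$reaction)
  # planted difference shows up in at least one truth reaction
  hits <- cmp$table[cmp$table$reaction %in% ex$truth_diff_reactions, ]
  expect_true(any(hits$pvalue < 0.05))
  small <- list(flux_levels = prof$flux_levels[, c(1:3, 6:7)],
                group_labels = ex$group_labels[c(1:3, 6:7)])
  expect_error(compare_flux_groups(structure(small, class = "flux_profile")),
               "3 samples")
})

test_that("every recorded flux level respects the model bounds", {
  ex <- generate_toy_metabolic_experiment(3, "none", seed = 8)
  prof <- run_flux_pipeline(ex$model, ex$expression, ex$group_labels)
  m <- ex$model
  for (r in m$reactions) {
    vals <- prof$flux_levels[r, ]
    vals <- vals[!is.na(vals)]
    expect_true(all(vals >= m$lb[[r]] - 1e-6 & vals <= m$ub[[r]] + 1e-6),
                label = r)
  }
  expect_true(all(prof$nad_optimum == 10))
})
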