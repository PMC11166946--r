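# Context-specific flux simulation: confidence-tier extraction driven by
# per-sample expression, NAD-sink-first optimization, iterative per-reaction
# flux levels, and Van der Waerden group comparison.

# Cache of expression-independent support sets, keyed by model$id.
.support_cache <- new.env(parent = emptyenv())

#' Essential pathway tags
#'
#' The pathway names whose reactions are always promoted to the top
#' confidence tier for simulation stability. Oxidative phosphorylation and
#' the citric-acid cycle are deliberately excluded so mitochondrial
#' dysregulation can surface in the comparisons.
#'
#' @return Character vector of pathway tags.
#' @export
essential_pathways <- function() {
  c("Glycolysis/Gluconeogenesis", "CoA Synthesis", "CoA Catabolism",
    "NAD Metabolism", "Fatty Acid Synthesis", "Fatty Acid Oxidation",
    "Biomass and Maintenance Functions")
}

#' Assign confidence tiers from reaction scores
#'
#' Reactions are ranked by score (descending, ties broken by reaction id
#' ascending). The top `round(n * f3)` become tier 3, the next
#' `round(n * f2)` tier 2, the remainder tier 1; rounding is half-up. Any
#' reaction whose pathway tag is listed in `essential` is then promoted to
#' tier 3.
#'
#' @param scores Named numeric vector of reaction scores (see
#'   [reaction_expression()]).
#' @param fractions Numeric triple `(f3, f2, f1)` summing to 1.
#' @param pathways Named character vector of pathway tags per reaction
#'   (e.g. `model$pathway`); may be `NULL` to skip promotion.
#' @param essential Pathway tags promoted to tier 3
#'   (default [essential_pathways()]).
#' @return A `confidence_assignment`: list with `tier` (named integer),
#'   `fractions`, `scores`, and `promoted` (reaction ids promoted).
#' @export
assign_confidence_tiers <- function(scores, fractions,
                                    pathways = NULL,
                                    essential = essential_pathways()) {
  assert_that(is.numeric(fractions) && length(fractions) == 3 &&
                all(fractions >= 0),
              "fractions must be three non-negative numbers")
  assert_that(abs(sum(fractions) - 1) <= 1e-9, "fractions must sum to 1")
  assert_that(!is.null(names(scores)), "scores must be named by reaction")
  n <- length(scores)
  ord <- order(-scores, names(scores))
  n3 <- round_half_up(n * fractions[1])
  n2 <- round_half_up(n * fractions[2])
  n2 <- min(n2, n - n3)
  tier <- stats::setNames(rep(1L, n), names(scores))
  tier[ord[seq_len(n3)]] <- 3L
  if (n2 > 0) tier[ord[n3 + seq_len(n2)]] <- 2L
  promoted <- character(0)
  if (!is.null(pathways)) {
    ess <- names(scores)[pathways[names(scores)] %in% essential]
    promoted <- ess[tier[ess] < 3L]
    tier[ess] <- 3L
  }
  structure(list(tier = tier, fractions = fractions, scores = scores,
                 promoted = promoted),
            class = "confidence_assignment")
}

#' @export
print.confidence_assignment <- function(x, ...) {
  cat("confidence_assignment:", sum(x$tier == 3), "tier-3,",
      sum(x$tier == 2), "tier-2,", sum(x$tier == 1), "tier-1",
      sprintf("(%d promoted)\n", length(x$promoted)))
  invisible(x)
}

# Support set of a reaction: the reactions carrying |flux| > epsilon in the
# deterministic optimum that maximizes it over the FULL model. A fixed
# property of the model, so cached by model id when one is set.
reaction_support_sets <- function(model, epsilon = 1e-6) {
  key <- model$id
  if (!is.null(key) && !is.null(.support_cache[[key]])) return(.support_cache[[key]])
  supports <- lapply(model$reactions, function(r) {
    res <- maximize_reaction(model, r)
    if (is.null(res)) return(character(0))
    model$reactions[abs(res$solution) > epsilon]
  })
  names(supports) <- model$reactions
  if (!is.null(key)) .support_cache[[key]] <- supports
  supports
}

# Restrict a model to a reaction subset.
subset_model <- function(model, keep) {
  keep <- intersect(model$reactions, keep)
  rxns <- lapply(keep, function(r) {
    list(id = r, mets = model$mets[[r]], lb = unname(model$lb[[r]]),
         ub = unname(model$ub[[r]]), rule = unname(model$rule[[r]]),
         pathway = unname(model$pathway[[r]]))
  })
  sub_id <- if (is.null(model$id)) NULL else
    paste0(model$id, "|", paste(sort(keep), collapse = ","))
  metabolic_model(model$metabolites, rxns, genes = model$genes, id = sub_id)
}

#' Extract a context-specific submodel from confidence tiers
#'
#' The retained set starts from the tier-3 reactions plus all exchange
#' reactions. Support passes then run over the retained non-exchange
#' reactions: each is maximized over the full model and every tier-2/1
#' reaction carrying `|flux| > epsilon` in that optimum joins the retained
#' set; passes repeat until stable. Non-retained reactions are removed.
#' Retained tier-3 reactions that cannot carry flux in the final submodel
#' are reported in the `blocked` attribute.
#'
#' @param model A feasible [metabolic_model()].
#' @param assignment A `confidence_assignment` (see
#'   [assign_confidence_tiers()]).
#' @param epsilon Flux tolerance for support membership.
#' @param report_blocked Solve the two variability LPs per retained tier-3
#'   reaction that identify blocked reactions; disable in bulk runs where
#'   only the flux levels are needed.
#' @return The context [metabolic_model()] with attributes `blocked` and
#'   `retained`.
#' @export
extract_context_model <- function(model, assignment, epsilon = 1e-6,
                                  report_blocked = TRUE) {
  feas <- solve_flux_lp(model$S, model$lb, model$ub,
                        numeric(length(model$reactions)))
  if (is.null(feas)) {
    stop(errorCondition("full model is infeasible",
                        class = c("spacefrail_model_infeasible", "error")))
  }
  tier <- assignment$tier[model$reactions]
  exch <- is_exchange_reaction(model)
  supports <- reaction_support_sets(model, epsilon = epsilon)
  retained <- union(model$reactions[tier == 3L], model$reactions[exch])
  visited <- character(0)
  for (i in seq_along(model$reactions)) {
    frontier <- setdiff(retained[!exch[retained]], visited)
    if (length(frontier) == 0) break
    visited <- union(visited, frontier)
    added <- unique(unlist(supports[frontier]))
    retained <- union(retained, added)
  }
  context <- subset_model(model, retained)
  tier3 <- intersect(context$reactions, model$reactions[tier == 3L])
  if (!report_blocked) {
    attr(context, "blocked") <- character(0)
    attr(context, "retained") <- context$reactions
    return(context)
  }
  blocked <- vapply(tier3, function(r) {
    fwd <- maximize_reaction(context, r)
    hi <- if (is.null(fwd)) 0 else fwd$value
    j <- match(r, context$reactions)
    obj <- numeric(length(context$reactions)); obj[j] <- -1
    bwd <- solve_flux_lp(context$S, context$lb, context$ub, obj)
    lo <- if (is.null(bwd)) 0 else sum(obj * bwd$solution)
    max(abs(hi), abs(lo)) <= epsilon
  }, logical(1))
  attr(context, "blocked") <- tier3[blocked]
  attr(context, "retained") <- context$reactions
  context
}

#' Compute one sample's per-reaction flux levels
#'
#' A sink reaction draining `nad_metabolite` is added when absent; its flux
#' is first maximized (`nad_optimum`), then constrained to stay at or above
#' `sink_factor * nad_optimum`, and every reaction of the context model is
#' then maximized in turn. The maximized value is the reaction's flux level.
#' Every LP solution satisfies steady state within 1e-6.
#'
#' @param context_model A [metabolic_model()] (typically from
#'   [extract_context_model()]).
#' @param nad_metabolite Metabolite drained by the sink (default `"nad_c"`).
#' @param sink_factor Retained fraction of the sink optimum (default 0.9).
#' @param sink_ub Upper bound of the added sink reaction.
#' @return Named numeric vector of flux levels (including the sink reaction
#'   `DM_<metabolite>`), with attribute `nad_optimum`.
#' @export
compute_flux_levels <- function(context_model, nad_metabolite = "nad_c",
                                sink_factor = 0.9, sink_ub = 1000) {
  assert_that(nad_metabolite %in% context_model$metabolites$id,
              "metabolite not in model: ", nad_metabolite)
  sink_id <- paste0("DM_", nad_metabolite)
  model <- context_model
  if (!(sink_id %in% model$reactions)) {
    rxns <- c(lapply(model$reactions, function(r) {
      list(id = r, mets = model$mets[[r]], lb = unname(model$lb[[r]]),
           ub = unname(model$ub[[r]]), rule = unname(model$rule[[r]]),
           pathway = unname(model$pathway[[r]]))
    }), list(list(id = sink_id,
                  mets = stats::setNames(-1, nad_metabolite),
                  lb = 0, ub = sink_ub, rule = "", pathway = "NAD Sink")))
    sub_id <- if (is.null(model$id)) NULL else paste0(model$id, "+sink")
    model <- metabolic_model(model$metabolites, rxns, genes = model$genes,
                             id = sub_id)
  }
  opt <- maximize_reaction(model, sink_id)
  if (is.null(opt)) {
    stop(errorCondition(paste0("sink optimization infeasible for ", sink_id),
                        class = c("spacefrail_model_infeasible", "error")))
  }
  nad_optimum <- opt$value
  ge <- matrix(0, 1, length(model$reactions))
  ge[1, match(sink_id, model$reactions)] <- 1
  rhs <- sink_factor * nad_optimum
  levels <- vapply(model$reactions, function(r) {
    res <- maximize_reaction(model, r, ge_mat = ge, ge_rhs = rhs)
    if (is.null(res)) {
      stop(errorCondition(
        paste0("flux optimization infeasible for reaction ", r,
               " under the NAD-sink constraint; consider lowering sink_factor"),
        class = c("spacefrail_model_infeasible", "error")))
    }
    res$value
  }, numeric(1))
  attr(levels, "nad_optimum") <- nad_optimum
  levels
}

#' Run the per-sample flux pipeline over a cohort
#'
#' For each sample: score reactions from its expression column, assign
#' confidence tiers, extract the context model, and compute flux levels.
#' Samples sharing a retained reaction set reuse the solved flux levels.
#'
#' @param model A [metabolic_model()].
#' @param expression Gene-by-sample numeric matrix over the model's genes.
#' @param group_labels Per-sample condition labels.
#' @param fractions Tier fraction triple `(f3, f2, f1)`.
#' @param nad_metabolite,sink_factor Passed to [compute_flux_levels()].
#' @param essential Essential pathway tags (default [essential_pathways()]).
#' @return A `flux_profile`: list with `flux_levels` (reaction-by-sample
#'   matrix, `NA` where a reaction is absent from a sample's context),
#'   `group_labels`, and `nad_optimum` per sample.
#' @export
run_flux_pipeline <- function(model, expression, group_labels,
                              fractions = c(0.55, 0.25, 0.20),
                              nad_metabolite = "nad_c", sink_factor = 0.9,
                              essential = essential_pathways()) {
  assert_that(is.matrix(expression) && !is.null(rownames(expression)),
              "expression must be a matrix with gene rownames")
  assert_that(length(group_labels) == ncol(expression),
              "group_labels must match expression columns")
  samples <- colnames(expression) %||% paste0("s", seq_len(ncol(expression)))
  sink_id <- paste0("DM_", nad_metabolite)
  all_rxns <- union(model$reactions, sink_id)
  flux <- matrix(NA_real_, nrow = length(all_rxns), ncol = length(samples),
                 dimnames = list(all_rxns, samples))
  nad_opt <- stats::setNames(numeric(length(samples)), samples)
  cache <- new.env(parent = emptyenv())
  for (i in seq_along(samples)) {
    scores <- reaction_expression(model, expression[, i])
    asg <- assign_confidence_tiers(scores, fractions,
                                   pathways = model$pathway,
                                   essential = essential)
    context <- extract_context_model(model, asg, report_blocked = FALSE)
    key <- paste(sort(attr(context, "retained")), collapse = "|")
    if (is.null(cache[[key]])) {
      cache[[key]] <- compute_flux_levels(context,
                                          nad_metabolite = nad_metabolite,
                                          sink_factor = sink_factor)
    }
    levels <- cache[[key]]
    flux[names(levels), i] <- levels
    nad_opt[i] <- attr(levels, "nad_optimum")
  }
  structure(list(flux_levels = flux, group_labels = group_labels,
                 nad_optimum = nad_opt, fractions = fractions),
            class = "flux_profile")
}

#' @export
print.flux_profile <- function(x, ...) {
  cat("flux_profile:", nrow(x$flux_levels), "reactions x",
      ncol(x$flux_levels), "samples; groups:",
      paste(names(table(x$group_labels)), table(x$group_labels),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Select tier fractions minimizing within-group flux variability
#'
#' Runs the full per-sample pipeline for each candidate fraction triple and
#' scores it by the summed within-group sample standard deviation of flux
#' levels (over reactions present in all samples of a group). The candidate
#' with the smallest objective wins; ties go to the larger tier-3 fraction.
#'
#' @param candidates List of `(f3, f2, f1)` triples. The default grid holds
#'   the two published working points.
#' @param model,expression,group_labels,... Passed to [run_flux_pipeline()].
#' @return List with `best` (the selected triple), `objective` per candidate,
#'   and `profiles` (the per-candidate `flux_profile`s).
#' @export
select_confidence_fractions <- function(model, expression, group_labels,
                                        candidates = list(c(0.55, 0.25, 0.20),
                                                          c(0.45, 0.40, 0.15)),
                                        ...) {
  assert_that(length(candidates) >= 1, "need at least one candidate triple")
  objective <- numeric(length(candidates))
  profiles <- vector("list", length(candidates))
  for (k in seq_along(candidates)) {
    prof <- run_flux_pipeline(model, expression, group_labels,
                              fractions = candidates[[k]], ...)
    profiles[[k]] <- prof
    obj <- 0
    for (g in unique(group_labels)) {
      sub <- prof$flux_levels[, group_labels == g, drop = FALSE]
      complete <- stats::complete.cases(sub)
      if (any(complete)) {
        obj <- obj + sum(apply(sub[complete, , drop = FALSE], 1, stats::sd))
      }
    }
    objective[k] <- obj
  }
  f3 <- vapply(candidates, `[`, numeric(1), 1L)
  best <- order(objective, -f3)[1]
  list(best = candidates[[best]], best_index = best,
       objective = objective, profiles = profiles)
}

#' Van der Waerden normal-scores test
#'
#' Pooled values are ranked (average ranks on ties) and converted to normal
#' scores `A_i = qnorm(R_i / (N + 1))`. With `s^2 = sum(A_i^2) / (N - 1)`,
#' the statistic is `T = sum_j n_j * mean(A_j)^2 / s^2`, compared to a
#' chi-square with `groups - 1` degrees of freedom. Degenerate inputs (all
#' values tied) give `T = 0`, `p = 1`.
#'
#' @param x Numeric values.
#' @param g Group labels (any number of groups >= 2).
#' @return List with `statistic` and `p.value`.
#' @export
vdw_test <- function(x, g) {
  g <- as.factor(g)
  assert_that(nlevels(g) >= 2, "need at least two groups")
  N <- length(x)
  A <- stats::qnorm(rank(x) / (N + 1))
  s2 <- sum(A^2) / (N - 1)
  if (s2 <= 0) return(list(statistic = 0, p.value = 1))
  Tstat <- sum(tapply(A, g, function(a) length(a) * mean(a)^2)) / s2
  list(statistic = unname(Tstat),
       p.value = stats::pchisq(Tstat, df = nlevels(g) - 1, lower.tail = FALSE))
}

#' Row-wise z-scores
#'
#' Standardizes each row to zero mean and unit sample SD; constant rows map
#' to all-zero rows.
#'
#' @param mat Numeric matrix.
#' @return Matrix of the same shape.
#' @export
row_zscores <- function(mat) {
  mu <- rowMeans(mat)
  sd <- apply(mat, 1, stats::sd)
  z <- (mat - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  z
}

#' Compare flux levels between two groups
#'
#' Applies the Van der Waerden test per reaction, classifies significance at
#' `p < 0.05` and `0.05 <= p < 0.1`, and standardizes flux rows to z-scores.
#' Reactions with any missing sample level are skipped with a warning.
#'
#' @param profile A `flux_profile` (see [run_flux_pipeline()]) with exactly
#'   two groups of at least three samples each.
#' @return A `flux_comparison`: data.frame `table` (reaction, statistic,
#'   pvalue, class) plus `zscores` matrix.
#' @export
compare_flux_groups <- function(profile) {
  flux <- profile$flux_levels
  g <- as.factor(profile$group_labels)
  assert_that(nlevels(g) == 2, "exactly two groups required")
  assert_that(all(table(g) >= 3), "each group needs at least 3 samples")
  complete <- stats::complete.cases(flux)
  if (any(!complete)) {
    warning(sum(!complete), " reaction(s) skipped: missing flux levels in ",
            "some samples", call. = FALSE)
  }
  flux <- flux[complete, , drop = FALSE]
  res <- t(vapply(rownames(flux), function(r) {
    v <- vdw_test(flux[r, ], g)
    c(v$statistic, v$p.value)
  }, numeric(2)))
  class_lab <- ifelse(res[, 2] < 0.05, "p<0.05",
                      ifelse(res[, 2] < 0.1, "0.05<=p<0.1", "ns"))
  tab <- data.frame(reaction = rownames(flux),
                    vdw_statistic = res[, 1],
                    pvalue = res[, 2],
                    class = class_lab,
                    constant = apply(flux, 1, function(x) stats::sd(x) == 0),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = tab, zscores = row_zscores(flux),
                 group_labels = profile$group_labels),
            class = "flux_comparison")
}

#' @export
print.flux_comparison <- function(x, ...) {
  cat("flux_comparison:", nrow(x$table), "reactions;",
      sum(x$table$class == "p<0.05"), "at p<0.05,",
      sum(x$table$class == "0.05<=p<0.1"), "at 0.05<=p<0.1\n")
  invisible(x)
}
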