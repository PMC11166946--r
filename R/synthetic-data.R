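# Synthetic-data generators with known planted structure. Every generator is
# a pure function of (parameters, seed): the caller's RNG state is left
# untouched and identical calls are bit-identical.

#' Generate a two-group bulk expression cohort
#'
#' Gaussian log-scale expression around per-gene baselines; a planted
#' fraction of genes receives a group-mean shift of `effect`, all other
#' genes share identical group means.
#'
#' @param n_genes Number of genes (>= 10).
#' @param n_per_group Samples per group (>= 3).
#' @param de_fraction Fraction of genes planted as differentially expressed.
#' @param effect Group-mean shift (expression units) for planted genes.
#' @param noise_sd Gaussian noise SD (> 0).
#' @param seed Integer seed.
#' @param groups Two group labels (second group carries the shift).
#' @return A `bulk_cohort`: list with `expression` (gene x sample),
#'   `group_labels`, `truth_de_genes`, `truth_effect`.
#' @export
generate_bulk <- function(n_genes, n_per_group, de_fraction = 0.1,
                          effect = 2, noise_sd = 1, seed = 1,
                          groups = c("ground", "flight")) {
  assert_that(is_count(n_genes, 10), "n_genes must be an integer >= 10")
  assert_that(is_count(n_per_group, 3), "n_per_group must be an integer >= 3")
  assert_that(de_fraction >= 0 && de_fraction <= 1,
              "de_fraction must be in [0, 1]")
  assert_that(noise_sd > 0, "noise_sd must be positive")
  assert_that(length(groups) == 2, "exactly two group labels")
  with_seed(seed, {
    genes <- sprintf("gene%04d", seq_len(n_genes))
    samples <- c(paste0(groups[1], "_", seq_len(n_per_group)),
                 paste0(groups[2], "_", seq_len(n_per_group)))
    group_labels <- rep(groups, each = n_per_group)
    baseline <- stats::rnorm(n_genes, mean = 8, sd = 2)
    n_de <- round_half_up(n_genes * de_fraction)
    de_genes <- if (n_de > 0) sort(sample(genes, n_de)) else character(0)
    mu <- matrix(baseline, n_genes, 2 * n_per_group)
    mu[match(de_genes, genes), group_labels == groups[2]] <-
      mu[match(de_genes, genes), group_labels == groups[2]] + effect
    expr <- mu + matrix(stats::rnorm(n_genes * 2 * n_per_group, sd = noise_sd),
                        n_genes, 2 * n_per_group)
    dimnames(expr) <- list(genes, samples)
    structure(list(expression = expr, group_labels = group_labels,
                   truth_de_genes = de_genes,
                   truth_effect = stats::setNames(rep(effect, n_de), de_genes)),
              class = "bulk_cohort")
  })
}

#' Generate a sarcopenia-style cohort with a planted co-expression module
#'
#' Module genes load on a shared latent factor with unit loading and noise
#' calibrated so the expected within-module pairwise correlation equals
#' `module_cor`. A continuous trait tracks the factor; binary classes split
#' the trait at zero, and planted predictor genes receive a between-class
#' mean shift.
#'
#' @param n_genes Total genes.
#' @param n_per_group Samples per class (default 59, a 118-sample cohort).
#' @param module_size Planted module size (>= 5).
#' @param module_cor Target within-module correlation in (0, 1).
#' @param n_predictors Planted single-gene predictors.
#' @param predictor_shift Between-class mean shift for predictor genes.
#' @param seed Integer seed.
#' @return A `sarcopenia_cohort`: `expression`, `group_labels`
#'   (sarcopenic/control), `trait` (continuous), `truth_module_genes`,
#'   `truth_predictor_genes`.
#' @export
generate_sarcopenia_cohort <- function(n_genes = 200, n_per_group = 59,
                                       module_size = 30, module_cor = 0.8,
                                       n_predictors = 5, predictor_shift = 2,
                                       seed = 1) {
  assert_that(is_count(module_size, 5), "module_size must be an integer >= 5")
  assert_that(module_cor > 0 && module_cor < 1, "module_cor must be in (0, 1)")
  assert_that(module_size <= n_genes, "module_size exceeds n_genes")
  assert_that(is_count(n_per_group, 3), "n_per_group must be an integer >= 3")
  assert_that(n_predictors >= 0 && module_size + n_predictors <= n_genes,
              "module_size + n_predictors exceeds n_genes")
  with_seed(seed, {
    n <- 2 * n_per_group
    genes <- sprintf("gene%04d", seq_len(n_genes))
    module_genes <- genes[seq_len(module_size)]
    predictor_genes <- if (n_predictors > 0)
      genes[module_size + seq_len(n_predictors)] else character(0)
    factor_scores <- stats::rnorm(n)
    noise_sd <- sqrt((1 - module_cor) / module_cor)
    expr <- matrix(stats::rnorm(n_genes * n), n_genes, n,
                   dimnames = list(genes, sprintf("s%03d", seq_len(n))))
    expr[module_genes, ] <-
      matrix(factor_scores, module_size, n, byrow = TRUE) +
      matrix(stats::rnorm(module_size * n, sd = noise_sd), module_size, n)
    trait <- factor_scores + stats::rnorm(n, sd = 0.3)
    classes <- ifelse(trait > stats::median(trait), "sarcopenic", "control")
    # enforce balanced classes via the median split with deterministic ties
    if (sum(classes == "sarcopenic") != n_per_group) {
      ord <- order(-trait, seq_along(trait))
      classes <- rep("control", n)
      classes[ord[seq_len(n_per_group)]] <- "sarcopenic"
    }
    for (g in predictor_genes) {
      expr[g, classes == "sarcopenic"] <- expr[g, classes == "sarcopenic"] +
        predictor_shift
    }
    structure(list(expression = expr, group_labels = classes, trait = trait,
                   truth_module_genes = module_genes,
                   truth_predictor_genes = predictor_genes),
              class = "sarcopenia_cohort")
  })
}

#' Generate a toy metabolic flux experiment
#'
#' Pairs the fixed toy network (see [toy_metabolic_model()]) with per-sample
#' gene expression for a flight and a ground group. Under
#' `flux_shift_mode = "tier-driven"`, the gene controlling the dedicated
#' pyruvate secretion branch (`g21`) is expressed high in flight and low in
#' ground, so the branch is tier-3 (retained) in flight and tier-1
#' (removed) in ground; under `"none"` all genes share one distribution in
#' both groups.
#'
#' @param n_per_group Samples per group (>= 3).
#' @param flux_shift_mode `"none"` or `"tier-driven"`.
#' @param seed Integer seed.
#' @return A `toy_metabolic_experiment`: `model`, `expression`
#'   (gene x sample), `group_labels`, `truth_diff_reactions`.
#' @export
generate_toy_metabolic_experiment <- function(n_per_group = 5,
                                              flux_shift_mode = c("none", "tier-driven"),
                                              seed = 1) {
  assert_that(is_count(n_per_group, 3), "n_per_group must be an integer >= 3")
  flux_shift_mode <- match.arg(flux_shift_mode)
  model <- toy_metabolic_model()
  with_seed(seed, {
    n <- 2 * n_per_group
    samples <- c(paste0("flight_", seq_len(n_per_group)),
                 paste0("ground_", seq_len(n_per_group)))
    group_labels <- rep(c("flight", "ground"), each = n_per_group)
    expr <- matrix(pmax(stats::rnorm(length(model$genes) * n, mean = 5, sd = 1), 0),
                   length(model$genes), n,
                   dimnames = list(model$genes, samples))
    truth <- character(0)
    if (flux_shift_mode == "tier-driven") {
      expr["g21", group_labels == "flight"] <-
        pmax(stats::rnorm(n_per_group, mean = 9, sd = 0.5), 0)
      expr["g21", group_labels == "ground"] <-
        pmax(stats::rnorm(n_per_group, mean = 1, sd = 0.5), 0)
      truth <- c("PYRWASTE", "EX_waste")
    }
    structure(list(model = model, expression = expr,
                   group_labels = group_labels,
                   truth_diff_reactions = truth),
              class = "toy_metabolic_experiment")
  })
}

#' Generate astronaut time-course and single-cell data
#'
#' The time-course matrix emulates plasma cell-free RNA profiles: per-gene
#' planted trajectory classes over three pre-flight, three in-flight and
#' three post-flight timepoints for `n_astronauts` subjects. The single-cell
#' table draws over-dispersed negative-binomial counts per cell type with a
#' planted post-flight (`R+1` onward) mean shift for a subset of genes.
#'
#' @param n_genes Genes in both outputs.
#' @param n_astronauts Subjects (>= 2; default 6).
#' @param n_cells_per_type Cells per (cell type, timepoint).
#' @param shift_log2fc Planted post-flight log2 shift for single-cell genes.
#' @param seed Integer seed.
#' @param dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @return List with `timecourse` (`synthetic_timecourse`: `values`,
#'   `labels`, `truth_class`) and `singlecell` (`synthetic_singlecell`:
#'   `counts` cell x gene, `cell_type`, `timepoint`, `truth_shifted_genes`,
#'   `base_mean`).
#' @export
generate_timecourse_and_singlecell <- function(n_genes = 40, n_astronauts = 6,
                                               n_cells_per_type = 100,
                                               shift_log2fc = 1, seed = 1,
                                               dispersion = 0.5) {
  assert_that(is_count(n_genes, 4), "n_genes must be an integer >= 4")
  assert_that(is_count(n_astronauts, 2), "n_astronauts must be >= 2")
  assert_that(is_count(n_cells_per_type, 10), "n_cells_per_type must be >= 10")
  with_seed(seed, {
    genes <- sprintf("gene%04d", seq_len(n_genes))
    classes <- c("down_up", "down_down", "stable", "offset")
    truth_class <- stats::setNames(
      sample(rep_len(classes, n_genes)), genes)
    timepoints <- c("L-92", "L-44", "L-3", "L+14", "L+45", "L+120",
                    "R+1", "R+30", "R+120")
    phase <- c(rep("pre", 3), rep("flight", 3), rep("post", 3))
    baseline <- 10
    mean_for <- function(cls, ph) {
      switch(cls,
        down_up   = c(pre = baseline, flight = 0.6 * baseline, post = baseline)[[ph]],
        down_down = c(pre = baseline, flight = 0.6 * baseline, post = 0.6 * baseline)[[ph]],
        stable    = baseline,
        offset    = c(pre = baseline, flight = baseline, post = 1.4 * baseline)[[ph]]
      )
    }
    cols <- as.vector(outer(paste0("astro", seq_len(n_astronauts)), timepoints,
                            paste, sep = "_"))
    values <- matrix(0, n_genes, length(cols), dimnames = list(genes, cols))
    for (gi in seq_len(n_genes)) {
      mus <- vapply(seq_along(timepoints),
                    function(ti) mean_for(truth_class[gi], phase[ti]),
                    numeric(1))
      values[gi, ] <- rep(mus, each = n_astronauts) +
        stats::rnorm(n_astronauts * length(timepoints), sd = 0.5)
    }
    labels <- data.frame(
      sample = cols,
      subject = rep(paste0("astro", seq_len(n_astronauts)), length(timepoints)),
      timepoint = rep(timepoints, each = n_astronauts),
      stringsAsFactors = FALSE
    )
    timecourse <- structure(list(values = values, labels = labels,
                                 truth_class = truth_class),
                            class = "synthetic_timecourse")

    cell_types <- c("T", "B", "NK", "Monocyte")
    sc_timepoints <- c("pre-flight", "R+1", "R+45")
    base_mean <- stats::setNames(stats::rexp(n_genes, rate = 0.5) + 0.2, genes)
    type_factor <- stats::setNames(stats::runif(length(cell_types), 0.5, 1.5),
                                   cell_types)
    shifted <- sort(sample(genes, max(1, round_half_up(n_genes * 0.25))))
    n_cells <- length(cell_types) * length(sc_timepoints) * n_cells_per_type
    cell_type <- rep(rep(cell_types, each = n_cells_per_type),
                     length(sc_timepoints))
    timepoint <- rep(sc_timepoints, each = length(cell_types) * n_cells_per_type)
    counts <- matrix(0L, nrow = n_cells, ncol = n_genes,
                     dimnames = list(sprintf("cell%05d", seq_len(n_cells)), genes))
    size <- 1 / dispersion
    for (g in genes) {
      mu <- base_mean[[g]] * type_factor[cell_type]
      if (g %in% shifted) {
        post <- timepoint != "pre-flight"
        mu[post] <- mu[post] * 2^shift_log2fc
      }
      counts[, g] <- stats::rnbinom(n_cells, mu = mu, size = size)
    }
    singlecell <- structure(list(counts = counts, cell_type = cell_type,
                                 timepoint = timepoint,
                                 truth_shifted_genes = shifted,
                                 base_mean = base_mean,
                                 type_factor = type_factor),
                            class = "synthetic_singlecell")
    list(timecourse = timecourse, singlecell = singlecell)
  })
}
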