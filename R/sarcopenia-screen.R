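# Sarcopenia-predictor discovery: per-gene Mann-Whitney screen, single-gene
# kNN Mean Accuracy Scores, co-expression modules with eigengene-trait
# correlation, and hypergeometric over-representation curation.

#' Per-gene Mann-Whitney U screen
#'
#' Tests every gene for a two-group location difference. The exact
#' two-sided p-value (full enumeration of the U null) is used when
#' `n1 + n2 <= 16` and the gene has no ties; otherwise the tie-corrected
#' normal approximation with continuity correction.
#'
#' @param expression Gene-by-sample numeric matrix.
#' @param labels Two-group labels, one per sample (each group >= 3).
#' @param alpha Unadjusted significance level defining `is_deg`.
#' @return Data frame with `gene`, `u_statistic`, `pvalue`, `padj`
#'   (Benjamini-Hochberg), `is_deg`, `exact`.
#' @export
mwu_screen <- function(expression, labels, alpha = 0.05) {
  assert_that(is.matrix(expression) && !is.null(rownames(expression)),
              "expression must be a matrix with gene rownames")
  g <- as.factor(labels)
  assert_that(nlevels(g) == 2, "labels must define exactly two groups")
  assert_that(all(table(g) >= 3), "each group needs at least 3 samples")
  assert_that(length(labels) == ncol(expression),
              "labels must match expression columns")
  n <- ncol(expression)
  a_idx <- which(g == levels(g)[1])
  b_idx <- which(g == levels(g)[2])
  res <- t(vapply(rownames(expression), function(gene) {
    x <- expression[gene, a_idx]
    y <- expression[gene, b_idx]
    ties <- anyDuplicated(c(x, y)) > 0
    exact <- (n <= 16) && !ties
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, exact = exact, correct = TRUE,
                         alternative = "two.sided"))
    c(u = unname(wt$statistic), p = wt$p.value, exact = as.numeric(exact))
  }, numeric(3)))
  data.frame(gene = rownames(expression),
             u_statistic = res[, 1],
             pvalue = res[, 2],
             padj = bh_adjust(res[, 2]),
             is_deg = res[, 2] < alpha,
             exact = res[, 3] == 1,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Deterministic stratified fold assignment: within each class, samples are
# shuffled once and dealt round-robin into folds.
stratified_folds <- function(labels, folds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

# Classify one held-out value by majority vote of its k nearest training
# values (absolute difference of the single gene value). Distance ties break
# toward the smaller training index; vote ties break toward the
# training-fold majority class, then the lexicographically smaller label.
knn_classify_1d <- function(train_x, train_y, test_x, k) {
  n <- length(train_x)
  counts <- table(train_y)
  maj <- names(counts)[counts == max(counts)]
  majority <- min(maj)
  vapply(test_x, function(x) {
    d <- abs(train_x - x)
    nb <- order(d, seq_len(n))[seq_len(k)]
    votes <- table(train_y[nb])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1) top else if (majority %in% top) majority else min(top)
  }, character(1))
}

#' Mean Accuracy Score of a single gene
#'
#' Repeated stratified cross-validation of a one-dimensional k-nearest-
#' neighbor classifier on a single gene's values, with neighbors taken by
#' absolute difference of the gene value. The score is exactly invariant
#' under positive affine transforms of the gene (general monotone maps can
#' reshuffle which side of a query is metrically closer, so no metric 1-D
#' classifier is invariant to them). The Mean Accuracy Score (MAS) is the
#' average fold accuracy over all folds and repeats.
#'
#' @param values Per-sample numeric values of one gene.
#' @param labels Two-group labels (each group >= `folds`).
#' @param k Neighbor count (default 5; must be < smallest training fold).
#' @param folds Cross-validation folds (default 5).
#' @param repeats Repeated fold draws (default 20).
#' @param seed Integer seed; each repeat is seeded deterministically from it.
#' @return A `mas_result`: list with `mas`, `fold_accuracies`, `k`,
#'   `cv_spec`.
#' @export
mas_score <- function(values, labels, k = 5, folds = 5, repeats = 20,
                      seed = 1) {
  g <- as.character(labels)
  classes <- sort(unique(g))
  assert_that(length(classes) == 2, "labels must define exactly two groups")
  assert_that(all(table(g) >= folds),
              "each group needs at least `folds` samples")
  assert_that(length(values) == length(g), "values/labels length mismatch")
  max_test_fold <- sum(ceiling(table(g) / folds))
  assert_that(k < length(g) - max_test_fold,
              "k must be smaller than the training-fold size")
  acc <- numeric(0)
  for (rep_i in seq_len(repeats)) {
    fold <- NULL
    for (attempt in seq_len(10)) {
      fold_try <- with_seed(child_seed(seed, rep_i * 100 + attempt),
                            stratified_folds(g, folds))
      ok <- all(vapply(seq_len(folds), function(f) {
        length(unique(g[fold_try != f])) == 2
      }, logical(1)))
      if (ok) { fold <- fold_try; break }
      message("redrawing fold assignment (repeat ", rep_i,
              "): a class was absent from a training fold")
    }
    if (is.null(fold)) {
      stop_invalid("could not build folds containing both classes after 10 attempts")
    }
    for (f in seq_len(folds)) {
      train <- fold != f
      pred <- knn_classify_1d(values[train], g[train], values[!train], k)
      acc <- c(acc, mean(pred == g[!train]))
    }
  }
  structure(list(mas = mean(acc), fold_accuracies = acc, k = k,
                 cv_spec = list(folds = folds, repeats = repeats, seed = seed)),
            class = "mas_result")
}

#' @export
print.mas_result <- function(x, ...) {
  cat(sprintf("mas_result: MAS = %.3f over %d folds (k = %d)\n",
              x$mas, length(x$fold_accuracies), x$k))
  invisible(x)
}

#' Detect co-expression modules and their trait correlation
#'
#' A deterministic weighted-correlation workflow: dissimilarity
#' `1 - |pearson cor|^power`, average-linkage hierarchical clustering cut at
#' `cut_height`; clusters below `min_module_size` pool into "unassigned".
#' Each module's eigengene is the first principal component of its
#' standardized submatrix (sign-oriented to correlate positively with mean
#' module expression) and is correlated with the trait when given.
#'
#' @param expression Gene-by-sample matrix (>= 4 samples). Zero-variance
#'   genes are dropped with a warning.
#' @param power Soft-threshold exponent on `|cor|` (default 6).
#' @param min_module_size Smallest reported module (default 10).
#' @param cut_height Tree cut height in dissimilarity units (default 0.9).
#' @param trait Optional per-sample trait for eigengene correlation.
#' @return List of `coex_module`s: `label`, `genes`, `eigengene`,
#'   `trait_cor`, `unassigned` flag; sorted by size, unassigned pool last.
#' @export
detect_modules <- function(expression, power = 6, min_module_size = 10,
                           cut_height = 0.9, trait = NULL) {
  assert_that(is.matrix(expression), "expression must be a matrix")
  assert_that(ncol(expression) >= 4, "need at least 4 samples")
  assert_that(nrow(expression) >= min_module_size,
              "need at least min_module_size genes")
  assert_that(power > 0, "power must be positive")
  vars <- apply(expression, 1, stats::var)
  if (any(vars == 0)) {
    warning(sum(vars == 0), " zero-variance gene(s) dropped before clustering",
            call. = FALSE)
    expression <- expression[vars > 0, , drop = FALSE]
  }
  cmat <- stats::cor(t(expression))
  diss <- 1 - abs(cmat)^power
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- table(cl)
  real <- names(sizes)[sizes >= min_module_size]
  make_module <- function(genes, label, unassigned) {
    sub <- expression[genes, , drop = FALSE]
    std <- t(scale(t(sub)))
    sv <- svd(std, nu = 0, nv = 1)
    eig <- sv$v[, 1]
    if (stats::cor(eig, colMeans(std)) < 0) eig <- -eig
    tc <- if (is.null(trait)) NA_real_ else stats::cor(eig, trait)
    structure(list(label = label, genes = genes, eigengene = eig,
                   trait_cor = tc, unassigned = unassigned),
              class = "coex_module")
  }
  ord <- real[order(-sizes[real])]
  modules <- lapply(seq_along(ord), function(i) {
    make_module(rownames(expression)[cl == as.integer(ord[i])],
                paste0("M", i), unassigned = FALSE)
  })
  pool <- rownames(expression)[!(cl %in% as.integer(real))]
  if (length(pool) >= 2) {
    modules <- c(modules, list(make_module(pool, "unassigned",
                                           unassigned = TRUE)))
  }
  modules
}

#' @export
print.coex_module <- function(x, ...) {
  cat(sprintf("coex_module %s: %d genes, trait_cor = %s\n", x$label,
              length(x$genes),
              ifelse(is.na(x$trait_cor), "NA", sprintf("%.3f", x$trait_cor))))
  invisible(x)
}

#' Curate a predictor panel by over-representation and MAS
#'
#' Per term, a one-sided hypergeometric p-value for over-representation of
#' the candidate genes in the universe; BH adjustment across terms. The
#' panel holds the candidates that belong to at least one enriched term
#' (`padj < term_alpha`) and have `mas > mas_threshold` (strict).
#'
#' @param candidates Candidate gene symbols (subset of `universe`).
#' @param universe Screened gene symbols.
#' @param term_sets Named list of term gene sets.
#' @param mas_results Named list of `mas_result`s (or a named numeric vector
#'   of MAS values) covering the candidates.
#' @param mas_threshold Strict lower bound on MAS (default 0.65).
#' @param term_alpha BH-adjusted significance for terms (default 0.05).
#' @return A `curation_result`: `panel`, `enriched_terms` data frame
#'   (`term`, `overlap`, `pvalue`, `padj`), `provenance` per candidate.
#' @export
overrepresentation_curate <- function(candidates, universe, term_sets,
                                      mas_results, mas_threshold = 0.65,
                                      term_alpha = 0.05) {
  assert_that(length(universe) > 0, "universe must be non-empty")
  universe <- unique(universe)
  candidates <- unique(candidates)
  assert_that(all(candidates %in% universe),
              "candidates must be a subset of the universe")
  mas <- if (is.numeric(mas_results)) mas_results
         else vapply(mas_results, function(m) m$mas, numeric(1))
  N <- length(universe)
  n_cand <- length(candidates)
  terms <- lapply(term_sets, intersect, y = universe)
  keep <- lengths(terms) > 0
  terms <- terms[keep]
  pvals <- vapply(terms, function(ts) {
    K <- length(ts)
    ov <- length(intersect(ts, candidates))
    stats::phyper(ov - 1, K, N - K, n_cand, lower.tail = FALSE)
  }, numeric(1))
  padj <- bh_adjust(pvals)
  overlap <- vapply(terms, function(ts) length(intersect(ts, candidates)),
                    integer(1))
  enriched <- data.frame(term = names(terms), overlap = overlap,
                         pvalue = pvals, padj = padj,
                         stringsAsFactors = FALSE, row.names = NULL)
  enriched <- enriched[order(enriched$pvalue, enriched$term), , drop = FALSE]
  sig_terms <- enriched$term[enriched$padj < term_alpha]
  in_term <- vapply(candidates, function(g) {
    any(vapply(terms[sig_terms], function(ts) g %in% ts, logical(1)))
  }, logical(1))
  gene_mas <- mas[candidates]
  pass_mas <- !is.na(gene_mas) & gene_mas > mas_threshold
  panel <- candidates[in_term & pass_mas]
  provenance <- data.frame(gene = candidates,
                           mas = unname(gene_mas),
                           in_enriched_term = unname(in_term),
                           stringsAsFactors = FALSE, row.names = NULL)
  structure(list(panel = panel,
                 enriched_terms = enriched[enriched$padj < term_alpha, ,
                                           drop = FALSE],
                 term_table = enriched,
                 provenance = provenance),
            class = "curation_result")
}

#' @export
print.curation_result <- function(x, ...) {
  cat("curation_result:", length(x$panel), "panel gene(s),",
      nrow(x$enriched_terms), "enriched term(s)\n")
  invisible(x)
}
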