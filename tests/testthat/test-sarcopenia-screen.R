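test_that("exact Mann-Whitney branch equals full enumeration", {
  mat <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 1,
                dimnames = list("g1", paste0("s", 1:6)))
  res <- mwu_screen(mat, rep(c("a", "b"), each = 3))
  expect_equal(res$u_statistic, 0)
  expect_equal(res$pvalue, 0.1)
  expect_true(res$exact)
  # identical groups give p = 1
  mat2 <- matrix(c(1, 2, 3, 1, 2, 3), nrow = 1,
                 dimnames = list("g1", paste0("s", 1:6)))
  res2 <- mwu_screen(mat2, rep(c("a", "b"), each = 3))
  expect_equal(res2$pvalue, 1)
  # random tie-free inputs across all splits with n1 + n2 <= 10
  set.seed(8)
  for (n1 in 3:5) {
    for (n2 in 3:min(5, 10 - n1)) {
      vals <- sample(1:100, n1 + n2)
      m <- matrix(vals, nrow = 1, dimnames = list("g", NULL))
      labels <- rep(c("a", "b"), c(n1, n2))
      got <- mwu_screen(m, labels)
      expect_equal(got$pvalue,
                   oracle_mwu_exact(vals[1:n1], vals[-(1:n1)]),
                   tolerance = 1e-12,
                   label = sprintf("exact p at n1=%d n2=%d", n1, n2))
    }
  }
})

test_that("normal-approximation branch stays close to the exact enumeration", {
  set.seed(15)
  for (rep_i in 1:5) {
    x <- rnorm(10); y <- rnorm(10, mean = 0.5)
    m <- matrix(c(x, y), nrow = 1, dimnames = list("g", NULL))
    labels <- rep(c("a", "b"), each = 10)
    approx_p <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    got <- mwu_screen(m, labels)
    expect_false(got$exact)  # n = 20 exceeds the exact-branch limit
    expect_equal(got$pvalue, approx_p)
    exact_p <- oracle_mwu_exact(x, y)
    expect_lt(abs(got$pvalue - exact_p), 0.01)
  }
})

test_that("mwu_screen validates group sizes and reports BH padj", {
  mat <- matrix(rnorm(40), nrow = 4, dimnames = list(paste0("g", 1:4), NULL))
  expect_error(mwu_screen(mat, rep(c("a", "b"), c(8, 2))), "3 samples")
  res <- mwu_screen(mat, rep(c("a", "b"), each = 5))
  expect_equal(res$padj, bh_adjust(res$pvalue))
  expect_equal(res$is_deg, res$pvalue < 0.05)
})

test_that("a perfectly separating gene attains MAS = 1", {
  set.seed(2)
  values <- c(rnorm(20, 0, 0.1), rnorm(20, 10, 0.1))
  labels <- rep(c("ctrl", "sarco"), each = 20)
  res <- mas_score(values, labels, seed = 3)
  expect_equal(res$mas, 1.0)
  expect_equal(res$mas, mean(res$fold_accuracies))
})

test_that("an uninformative gene scores near chance", {
  values <- rep(1, 40)
  labels <- rep(c("a", "b"), each = 20)
  res <- mas_score(values, labels, seed = 7)
  expect_gte(res$mas, 0.35)
  expect_lte(res$mas, 0.65)
})

test_that("mas_score is invariant under positive affine transforms", {
  set.seed(31)
  for (case in 1:13) {
    values <- rnorm(30, mean = rep(c(0, 1), each = 15))
    labels <- rep(c("a", "b"), each = 15)
    a <- runif(1, 0.1, 50); b <- runif(1, -20, 20)
    base <- mas_score(values, labels, repeats = 3, seed = case)$mas
    expect_equal(mas_score(a * values + b, labels, repeats = 3,
                           seed = case)$mas,
                 base, label = sprintf("case %d", case))
  }
})

test_that("mas_score enforces fold-size preconditions", {
  values <- rnorm(8)
  labels <- rep(c("a", "b"), each = 4)
  expect_error(mas_score(values, labels, folds = 5), "folds")
})

test_that("a planted module is recovered with a trait-correlated eigengene", {
  cohort <- generate_sarcopenia_cohort(n_genes = 200, n_per_group = 59,
                                       module_size = 30, module_cor = 0.8,
                                       n_predictors = 0, seed = 42)
  modules <- detect_modules(cohort$expression, trait = cohort$trait)
  real <- Filter(function(m) !m$unassigned, modules)
  expect_gte(length(real), 1)
  best <- real[[which.max(vapply(real, function(m) abs(m$trait_cor),
                                 numeric(1)))]]
  recovered <- length(intersect(best$genes, cohort$truth_module_genes)) /
    length(cohort$truth_module_genes)
  expect_gte(recovered, 0.8)
  expect_gte(abs(best$trait_cor), 0.8)
  expect_lt(abs(mean(best$eigengene)), 1e-10)
})

test_that("two independent planted modules are both recovered", {
  c1 <- generate_sarcopenia_cohort(n_genes = 100, n_per_group = 40,
                                   module_size = 20, module_cor = 0.8,
                                   n_predictors = 0, seed = 5)
  c2 <- generate_sarcopenia_cohort(n_genes = 100, n_per_group = 40,
                                   module_size = 20, module_cor = 0.8,
                                   n_predictors = 0, seed = 6)
  genes2 <- paste0("m2_", rownames(c2$expression))
  expr <- rbind(c1$expression, `rownames<-`(c2$expression, genes2))
  modules <- detect_modules(expr)
  real <- Filter(function(m) !m$unassigned, modules)
  expect_equal(length(real), 2)
  truth <- list(c1$truth_module_genes, paste0("m2_", c2$truth_module_genes))
  acc <- vapply(real, function(m) {
    max(vapply(truth, function(tg)
      length(intersect(m$genes, tg)) / length(union(m$genes, tg)),
      numeric(1)))
  }, numeric(1))
  expect_true(all(acc >= 0.8))
})

test_that("all-noise expression yields no trait-correlated module", {
  strong <- 0
  for (s in 1:30) {
    cohort <- generate_bulk(n_genes = 80, n_per_group = 30, de_fraction = 0,
                            seed = 100 + s)
    set.seed(200 + s)
    trait <- rnorm(60)
    modules <- detect_modules(cohort$expression, trait = trait)
    real <- Filter(function(m) !m$unassigned, modules)
    if (length(real) > 0 &&
        any(vapply(real, function(m) abs(m$trait_cor), numeric(1)) > 0.5)) {
      strong <- strong + 1
    }
  }
  expect_lte(strong / 30, 0.05)
})

test_that("the module eigengene explains at least any single gene's share", {
  cohort <- generate_sarcopenia_cohort(n_genes = 60, n_per_group = 30,
                                       module_size = 15, seed = 9)
  modules <- detect_modules(cohort$expression)
  m <- modules[[1]]
  sub <- cohort$expression[m$genes, , drop = FALSE]
  std <- t(scale(t(sub)))
  eig_var <- sum((std %*% m$eigengene)^2)
  for (gi in seq_len(nrow(std))) {
    u <- std[gi, ] / sqrt(sum(std[gi, ]^2))
    expect_lte(sum((std %*% u)^2), eig_var + 1e-8)
  }
})

test_that("zero-variance genes are dropped with a warning before clustering", {
  cohort <- generate_sarcopenia_cohort(n_genes = 40, n_per_group = 20, seed = 2,
                                       module_size = 15)
  expr <- cohort$expression
  expr["gene0040", ] <- 5
  expect_warning(modules <- detect_modules(expr), "zero-variance")
  expect_false("gene0040" %in% unlist(lapply(modules, `[[`, "genes")))
})

test_that("hypergeometric over-representation matches enumeration and closed form", {
  universe <- paste0("u", 1:20)
  term <- list(T1 = universe[1:5])
  candidates <- c(universe[1:4], universe[10])
  mas <- stats::setNames(rep(1, 5), candidates)
  res <- overrepresentation_curate(candidates, universe, term, mas,
                                   term_alpha = 1)
  expect_equal(res$term_table$pvalue,
               phyper(3, 5, 15, 5, lower.tail = FALSE))
  # enumeration oracle on a small universe
  universe2 <- paste0("v", 1:12)
  term2 <- list(T1 = universe2[1:4])
  cand2 <- c(universe2[1:2], universe2[5:7])
  res2 <- overrepresentation_curate(cand2, universe2, term2,
                                    stats::setNames(rep(1, 5), cand2),
                                    term_alpha = 1)
  expect_equal(res2$term_table$pvalue, oracle_hyper_tail(2, 4, 12, 5),
               tolerance = 1e-12)
  # candidates = universe makes every term p = 1
  res3 <- overrepresentation_curate(universe, universe, term,
                                    stats::setNames(rep(1, 20), universe),
                                    term_alpha = 1)
  expect_equal(res3$term_table$pvalue, 1)
})

test_that("the curated panel requires both an enriched term and MAS above threshold", {
  universe <- paste0("u", 1:30)
  term <- list(GOOD = universe[1:6])
  candidates <- universe[1:3]
  mas <- stats::setNames(c(0.7, 0.65, 0.6), candidates)
  res <- overrepresentation_curate(candidates, universe, term, mas,
                                   mas_threshold = 0.65, term_alpha = 0.05)
  expect_identical(res$panel, "u1")   # 0.65 fails the strict threshold
  expect_error(overrepresentation_curate("x", character(0), term, mas),
               "universe")
})

test_that("type-I error of the screen is near nominal on null cohorts", {
  cohort <- generate_bulk(n_genes = 1000, n_per_group = 20, de_fraction = 0,
                          seed = 77)
  res <- mwu_screen(cohort$expression, cohort$group_labels)
  rate <- mean(res$is_deg)
  # binomial tolerance around 0.05 over 1000 genes
  expect_gt(rate, 0.05 - 3 * sqrt(0.05 * 0.95 / 1000))
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / 1000))
})
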