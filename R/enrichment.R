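# Gene-set enrichment: frailty-pathway selection, weighted running-sum
# enrichment scores with gene-label permutation NES, BH adjustment, and
# direction summaries.

#' Rank genes by their test statistic
#'
#' Builds the ranked list used for enrichment: genes sorted by score
#' (descending), ties broken by gene symbol so the order is deterministic.
#' Duplicate genes keep their largest-magnitude score.
#'
#' @param genes Character vector of gene symbols.
#' @param scores Signed ranking statistic (e.g. the per-gene t-score).
#' @return Named numeric vector, sorted descending.
#' @export
rank_genes <- function(genes, scores) {
  assert_that(length(genes) == length(scores), "genes/scores length mismatch")
  assert_that(!any(is.na(scores)), "scores must not be missing")
  if (anyDuplicated(genes)) {
    keep <- !duplicated(genes[order(-abs(scores))])
    ord0 <- order(-abs(scores))[keep]
    genes <- genes[ord0]; scores <- scores[ord0]
  }
  ord <- order(-scores, genes)
  stats::setNames(scores[ord], genes[ord])
}

#' Select putative frailty pathways by biomarker membership
#'
#' Retains the gene sets containing at least `min_hits` biomarker genes.
#'
#' @param collection Named list of gene sets (see [read_gmt()]).
#' @param biomarkers Character vector of biomarker symbols.
#' @param min_hits Minimum biomarker members (default 2).
#' @return The retained collection with attributes `biomarker_hits`
#'   (named integer, all retained sets) and `frailty_flag` (all `TRUE`).
#' @export
select_frailty_pathways <- function(collection, biomarkers, min_hits = 2) {
  assert_that(length(biomarkers) > 0, "biomarkers must be non-empty")
  if (length(collection) == 0) {
    out <- collection
    attr(out, "biomarker_hits") <- integer(0)
    return(out)
  }
  hits <- vapply(collection, function(s) length(intersect(s, biomarkers)),
                 integer(1))
  keep <- hits >= min_hits
  out <- collection[keep]
  attr(out, "biomarker_hits") <- hits[keep]
  attr(out, "frailty_flag") <- stats::setNames(rep(TRUE, sum(keep)),
                                               names(collection)[keep])
  class(out) <- "gene_set_collection"
  out
}

# Running-sum enrichment score from hit positions in a ranked list.
# Hits increment by |score|^weight / sum(|score|^weight over the set);
# misses decrement by 1/(N - k). Only positions adjacent to hits can be the
# extremum, so the score is computed from the k hit positions directly.
# Returns list(es, extremum_index).
es_from_positions <- function(positions, abs_scores_w, N) {
  k <- length(positions)
  positions <- sort(positions)
  w <- abs_scores_w[positions]
  denom <- sum(w)
  hit_cum <- if (denom > 0) cumsum(w) / denom else cumsum(rep(1 / k, k))
  miss_step <- 1 / (N - k)
  # running sum immediately after hit i, and immediately before hit i
  after <- hit_cum - (positions - seq_len(k)) * miss_step
  before <- c(0, hit_cum[-k]) - (positions - seq_len(k)) * miss_step
  hi <- max(after); lo <- min(before)
  # the positive extremum wins magnitude ties (tolerance absorbs rounding)
  if (hi >= -lo - 1e-12) {
    list(es = hi, extremum = positions[which.max(after)])
  } else {
    list(es = lo, extremum = positions[which.min(before)])
  }
}

#' Enrichment score of one gene set on a ranked list
#'
#' The signed maximum-magnitude deviation of the weighted running sum:
#' hits increment by `|score|^weight / sum_set |score|^weight`, misses
#' decrement by `1 / (N - k)`.
#'
#' @param ranked Named numeric vector sorted descending.
#' @param set Character vector of member genes.
#' @param weight Exponent on `|score|` (default 1).
#' @return List with `es`, `extremum` (rank position of the extremum) and
#'   `leading_edge`.
#' @export
gsea_es <- function(ranked, set, weight = 1) {
  pos <- which(names(ranked) %in% set)
  assert_that(length(pos) >= 1, "set does not intersect the ranked list")
  assert_that(length(pos) < length(ranked),
              "set must not cover the whole ranked list")
  obs <- es_from_positions(pos, abs(ranked)^weight, length(ranked))
  le <- if (obs$es >= 0) names(ranked)[pos[pos <= obs$extremum]]
        else names(ranked)[pos[pos >= obs$extremum]]
  list(es = obs$es, extremum = obs$extremum, leading_edge = le)
}

#' Gene-set enrichment with permutation-normalized scores
#'
#' For each set, the enrichment score (ES) is the maximum-magnitude
#' deviation of a weighted running sum over the ranked list. The null is a
#' gene-label permutation: per permutation, `k` genes are drawn uniformly
#' without replacement. NES divides ES by the mean magnitude of same-sign
#' permuted scores; the p-value is
#' `(1 + # same-sign permutations at least as extreme) / (1 + # same-sign)`.
#' BH adjustment runs across all scored sets. Sets intersecting the ranked
#' list in fewer than `min_size` genes are skipped with a warning, as are
#' sets larger than the ranked list. When no same-sign permutation exists,
#' NES and p are reported missing and excluded from BH.
#'
#' @param ranked Named numeric vector sorted descending (see
#'   [rank_genes()]).
#' @param collection Named list of gene sets.
#' @param weight Exponent on `|score|` for hit increments (default 1).
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed for the permutation draw.
#' @param min_size Minimum set/ranked-list intersection (default 2; 1 is
#'   permitted for single-gene reference cases).
#' @return Data frame with `set`, `size`, `es`, `nes`, `pvalue`, `padj`,
#'   `leading_edge` (list column).
#' @export
gsea_enrichment <- function(ranked, collection, weight = 1, n_perm = 1000,
                            seed = 1, min_size = 2) {
  assert_that(length(ranked) >= 3, "ranked list must hold at least 3 genes")
  assert_that(!is.null(names(ranked)), "ranked list must be named")
  assert_that(!anyDuplicated(names(ranked)), "ranked list has duplicate genes")
  assert_that(all(diff(ranked) <= 0), "ranked scores must be sorted descending")
  assert_that(is_count(n_perm, 100), "n_perm must be an integer >= 100")
  N <- length(ranked)
  abs_w <- abs(ranked)^weight
  sizes <- vapply(collection, function(s) sum(names(ranked) %in% s), integer(1))
  skip <- sizes < min_size | sizes >= N
  if (any(skip)) {
    warning("skipping ", sum(skip), " set(s) with ranked-list intersection < ",
            min_size, " or >= ranked-list length", call. = FALSE)
  }
  scored <- names(collection)[!skip]
  # one permutation pool per distinct intersection size
  perm_es <- new.env(parent = emptyenv())
  perm_for_size <- function(k) {
    key <- as.character(k)
    if (is.null(perm_es[[key]])) {
      perm_es[[key]] <- with_seed(child_seed(seed, k), {
        vapply(seq_len(n_perm), function(i) {
          es_from_positions(sample.int(N, k), abs_w, N)$es
        }, numeric(1))
      })
    }
    perm_es[[key]]
  }
  rows <- lapply(scored, function(nm) {
    obs <- gsea_es(ranked, collection[[nm]], weight = weight)
    k <- sum(names(ranked) %in% collection[[nm]])
    perms <- perm_for_size(k)
    same <- if (obs$es >= 0) perms[perms >= 0] else perms[perms < 0]
    if (length(same) == 0 || mean(abs(same)) == 0) {
      nes <- NA_real_; pval <- NA_real_
    } else {
      nes <- obs$es / mean(abs(same))
      pval <- (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
    }
    list(set = nm, size = k, es = obs$es, nes = nes, pvalue = pval,
         leading_edge = obs$leading_edge)
  })
  res <- data.frame(
    set = vapply(rows, `[[`, character(1), "set"),
    size = vapply(rows, `[[`, numeric(1), "size"),
    es = vapply(rows, `[[`, numeric(1), "es"),
    nes = vapply(rows, `[[`, numeric(1), "nes"),
    pvalue = vapply(rows, `[[`, numeric(1), "pvalue"),
    stringsAsFactors = FALSE
  )
  res$padj <- NA_real_
  ok <- !is.na(res$pvalue)
  res$padj[ok] <- bh_adjust(res$pvalue[ok])
  res$leading_edge <- lapply(rows, `[[`, "leading_edge")
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted values, clipped to 1, order-preserving with the input.
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @return Adjusted values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  assert_that(is.numeric(pvalues), "pvalues must be numeric")
  assert_that(!any(is.na(pvalues)) && all(pvalues >= 0 & pvalues <= 1),
              "pvalues must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Summarize enrichment directions
#'
#' Fractions of sets increased (`padj < padj_cut`, `nes > 0`), decreased
#' (`padj < padj_cut`, `nes < 0`) and stable (the remainder, including sets
#' with missing NES).
#'
#' @param results Data frame from [gsea_enrichment()].
#' @param padj_cut Reporting cut on the adjusted p-value (default 0.3).
#' @return Named numeric vector `(increased, decreased, stable)` summing
#'   to 1.
#' @export
direction_summary <- function(results, padj_cut = 0.3) {
  assert_that(is.data.frame(results) && nrow(results) > 0,
              "results must be a non-empty data frame")
  sig <- !is.na(results$padj) & results$padj < padj_cut
  inc <- mean(sig & results$nes > 0, na.rm = FALSE)
  dec <- mean(sig & results$nes < 0, na.rm = FALSE)
  inc[is.na(inc)] <- 0; dec[is.na(dec)] <- 0
  c(increased = inc, decreased = dec, stable = 1 - inc - dec)
}
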