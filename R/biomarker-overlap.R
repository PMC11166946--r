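# Frailty-biomarker handling: ortholog translation, adjusted-p DEG
# filtering, and cross-dataset / cross-species overlap partitioning.

#' Translate gene symbols across species
#'
#' Exact, case-sensitive symbol lookup against a biomarker mapping table.
#'
#' @param symbols Character vector of gene symbols.
#' @param table Mapping table (see [read_biomarker_table()]).
#' @param direction `"human_to_mouse"` or `"mouse_to_human"`.
#' @return List with `mapped` (translated symbols, input order, unmapped
#'   dropped) and `unmapped` (input symbols without a table entry).
#' @export
map_orthologs <- function(symbols, table = frailty_biomarkers(),
                          direction = c("human_to_mouse", "mouse_to_human")) {
  direction <- match.arg(direction)
  assert_that(is.data.frame(table) && nrow(table) > 0,
              "biomarker table is empty")
  from <- if (direction == "human_to_mouse") table$human_symbol else table$mouse_symbol
  to <- if (direction == "human_to_mouse") table$mouse_symbol else table$human_symbol
  idx <- match(symbols, from)
  list(mapped = to[idx[!is.na(idx)]],
       unmapped = symbols[is.na(idx)])
}

#' Filter DEG records to frailty biomarkers under an adjusted-p cutoff
#'
#' Keeps records whose gene is a biomarker for the record's species and
#' whose `padj` is strictly below the cutoff. Records with missing `padj`
#' are excluded with a warning. Duplicate genes within one dataset keep the
#' record with the smallest `padj`.
#'
#' @param table DEG data frame (see [read_de_table()]); needs a `species`
#'   column or the `species` argument.
#' @param biomarkers Biomarker mapping table.
#' @param padj_cutoff Strict upper bound on `padj` (default 0.5).
#' @param species Species override when the table has no `species` column.
#' @return Filtered DEG data frame, original fields preserved.
#' @export
filter_frailty_degs <- function(table, biomarkers = frailty_biomarkers(),
                                padj_cutoff = 0.5, species = NULL) {
  if (nrow(table) == 0) return(table)
  if (is.null(table$species)) {
    assert_that(!is.null(species), "species must be given (column or argument)")
    table$species <- match.arg(species, c("human", "mouse"))
  }
  assert_that(all(table$species %in% c("human", "mouse")),
              "species must be 'human' or 'mouse'")
  symbol_col <- ifelse(table$species == "human", "human_symbol", "mouse_symbol")
  is_biomarker <- vapply(seq_len(nrow(table)), function(i) {
    table$gene[i] %in% biomarkers[[symbol_col[i]]]
  }, logical(1))
  na_padj <- is_biomarker & is.na(table$padj)
  if (any(na_padj)) {
    warning(sum(na_padj), " biomarker record(s) excluded: missing padj",
            call. = FALSE)
  }
  keep <- is_biomarker & !is.na(table$padj) & table$padj < padj_cutoff
  out <- table[keep, , drop = FALSE]
  if (nrow(out) > 1) {
    ds <- if (is.null(out$dataset)) rep("", nrow(out)) else out$dataset
    ord <- order(ds, out$gene, out$padj)
    out <- out[ord, , drop = FALSE]
    out <- out[!duplicated(paste(ds[ord], out$gene)), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Partition named gene sets into disjoint overlap compartments
#'
#' Enumerates every non-empty label combination (the compartments of a Venn
#' or upset plot). Compartments are pairwise disjoint and their union equals
#' the union of the input sets.
#'
#' @param named_sets Named list (>= 2 labels) of character vectors.
#' @return An `overlap_partition`: list with `sets`, `compartments` (named
#'   by `label1&label2&...`), `counts`, and for exactly two labels also
#'   `shared`/`only` aliases.
#' @export
overlap_partition <- function(named_sets) {
  assert_that(is.list(named_sets) && length(named_sets) >= 2,
              "need at least two named sets")
  assert_that(!is.null(names(named_sets)) && all(nzchar(names(named_sets))),
              "sets must be named")
  assert_that(all(lengths(named_sets) > 0), "sets must be non-empty")
  named_sets <- lapply(named_sets, unique)
  labels <- names(named_sets)
  genes <- sort(unique(unlist(named_sets)))
  membership <- vapply(named_sets, function(s) genes %in% s,
                       logical(length(genes)))
  if (length(genes) == 1) membership <- matrix(membership, nrow = 1,
                                               dimnames = list(NULL, labels))
  key <- apply(membership, 1, function(m) paste(labels[m], collapse = "&"))
  compartments <- split(genes, key)
  # order compartments by label combination (singletons first, then pairs...)
  n_labels <- lengths(strsplit(names(compartments), "&", fixed = TRUE))
  compartments <- compartments[order(n_labels, names(compartments))]
  out <- list(sets = named_sets,
              compartments = compartments,
              counts = lengths(compartments))
  if (length(labels) == 2) {
    shared_key <- paste(labels, collapse = "&")
    out$shared <- compartments[[shared_key]] %||% character(0)
    out$only <- stats::setNames(
      lapply(labels, function(l) compartments[[l]] %||% character(0)), labels)
  }
  structure(out, class = "overlap_partition")
}

#' @export
print.overlap_partition <- function(x, ...) {
  cat("overlap_partition over", length(x$sets), "sets\n")
  print(x$counts)
  invisible(x)
}

#' Integer percentages of partition compartments
#'
#' Percent of each compartment relative to the sum of the disjoint
#' compartment counts, rounded half-up to whole percent. The denominator is
#' the compartment-count sum (equivalently, the size of the union); when a
#' nominal total differing from that sum is supplied it is echoed in the
#' `nominal_total` attribute but never used in the computation.
#'
#' @param partition An `overlap_partition`, or a named numeric vector of
#'   compartment counts.
#' @param nominal_total Optional externally stated total, recorded only.
#' @return Named integer vector of percentages with attributes
#'   `denominator` and (if given) `nominal_total`.
#' @export
partition_percentages <- function(partition, nominal_total = NULL) {
  counts <- if (inherits(partition, "overlap_partition")) partition$counts
            else partition
  assert_that(is.numeric(counts) && length(counts) >= 1 && all(counts >= 0),
              "counts must be non-negative numbers")
  total <- sum(counts)
  assert_that(total >= 1, "partition is empty")
  pct <- round_half_up(100 * counts / total)
  pct <- stats::setNames(as.integer(pct), names(counts))
  attr(pct, "denominator") <- total
  if (!is.null(nominal_total)) attr(pct, "nominal_total") <- nominal_total
  pct
}
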