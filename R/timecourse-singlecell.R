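# Astronaut time-course summarization / trajectory classification and
# single-cell frailty-gene summaries.

# Parse mission-time labels: "L-92" (pre), "L+14" (flight), "R+1" (post).
# Returns data.frame(label, phase, time) ordered by mission time.
parse_timepoints <- function(labels) {
  assert_that(all(grepl("^[LR][+-][0-9]+$", labels) | labels == "pre-flight baseline"),
              "timepoint labels must look like L-92, L+14 or R+1")
  phase <- ifelse(grepl("^L-", labels), "pre",
                  ifelse(grepl("^L\\+", labels), "flight", "post"))
  num <- as.numeric(sub("^[LR][+-]", "", labels))
  time <- ifelse(phase == "pre", -num,
                 ifelse(phase == "flight", num, 1e6 + num))
  data.frame(label = labels, phase = phase, time = time,
             stringsAsFactors = FALSE)
}

#' Summarize a subject-by-timepoint series into a time-course matrix
#'
#' Averages expression across subjects per timepoint (missing values are
#' excluded from the mean), then pools the three pre-flight timepoints into
#' a single `pre-flight baseline` column.
#'
#' @param values Gene-by-column matrix with columns named
#'   `subject_timepoint` (or any names matched by `labels$sample`).
#' @param labels Data frame with `sample`, `subject`, `timepoint`
#'   (timepoints as `L-n` pre-flight, `L+n` in-flight, `R+n` post-flight).
#' @return A `timecourse_matrix`: `values` (gene x timepoint, baseline
#'   first), `timepoints` (label/phase/time), `n_subjects`.
#' @export
summarize_timecourse <- function(values, labels) {
  assert_that(is.matrix(values), "values must be a matrix")
  assert_that(all(c("sample", "subject", "timepoint") %in% names(labels)),
              "labels needs columns sample, subject, timepoint")
  assert_that(all(colnames(values) %in% labels$sample),
              "every column must be described in labels")
  tp_info <- parse_timepoints(unique(labels$timepoint))
  tp_info <- tp_info[order(tp_info$time), , drop = FALSE]
  assert_that(sum(tp_info$phase == "pre") == 3,
              "exactly three pre-flight timepoints are expected")
  assert_that(any(tp_info$phase == "flight") && any(tp_info$phase == "post"),
              "need at least one in-flight and one post-flight timepoint")
  col_tp <- labels$timepoint[match(colnames(values), labels$sample)]
  per_tp <- vapply(tp_info$label, function(tp) {
    sub <- values[, col_tp == tp, drop = FALSE]
    m <- rowMeans(sub, na.rm = TRUE)
    if (any(!is.finite(m))) {
      stop_invalid("timepoint ", tp, " has zero non-missing subjects for ",
                   "some gene")
    }
    m
  }, numeric(nrow(values)))
  if (nrow(values) == 1) per_tp <- matrix(per_tp, nrow = 1,
                                          dimnames = list(rownames(values),
                                                          tp_info$label))
  pre_cols <- tp_info$label[tp_info$phase == "pre"]
  baseline <- rowMeans(per_tp[, pre_cols, drop = FALSE])
  keep <- tp_info$phase != "pre"
  out_vals <- cbind(`pre-flight baseline` = baseline,
                    per_tp[, tp_info$label[keep], drop = FALSE])
  out_tp <- rbind(
    data.frame(label = "pre-flight baseline", phase = "pre",
               time = min(tp_info$time) , stringsAsFactors = FALSE),
    tp_info[keep, , drop = FALSE]
  )
  rownames(out_tp) <- NULL
  structure(list(values = out_vals, timepoints = out_tp,
                 n_subjects = length(unique(labels$subject))),
            class = "timecourse_matrix")
}

#' @export
print.timecourse_matrix <- function(x, ...) {
  cat("timecourse_matrix:", nrow(x$values), "genes x", ncol(x$values),
      "timepoints (", x$n_subjects, "subjects averaged )\n")
  invisible(x)
}

#' Classify per-gene expression trajectories
#'
#' Directions relative to the pooled pre-flight baseline: the in-flight
#' (post-flight) direction compares the mean of flight-phase (post-phase)
#' values against `baseline * (1 +/- delta)`; `returned_to_baseline` checks
#' only the final post-flight value against `delta * baseline`. When a
#' gene's baseline is not positive, the same `delta` is applied as an
#' absolute difference threshold.
#'
#' @param tc A `timecourse_matrix` (see [summarize_timecourse()]).
#' @param delta Relative threshold (default 0.2).
#' @return Data frame with `gene`, `inflight_direction`,
#'   `postflight_direction`, `returned_to_baseline`, `delta`.
#' @export
classify_trajectories <- function(tc, delta = 0.2) {
  assert_that(inherits(tc, "timecourse_matrix"), "tc must be a timecourse_matrix")
  assert_that(delta >= 0, "delta must be non-negative")
  vals <- tc$values
  phase <- tc$timepoints$phase
  baseline <- vals[, 1]
  flight_mean <- if (any(phase == "flight")) {
    rowMeans(vals[, phase == "flight", drop = FALSE])
  } else rep(NA_real_, nrow(vals))
  post_cols <- which(phase == "post")
  post_mean <- rowMeans(vals[, post_cols, drop = FALSE])
  final_post <- vals[, post_cols[length(post_cols)]]
  direction <- function(value, base) {
    if (is.na(value)) return(NA_character_)
    tolerance <- if (base > 0) delta * base else delta
    if (value < base - tolerance) "down"
    else if (value > base + tolerance) "up"
    else "stable"
  }
  out <- data.frame(
    gene = rownames(vals),
    inflight_direction = vapply(seq_len(nrow(vals)), function(i)
      direction(flight_mean[i], baseline[i]), character(1)),
    postflight_direction = vapply(seq_len(nrow(vals)), function(i)
      direction(post_mean[i], baseline[i]), character(1)),
    returned_to_baseline = vapply(seq_len(nrow(vals)), function(i) {
      tolerance <- if (baseline[i] > 0) delta * baseline[i] else delta
      abs(final_post[i] - baseline[i]) <= tolerance
    }, logical(1)),
    delta = delta,
    stringsAsFactors = FALSE, row.names = NULL
  )
  out
}

#' Summarize single-cell expression per cell type and timepoint
#'
#' Counts are normalized per cell to the median library size and
#' log1p-transformed. Per (gene, cell type, timepoint) the summary reports
#' the mean normalized expression and the percentage of expressing cells.
#' Genes are classed per cell type at `R+1` (the spaceflight condition)
#' against pooled pre-flight cells: increased when the log2 fold change of
#' the normalized means is `>= lfc_threshold` and the gene is expressed in
#' at least `min_pct` percent of cells in either condition; decreased
#' symmetrically; stable otherwise. Class percentages are reported for the
#' panel and for all genes (background).
#'
#' @param counts Cell-by-gene count matrix (integers >= 0).
#' @param cell_type,timepoint Per-cell labels; timepoints are `pre-flight`
#'   (or any `L-n`), `R+1`, and later `R+n` values.
#' @param panel Gene panel to contrast against the background (default all
#'   genes). Absent panel genes are reported in the `missing_panel_genes`
#'   attribute, not fatal.
#' @param lfc_threshold Absolute log2 fold-change gate (default 0.25).
#' @param min_pct Percent-expressing gate (default 10).
#' @return A `celltype_summary`: `per_timepoint` data frame (gene,
#'   cell_type, timepoint, mean_expression, pct_expressing), `classes`
#'   data frame (gene, cell_type, class), and `percentages` data frame
#'   (cell_type, scope, increased, decreased, stable).
#' @export
summarize_singlecell <- function(counts, cell_type, timepoint, panel = NULL,
                                 lfc_threshold = 0.25, min_pct = 10) {
  assert_that(is.matrix(counts) && !is.null(colnames(counts)),
              "counts must be a cell x gene matrix with gene colnames")
  assert_that(all(counts >= 0) && all(counts == floor(counts)),
              "counts must be non-negative integers")
  assert_that(length(cell_type) == nrow(counts) &&
                length(timepoint) == nrow(counts),
              "cell_type/timepoint must have one entry per cell")
  genes <- colnames(counts)
  panel <- panel %||% genes
  missing_panel <- setdiff(panel, genes)
  panel <- intersect(panel, genes)
  tp_norm <- ifelse(grepl("^L-", timepoint) | timepoint == "pre-flight",
                    "pre-flight", timepoint)
  lib <- rowSums(counts)
  lib[lib == 0] <- 1
  norm <- counts / lib * stats::median(rowSums(counts))
  logn <- log1p(norm)
  combos <- unique(data.frame(cell_type = cell_type, timepoint = tp_norm,
                              stringsAsFactors = FALSE))
  combos <- combos[order(combos$cell_type, combos$timepoint), , drop = FALSE]
  per_tp <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    sel <- cell_type == combos$cell_type[i] & tp_norm == combos$timepoint[i]
    data.frame(gene = genes,
               cell_type = combos$cell_type[i],
               timepoint = combos$timepoint[i],
               mean_expression = colMeans(logn[sel, , drop = FALSE]),
               mean_norm = colMeans(norm[sel, , drop = FALSE]),
               pct_expressing = 100 * colMeans(counts[sel, , drop = FALSE] > 0),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  types <- unique(cell_type)
  classable <- vapply(types, function(ct) {
    any(cell_type == ct & tp_norm == "pre-flight") &&
      any(cell_type == ct & tp_norm == "R+1")
  }, logical(1))
  if (any(!classable)) {
    warning("cell type(s) without both pre-flight and R+1 cells excluded ",
            "from classification: ", paste(types[!classable], collapse = ", "),
            call. = FALSE)
  }
  classes <- do.call(rbind, lapply(types[classable], function(ct) {
    pre <- per_tp[per_tp$cell_type == ct & per_tp$timepoint == "pre-flight", ]
    r1 <- per_tp[per_tp$cell_type == ct & per_tp$timepoint == "R+1", ]
    pre <- pre[match(genes, pre$gene), ]
    r1 <- r1[match(genes, r1$gene), ]
    lfc <- log2((r1$mean_norm + 1) / (pre$mean_norm + 1))
    pct_ok <- pmax(pre$pct_expressing, r1$pct_expressing) >= min_pct
    cls <- ifelse(lfc >= lfc_threshold & pct_ok, "increased",
                  ifelse(lfc <= -lfc_threshold & pct_ok, "decreased", "stable"))
    data.frame(gene = genes, cell_type = ct, log2fc = lfc, class = cls,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  pct_table <- function(cls_sub, scope, ct) {
    n <- nrow(cls_sub)
    inc <- 100 * sum(cls_sub$class == "increased") / n
    dec <- 100 * sum(cls_sub$class == "decreased") / n
    data.frame(cell_type = ct, scope = scope, increased = inc,
               decreased = dec, stable = 100 - inc - dec,
               stringsAsFactors = FALSE)
  }
  percentages <- do.call(rbind, lapply(types[classable], function(ct) {
    sub <- classes[classes$cell_type == ct, ]
    rbind(pct_table(sub[sub$gene %in% panel, , drop = FALSE], "panel", ct),
          pct_table(sub, "background", ct))
  }))
  structure(list(per_timepoint = per_tp[, c("gene", "cell_type", "timepoint",
                                            "mean_expression", "pct_expressing")],
                 classes = classes,
                 percentages = percentages,
                 missing_panel_genes = missing_panel,
                 lfc_threshold = lfc_threshold, min_pct = min_pct),
            class = "celltype_summary")
}

#' @export
print.celltype_summary <- function(x, ...) {
  cat("celltype_summary:", length(unique(x$classes$cell_type)),
      "cell types classified at R+1 vs pre-flight\n")
  print(x$percentages)
  invisible(x)
}
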