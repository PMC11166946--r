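# Delimited-text readers and writers for every pipeline input/output format.

#' Read a differential-expression table
#'
#' Reads a delimited text file with header columns `gene`, `log2fc`,
#' `pvalue`, `padj`, `tscore`; extra columns are preserved. Dataset, species
#' and tissue tags are attached as columns when supplied.
#'
#' @param path Path to a delimited text file.
#' @param dataset,species,tissue Optional tags recorded per record. `species`
#'   must be `"human"` or `"mouse"` when given.
#' @param sep Field separator (default tab).
#' @return A `data.frame` of DEG records.
#' @export
read_de_table <- function(path, dataset = NULL, species = NULL, tissue = NULL,
                          sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("gene", "log2fc", "pvalue", "padj")
  missing_cols <- setdiff(required, names(df))
  assert_that(length(missing_cols) == 0,
              "DE table is missing columns: ", paste(missing_cols, collapse = ", "))
  assert_that(all(nzchar(df$gene)), "DE table contains empty gene symbols")
  if (!is.null(dataset)) df$dataset <- dataset
  if (!is.null(species)) {
    species <- match.arg(species, c("human", "mouse"))
    df$species <- species
  }
  if (!is.null(tissue)) df$tissue <- tissue
  df
}

#' Write a differential-expression table
#'
#' @param df Data frame of DEG records (see [read_de_table()]).
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_de_table <- function(df, path, sep = "\t") {
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-by-sample expression matrix
#'
#' Genes are rows; the header holds sample identifiers; the first column
#' holds gene symbols.
#'
#' @param path Path to a delimited text file.
#' @param sep Field separator.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_matrix <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          stringsAsFactors = FALSE, check.names = FALSE)
  as.matrix(df)
}

#' Write a gene-by-sample expression matrix
#'
#' @param mat Numeric matrix, genes as rows.
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_expression_matrix <- function(mat, path, sep = "\t") {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' GMT is tab-delimited: set name, description, then member genes. Empty
#' member fields are dropped.
#'
#' @param path Path to a `.gmt` file.
#' @return A `gene_set_collection`: named list of character vectors with a
#'   `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  assert_that(!anyDuplicated(names(sets)), "duplicate set names in GMT file")
  assert_that(all(lengths(sets) > 0), "GMT file contains an empty gene set")
  attr(sets, "description") <- vapply(parts, `[`, character(1), 2L)
  class(sets) <- "gene_set_collection"
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets Named list of character vectors (or `gene_set_collection`).
#' @param path Output path.
#' @param description Per-set description column; recycled.
#' @export
write_gmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection with", length(x), "sets;",
      "sizes", paste(range(lengths(x)), collapse = "-"), "\n")
  invisible(x)
}

#' Read a cross-species biomarker mapping table
#'
#' Four delimited columns: `mouse_symbol`, `mouse_id`, `human_symbol`,
#' `human_id`. The packaged default is the curated frailty biomarker list.
#'
#' @param path Path to the table; defaults to the bundled frailty biomarkers.
#' @param sep Field separator.
#' @return A `data.frame` with the four mapping columns.
#' @export
read_biomarker_table <- function(path = NULL, sep = "\t") {
  if (is.null(path)) {
    path <- system.file("extdata", "frailty_biomarkers.tsv",
                        package = "spacefrail", mustWork = TRUE)
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  required <- c("mouse_symbol", "mouse_id", "human_symbol", "human_id")
  missing_cols <- setdiff(required, names(df))
  assert_that(length(missing_cols) == 0,
              "biomarker table is missing columns: ",
              paste(missing_cols, collapse = ", "))
  assert_that(all(nzchar(df$mouse_symbol)) && all(nzchar(df$human_symbol)),
              "biomarker table has empty symbols")
  assert_that(!anyDuplicated(df$mouse_symbol) && !anyDuplicated(df$human_symbol),
              "biomarker symbols must be unique within each species column")
  df
}

#' The bundled frailty biomarker table
#'
#' Curated human/mouse frailty biomarker gene symbols with Ensembl
#' identifiers, used as the default ortholog mapping and biomarker list.
#'
#' @return A `data.frame`; see [read_biomarker_table()].
#' @export
frailty_biomarkers <- function() {
  read_biomarker_table()
}

#' Write per-cell metadata
#'
#' @param meta Data frame with at least `cell`, `cell_type`, `timepoint`.
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_cell_metadata <- function(meta, path, sep = "\t") {
  required <- c("cell", "cell_type", "timepoint")
  assert_that(all(required %in% names(meta)),
              "cell metadata needs columns: ", paste(required, collapse = ", "))
  utils::write.table(meta, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read single-cell counts from matrix-market or delimited text
#'
#' @param path `.mtx` file (cells x genes, with `path.genes`/`path.cells`
#'   sidecar name files accepted via `genes`/`cells`) or a delimited matrix
#'   with cell rows and a header of gene names.
#' @param genes,cells Optional paths to row/column name files for `.mtx`.
#' @param sep Field separator for the delimited branch.
#' @return A base matrix, cells as rows.
#' @export
read_sc_counts <- function(path, genes = NULL, cells = NULL, sep = "\t") {
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    if (!is.null(cells)) rownames(m) <- readLines(cells)
    if (!is.null(genes)) colnames(m) <- readLines(genes)
    return(m)
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          stringsAsFactors = FALSE, check.names = FALSE)
  as.matrix(df)
}
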