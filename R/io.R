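#' Read a gene-by-sample expression table with sample metadata
#'
#' Expression tables are tab-separated with a header row of sample
#' identifiers and a first column `gene`; values are log2 intensities.
#' Metadata maps each sample to a WHO grade (`NORMAL`, `PA1`, `AS2`,
#' `AS3`, `GBM4`) and an optional cohort tag.
#'
#' @param path Path to the expression TSV.
#' @param metadata_path Path to the metadata TSV (columns `sample`,
#'   `grade`, optional `cohort`).
#' @return A list with elements `expr` (wide tibble, `gene` column first)
#'   and `metadata` (tibble). Samples present in the expression table but
#'   absent from the metadata raise a consistency error; duplicated genes
#'   or non-numeric cells raise a format error.
#' @export
read_expression <- function(path, metadata_path) {
  expr <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(expr)[1] != "gene") names(expr)[1] <- "gene"
  expr$gene <- as.character(expr$gene)
  metadata <- readr::read_tsv(metadata_path, show_col_types = FALSE,
                              progress = FALSE)
  metadata$sample <- as.character(metadata$sample)
  expr_to_matrix(expr)          # validates genes + numeric cells
  check_metadata(expr, metadata)
  # keep only samples with metadata, in file order
  keep <- intersect(names(expr), c("gene", metadata$sample))
  list(expr = expr[keep],
       metadata = metadata[metadata$sample %in% names(expr), , drop = FALSE])
}

#' Write an expression tibble (and optional metadata) to TSV
#'
#' @param expr Wide expression tibble with a `gene` column.
#' @param path Output TSV path.
#' @param metadata Optional metadata tibble written next to it.
#' @param metadata_path Output path for the metadata TSV.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, metadata = NULL,
                             metadata_path = NULL) {
  readr::write_tsv(expr, path, progress = FALSE)
  if (!is.null(metadata)) {
    stopifnot(!is.null(metadata_path))
    readr::write_tsv(metadata, metadata_path, progress = FALSE)
  }
  invisible(path)
}

#' Convert log2 expression to tumor-versus-reference log-ratios
#'
#' For every tumor sample `d` and gene `g` the log-ratio is
#' `expr[g, d] - mean(expr[g, reference samples])`, i.e. the log2 ratio of
#' the tumor expression to the average of the designated reference grade.
#' Reference samples are dropped from the output.
#'
#' @param expr Wide expression tibble (`gene` column + sample columns).
#' @param metadata Sample metadata tibble (`sample`, `grade`).
#' @param reference_grade Grade whose samples form the reference
#'   (default `"NORMAL"`).
#' @return Wide tibble of log-ratios for the non-reference samples, same
#'   gene order as the input.
#' @export
to_log_ratios <- function(expr, metadata, reference_grade = "NORMAL") {
  check_metadata(expr, metadata)
  m <- expr_to_matrix(expr)
  refs <- samples_of_grade(metadata, reference_grade, colnames(m))
  if (length(refs) == 0) {
    abort_astro(paste0("no samples with reference grade ", reference_grade),
                "astronet_consistency_error")
  }
  tumors <- setdiff(colnames(m), refs)
  ref_mean <- rowMeans(m[, refs, drop = FALSE])
  lr <- m[, tumors, drop = FALSE] - ref_mean
  matrix_to_expr(lr)
}

#' Read or write a regulatory-network edge list
#'
#' Edge lists are TSVs with columns `tf`, `target`, `coefficient`,
#' `sign` (`activator` or `repressor`) and `p_value`. The sign label must
#' agree with the sign of the coefficient.
#'
#' @param network An `astro_network` object or an edge tibble.
#' @param path TSV path.
#' @return `read_edge_list()` returns the edge tibble;
#'   `write_edge_list()` returns `path` invisibly.
#' @export
write_edge_list <- function(network, path) {
  edges <- if (inherits(network, "astro_network")) network$edges else network
  edges <- edges[c("tf", "target", "coefficient", "sign", "p_value")]
  check_edge_signs(edges)
  readr::write_tsv(edges, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  edges <- readr::read_tsv(
    path, progress = FALSE,
    col_types = readr::cols(
      tf = readr::col_character(),
      target = readr::col_character(),
      coefficient = readr::col_double(),
      sign = readr::col_character(),
      p_value = readr::col_double()
    )
  )
  check_edge_signs(edges)
  edges
}

check_edge_signs <- function(edges) {
  bad <- (edges$sign == "activator" & edges$coefficient <= 0) |
    (edges$sign == "repressor" & edges$coefficient >= 0) |
    !(edges$sign %in% c("activator", "repressor"))
  if (any(bad)) {
    abort_astro(
      paste0("edge sign label inconsistent with coefficient for: ",
             paste(paste0(edges$tf[bad], "->", edges$target[bad]),
                   collapse = ", ")),
      "astronet_consistency_error"
    )
  }
  invisible(TRUE)
}

#' Read a gene-annotation table
#'
#' Two-column TSV (`category`, `gene`); categories such as TF, kinase,
#' oncogene may overlap. Returned as a named list of gene-identifier
#' character vectors.
#'
#' @param path Annotation TSV path.
#' @return Named list of character vectors, one per category.
#' @export
read_annotations <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("category", "gene") %in% names(tab)))
  split(as.character(tab$gene), tab$category)
}

#' Read a subtype-centroid table
#'
#' TSV with a `gene` column and one numeric column per molecular subtype
#' (e.g. Neural, Proneural, Classical, Mesenchymal) holding centroid mean
#' expression levels.
#'
#' @param path Centroid TSV path.
#' @return Wide tibble (`gene` + one column per subtype).
#' @export
read_centroids <- function(path) {
  cen <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(cen)[1] != "gene") names(cen)[1] <- "gene"
  cen$gene <- as.character(cen$gene)
  if (anyDuplicated(cen$gene)) {
    abort_astro("duplicated gene in centroid table", "astronet_format_error")
  }
  if (ncol(cen) < 3) {
    abort_astro("centroid table needs at least two subtypes",
                "astronet_format_error")
  }
  cen
}

#' Read a per-gene mutation-layer table
#'
#' TSV with columns `gene` and `log_ratio` holding the average tumor vs
#' normal log2-ratio of DNA methylation or gene copy number.
#'
#' @param path Mutation TSV path.
#' @param layer `"methylation"` or `"copy_number"`.
#' @return Tibble with columns `gene`, `log_ratio`, `layer`.
#' @export
read_mutation_table <- function(path, layer = c("methylation", "copy_number")) {
  layer <- match.arg(layer)
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("gene", "log_ratio") %in% names(tab)))
  if (anyDuplicated(tab$gene)) {
    abort_astro("duplicated gene in mutation table", "astronet_format_error")
  }
  tibble::tibble(gene = as.character(tab$gene),
                 log_ratio = as.numeric(tab$log_ratio),
                 layer = layer)
}
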