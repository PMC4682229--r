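#' @keywords internal
#' @importFrom rlang .data
#' @importFrom utils head
"_PACKAGE"

#' WHO grade labels used throughout the package
#'
#' `astro_grades()` returns the five sample labels the pipeline understands:
#' the normal-brain reference plus the four tumor grades, ordered by
#' malignancy. `tumor_grades()` returns the four tumor grades only.
#'
#' @return Character vector of grade labels.
#' @export
astro_grades <- function() c("NORMAL", "PA1", "AS2", "AS3", "GBM4")

#' @rdname astro_grades
#' @export
tumor_grades <- function() c("PA1", "AS2", "AS3", "GBM4")

# Numeric WHO grade used for trend statistics
grade_number <- function(grade) {
  match(grade, tumor_grades())
}

abort_astro <- function(msg, class) {
  rlang::abort(msg, class = c(class, "astronet_error"))
}

# Convert a wide expression tibble (gene + one column per sample) to a
# numeric matrix with gene rownames. Validates uniqueness and numeric cells.
expr_to_matrix <- function(expr) {
  stopifnot(is.data.frame(expr), "gene" %in% names(expr))
  genes <- as.character(expr$gene)
  dup <- unique(genes[duplicated(genes)])
  if (length(dup) > 0) {
    abort_astro(
      paste0("duplicated gene identifier(s): ", paste(dup, collapse = ", ")),
      "astronet_format_error"
    )
  }
  vals <- expr[setdiff(names(expr), "gene")]
  bad <- names(vals)[!vapply(vals, is.numeric, logical(1))]
  if (length(bad) > 0) {
    abort_astro(
      paste0("non-numeric expression column(s): ", paste(bad, collapse = ", ")),
      "astronet_format_error"
    )
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  m
}

matrix_to_expr <- function(m) {
  tibble::as_tibble(m, rownames = "gene")
}

# Validate that metadata covers exactly the samples of an expression tibble.
check_metadata <- function(expr, metadata) {
  stopifnot(all(c("sample", "grade") %in% names(metadata)))
  samples <- setdiff(names(expr), "gene")
  if (anyDuplicated(metadata$sample)) {
    abort_astro("duplicated sample identifiers in metadata",
                "astronet_consistency_error")
  }
  missing_meta <- setdiff(samples, metadata$sample)
  if (length(missing_meta) > 0) {
    abort_astro(
      paste0("sample(s) missing from metadata: ",
             paste(missing_meta, collapse = ", ")),
      "astronet_consistency_error"
    )
  }
  bad_grade <- setdiff(unique(metadata$grade), astro_grades())
  if (length(bad_grade) > 0) {
    abort_astro(
      paste0("unknown grade label(s): ", paste(bad_grade, collapse = ", ")),
      "astronet_consistency_error"
    )
  }
  invisible(TRUE)
}

samples_of_grade <- function(metadata, grade, samples = NULL) {
  s <- metadata$sample[metadata$grade %in% grade]
  if (!is.null(samples)) s <- intersect(samples, s)
  s
}

`%||%` <- rlang::`%||%`
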