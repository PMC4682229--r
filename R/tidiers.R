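#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a regulatory network into its edge table
#'
#' @param x An `astro_network`.
#' @param ... Unused.
#' @return Tibble with one row per selected edge (`tf`, `target`,
#'   `coefficient`, `sign`, `p_value`).
#' @method tidy astro_network
#' @export
tidy.astro_network <- function(x, ...) {
  x$edges
}

#' One-row summary of a regulatory network
#'
#' @param x An `astro_network`.
#' @param ... Unused.
#' @return Tibble with columns `n_tfs`, `n_signature_genes`,
#'   `possible_links`, `n_edges`, `n_activator`, `n_repressor`,
#'   `n_genes_without_regulators`, `n_tfs_without_targets`.
#' @method glance astro_network
#' @export
glance.astro_network <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    n_tfs = length(x$tfs),
    n_signature_genes = length(x$signature_genes),
    possible_links = s$possible_links,
    n_edges = s$n_edges,
    n_activator = s$n_activator,
    n_repressor = s$n_repressor,
    n_genes_without_regulators = length(s$genes_without_regulators),
    n_tfs_without_targets = length(s$tfs_without_targets)
  )
}

#' Tidy a lasso path into its event table
#'
#' @param x An `astro_lasso_path`.
#' @param ... Unused.
#' @return Tibble of path events (`step`, `lambda`, `predictor`,
#'   `action`, `sign`).
#' @method tidy astro_lasso_path
#' @export
tidy.astro_lasso_path <- function(x, ...) {
  x$events
}

#' One-row summary of a lasso path
#'
#' @param x An `astro_lasso_path`.
#' @param ... Unused.
#' @return Tibble with `n_predictors`, `n_knots`, `n_entries`,
#'   `n_drops`, `lambda_max`, `completed`.
#' @method glance astro_lasso_path
#' @export
glance.astro_lasso_path <- function(x, ...) {
  tibble::tibble(
    n_predictors = length(x$predictors),
    n_knots = length(x$knots),
    n_entries = sum(x$events$action == "enter"),
    n_drops = sum(x$events$action == "drop"),
    lambda_max = if (length(x$knots) > 0) x$knots[1] else 0,
    completed = x$completed
  )
}
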