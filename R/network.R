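#' Select the regulators of one signature gene
#'
#' Fits the sparse linear model \eqn{e_{id} = \sum_j a_{ji} e_{jd}}
#' for one signature gene over tumor samples: the gene's log-ratio
#' response is traced along the lasso path over all candidate TF
#' log-ratios (excluding the gene itself when it is a TF), every entering
#' predictor is scored with the covariance test, and predictors whose
#' first-entry p-value falls below `p_threshold` are kept. Reported
#' coefficients come from an unpenalized least-squares refit (no
#' intercept) restricted to the selected set; the sign label is
#' `activator` for positive and `repressor` for negative coefficients.
#'
#' @param gene Signature gene identifier (the response).
#' @param lr Wide log-ratio tibble (`gene` + tumor sample columns).
#' @param tf_set Character vector of TF gene identifiers present in
#'   `lr`.
#' @param p_threshold Covariance-test significance threshold
#'   (default `5e-5`).
#' @param sigma2 Optional noise variance; estimated by
#'   [estimate_noise_variance()] when `NULL`.
#' @return Tibble with columns `tf`, `target`, `coefficient`, `sign`,
#'   `p_value` (possibly empty).
#' @export
fit_gene_model <- function(gene, lr, tf_set, p_threshold = 5e-5,
                           sigma2 = NULL) {
  m <- expr_to_matrix(lr)
  if (ncol(m) < 3) abort_astro("need at least three tumor samples",
                               "astronet_consistency_error")
  if (!gene %in% rownames(m)) {
    abort_astro(paste0("gene not in log-ratio table: ", gene),
                "astronet_consistency_error")
  }
  preds <- setdiff(intersect(tf_set, rownames(m)), gene)
  if (length(preds) == 0) {
    return(empty_edges())
  }
  y <- m[gene, ]
  X <- t(m[preds, , drop = FALSE])
  if (is.null(sigma2)) sigma2 <- estimate_noise_variance(X, y)
  path <- lasso_path(X, y)
  ct <- covariance_test(path, sigma2)
  sel <- ct$predictor[ct$p < p_threshold]
  if (length(sel) == 0) return(empty_edges())
  refit <- stats::lm.fit(X[, sel, drop = FALSE], y)
  coefs <- refit$coefficients
  keep <- !is.na(coefs) & coefs != 0
  sel <- sel[keep]; coefs <- coefs[keep]
  if (length(sel) == 0) return(empty_edges())
  tibble::tibble(
    tf = unname(sel), target = gene, coefficient = unname(coefs),
    sign = unname(ifelse(coefs > 0, "activator", "repressor")),
    p_value = ct$p[match(sel, ct$predictor)]
  )
}

empty_edges <- function() {
  tibble::tibble(tf = character(), target = character(),
                 coefficient = numeric(), sign = character(),
                 p_value = numeric())
}

#' Infer the signature-specific regulatory network
#'
#' Runs [fit_gene_model()] for every signature gene and assembles the
#' union of the per-gene selections into a directed, signed, weighted
#' TF-to-target network. The summary reports the conventional
#' possible-link denominator `|TF| x N` (every TF against every
#' signature gene) alongside the self-pair-excluded count, the numbers
#' of activator and repressor links, signature genes without any
#' selected regulator, and TFs without outgoing links.
#'
#' @param signature_genes Character vector of signature genes (the
#'   responses; must include the TFs of `tf_set`).
#' @param lr Wide log-ratio tibble over tumor samples.
#' @param tf_set Character vector of TF genes among the signature.
#' @param p_threshold Covariance-test threshold (default `5e-5`).
#' @return An object of class `astro_network`: list with `edges`
#'   (tibble), `signature_genes`, `tfs`, and `summary` (list of counts).
#' @export
infer_network <- function(signature_genes, lr, tf_set, p_threshold = 5e-5) {
  edges <- purrr::map_dfr(signature_genes, function(g) {
    fit_gene_model(g, lr, tf_set, p_threshold)
  })
  if (nrow(edges) > 0 && any(edges$tf == edges$target)) {
    abort_astro("self-edge produced; this should be impossible",
                "astronet_consistency_error")
  }
  new_astro_network(edges, signature_genes, tf_set, p_threshold)
}

new_astro_network <- function(edges, signature_genes, tf_set,
                              p_threshold = NA_real_) {
  summary <- list(
    possible_links = possible_links(length(tf_set), length(signature_genes)),
    possible_links_self_excluded =
      possible_links(length(tf_set), length(signature_genes),
                     exclude_self = TRUE),
    n_edges = nrow(edges),
    n_activator = sum(edges$sign == "activator"),
    n_repressor = sum(edges$sign == "repressor"),
    genes_without_regulators = setdiff(signature_genes, edges$target),
    tfs_without_targets = setdiff(tf_set, edges$tf),
    p_threshold = p_threshold
  )
  structure(list(edges = edges, signature_genes = signature_genes,
                 tfs = tf_set, summary = summary),
            class = "astro_network")
}

#' Theoretically possible TF-to-signature-gene links
#'
#' The conventional denominator counts every TF against every signature
#' gene (`n_tf * n_signature`); with `exclude_self = TRUE` the TF
#' self-pairs are removed (`n_tf * n_signature - n_tf`), matching the
#' model's exclusion of self-regulation.
#'
#' @param n_tf Number of TFs.
#' @param n_signature Number of signature genes (TFs included).
#' @param exclude_self Remove TF self-pairs.
#' @return Integer count.
#' @export
possible_links <- function(n_tf, n_signature, exclude_self = FALSE) {
  n <- n_tf * n_signature
  if (exclude_self) n <- n - n_tf
  n
}

#' @export
print.astro_network <- function(x, ...) {
  s <- x$summary
  cat("Signature-specific regulatory network\n")
  cat(sprintf("  %d TFs x %d signature genes (%d possible links)\n",
              length(x$tfs), length(x$signature_genes), s$possible_links))
  cat(sprintf("  %d selected links: %d activator, %d repressor\n",
              s$n_edges, s$n_activator, s$n_repressor))
  cat(sprintf("  %d signature genes without regulators; %d TFs without targets\n",
              length(s$genes_without_regulators),
              length(s$tfs_without_targets)))
  invisible(x)
}

#' Compare an inferred network with a planted coefficient matrix
#'
#' Edge-level precision, recall and sign agreement against the ground
#' truth of a simulated cohort.
#'
#' @param network An `astro_network`.
#' @param coeff_matrix TF x target matrix of true coefficients (zeros
#'   mean no edge).
#' @return Tibble with columns `n_true`, `n_selected`, `tp`,
#'   `precision`, `recall`, `sign_agreement`.
#' @export
network_recovery <- function(network, coeff_matrix) {
  truth <- which(coeff_matrix != 0, arr.ind = TRUE)
  true_keys <- paste(rownames(coeff_matrix)[truth[, 1]],
                     colnames(coeff_matrix)[truth[, 2]], sep = "->")
  true_signs <- sign(coeff_matrix[coeff_matrix != 0])
  names(true_signs) <- true_keys
  edges <- network$edges
  sel_keys <- paste(edges$tf, edges$target, sep = "->")
  tp_keys <- intersect(sel_keys, true_keys)
  tp <- length(tp_keys)
  sign_agree <- if (tp == 0) NA_real_ else {
    est <- sign(edges$coefficient[match(tp_keys, sel_keys)])
    mean(est == true_signs[tp_keys])
  }
  tibble::tibble(
    n_true = length(true_keys), n_selected = nrow(edges), tp = tp,
    precision = if (nrow(edges) == 0) NA_real_ else tp / nrow(edges),
    recall = if (length(true_keys) == 0) NA_real_ else tp / length(true_keys),
    sign_agreement = sign_agree
  )
}
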