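#' Rank TFs by outgoing regulatory links
#'
#' Counts, per TF, the outgoing links to all signature genes and to TFs
#' only; optionally adds the mean expression log-ratio contrast between
#' the pooled adult grades (AS II + AS III + GBM IV) and PA I. Sorted by
#' total out-degree, ties broken lexicographically.
#'
#' @param network An `astro_network`.
#' @param lr Optional wide log-ratio tibble to compute the expression
#'   contrast.
#' @param metadata Sample metadata (required with `lr`).
#' @return Tibble with columns `tf`, `out_degree`, `out_degree_tf`,
#'   and `expr_contrast` when expression is supplied.
#' @export
hub_ranking <- function(network, lr = NULL, metadata = NULL) {
  tfs <- network$tfs
  edges <- network$edges
  out_total <- table(factor(edges$tf, levels = tfs))
  out_tf <- table(factor(edges$tf[edges$target %in% tfs], levels = tfs))
  rep <- tibble::tibble(tf = tfs,
                        out_degree = as.integer(out_total[tfs]),
                        out_degree_tf = as.integer(out_tf[tfs]))
  if (!is.null(lr)) {
    m <- expr_to_matrix(lr)
    pa <- samples_of_grade(metadata, "PA1", colnames(m))
    adult <- samples_of_grade(metadata, c("AS2", "AS3", "GBM4"), colnames(m))
    present <- intersect(tfs, rownames(m))
    contrast <- rowMeans(m[present, adult, drop = FALSE]) -
      rowMeans(m[present, pa, drop = FALSE])
    rep$expr_contrast <- contrast[match(rep$tf, present)]
  }
  dplyr::arrange(rep, dplyr::desc(.data$out_degree), .data$tf)
}

#' TFs high in the TF-to-TF regulatory hierarchy
#'
#' Returns the TFs with strictly more than `threshold` outgoing links to
#' other TFs.
#'
#' @param network An `astro_network`.
#' @param threshold Strict lower bound on the TF-only out-degree
#'   (default 5).
#' @return Tibble with columns `tf`, `out_degree_tf`.
#' @export
tf_hierarchy <- function(network, threshold = 5) {
  rep <- hub_ranking(network)
  out <- rep[rep$out_degree_tf > threshold, c("tf", "out_degree_tf")]
  dplyr::arrange(out, dplyr::desc(.data$out_degree_tf), .data$tf)
}

#' Predict signature-gene expression from TF profiles
#'
#' Applies the inferred linear model: the predicted log-ratio of gene
#' `i` in sample `d` is the sum over its selected regulators `j` of
#' `a_ji` times the TF's observed log-ratio. Genes without regulators
#' are excluded from the correlation summary and counted separately —
#' this is the cross-cohort validation used to test the network's
#' predictive power on independently generated data.
#'
#' @param network An `astro_network`.
#' @param lr Wide log-ratio tibble of the validation cohort (must
#'   contain every TF with an outgoing edge; target genes needed only
#'   for the observed-vs-predicted correlations).
#' @return List with `predicted` (wide tibble, one row per regulated
#'   gene), `gene_cor` (tibble `gene`, `r`, `n_regulators`), and
#'   `n_unregulated` (genes with no regulators).
#' @export
predict_expression <- function(network, lr) {
  edges <- network$edges
  m <- expr_to_matrix(lr)
  need_tf <- unique(edges$tf)
  missing_tf <- setdiff(need_tf, rownames(m))
  if (length(missing_tf) > 0) {
    genes_hit <- unique(edges$target[edges$tf %in% missing_tf])
    abort_astro(
      paste0("TF(s) missing from log-ratio table: ",
             paste(missing_tf, collapse = ", "), "; affected gene(s): ",
             paste(genes_hit, collapse = ", ")),
      "astronet_consistency_error"
    )
  }
  targets <- unique(edges$target)
  A <- matrix(0, length(need_tf), length(targets),
              dimnames = list(need_tf, targets))
  A[cbind(match(edges$tf, need_tf), match(edges$target, targets))] <-
    edges$coefficient
  pred <- t(A) %*% m[need_tf, , drop = FALSE]
  observed <- intersect(targets, rownames(m))
  gene_cor <- purrr::map_dfr(observed, function(g) {
    obs <- m[g, ]
    r <- if (stats::sd(obs) == 0 || stats::sd(pred[g, ]) == 0) {
      NA_real_
    } else stats::cor(pred[g, ], obs)
    tibble::tibble(gene = g, r = r,
                   n_regulators = sum(edges$target == g))
  })
  list(predicted = matrix_to_expr(pred), gene_cor = gene_cor,
       n_unregulated = length(setdiff(network$signature_genes, targets)))
}

#' Summary of predictive validation
#'
#' @param gene_cor Per-gene correlation tibble from
#'   [predict_expression()].
#' @return Tibble with `median_r`, `frac_positive`, `n_genes`.
#' @export
validation_summary <- function(gene_cor) {
  r <- gene_cor$r[!is.na(gene_cor$r)]
  tibble::tibble(median_r = stats::median(r),
                 frac_positive = mean(r > 0), n_genes = length(r))
}

#' Categorize TFs by expression versus mutation deviation
#'
#' Places each TF on the expression-change versus mutation-change plane
#' and labels it: `CENTER` when both absolute values fall below
#' `deviation_threshold`; `EXPR_ONLY` / `MUT_ONLY` when exactly one
#' exceeds it; otherwise `CONCORDANT` when the two signs satisfy the
#' layer's expected coupling (copy number: same sign; methylation:
#' opposite sign, promoter hypermethylation accompanying
#' underexpression) and `DISCORDANT` otherwise.
#'
#' @param expr_contrast Named numeric vector of per-TF mean expression
#'   log-ratios.
#' @param mutations Mutation tibble (`gene`, `log_ratio`, `layer`).
#' @param deviation_threshold Absolute log2 deviation regarded as strong
#'   (default 1).
#' @return Tibble with columns `tf`, `expr`, `mutation`, `layer`,
#'   `category`. TFs missing a layer value are skipped with a message.
#' @export
mutation_expression_map <- function(expr_contrast, mutations,
                                    deviation_threshold = 1) {
  layer <- unique(mutations$layer)
  stopifnot(length(layer) == 1)
  tfs <- names(expr_contrast)
  missing <- setdiff(tfs, mutations$gene)
  if (length(missing) > 0) {
    message("skipping TF(s) without a ", layer, " value: ",
            paste(missing, collapse = ", "))
    tfs <- setdiff(tfs, missing)
  }
  mu <- mutations$log_ratio[match(tfs, mutations$gene)]
  ex <- expr_contrast[tfs]
  strong_e <- abs(ex) >= deviation_threshold
  strong_m <- abs(mu) >= deviation_threshold
  expected_same_sign <- layer == "copy_number"
  concord <- if (expected_same_sign) {
    sign(ex) == sign(mu)
  } else {
    sign(ex) == -sign(mu)
  }
  category <- dplyr::case_when(
    !strong_e & !strong_m ~ "CENTER",
    strong_e & !strong_m ~ "EXPR_ONLY",
    !strong_e & strong_m ~ "MUT_ONLY",
    concord ~ "CONCORDANT",
    TRUE ~ "DISCORDANT"
  )
  tibble::tibble(tf = tfs, expr = unname(ex), mutation = mu,
                 layer = layer, category = category)
}
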