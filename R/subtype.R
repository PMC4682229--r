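#' Intersect a sample's genes with the centroid genes
#'
#' Returns the common genes in centroid order (deterministic) together
#' with the fraction of centroid genes covered.
#'
#' @param sample_genes Character vector of genes measured in the sample.
#' @param centroid_genes Character vector of centroid genes.
#' @return List with `genes` (character, centroid order) and `coverage`
#'   (fraction of centroid genes present).
#' @export
intersect_signature <- function(sample_genes, centroid_genes) {
  common <- centroid_genes[centroid_genes %in% sample_genes]
  if (length(common) == 0) {
    abort_astro("no genes shared between sample and centroids",
                "astronet_consistency_error")
  }
  list(genes = common, coverage = length(common) / length(centroid_genes))
}

#' P-value for a Pearson correlation
#'
#' Uses the exact t transform `t = r * sqrt(n - 2) / sqrt(1 - r^2)` with
#' `n - 2` degrees of freedom. One-sided by default (testing that the
#' correlation is greater than zero, the convention for centroid
#' assignment); two-sided available.
#'
#' @param r Pearson correlation coefficient.
#' @param n Number of paired observations (>= 3).
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return The p-value.
#' @export
correlation_pvalue <- function(r, n, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (n < 3) abort_astro("need n >= 3", "astronet_config_error")
  if (abs(r) > 1 + 1e-12) abort_astro("|r| > 1", "astronet_config_error")
  r <- max(-1, min(1, r))
  if (abs(r) == 1) {
    p_two <- 0
  } else {
    t <- r * sqrt(n - 2) / sqrt(1 - r^2)
    p_two <- 2 * stats::pt(-abs(t), n - 2)
  }
  if (alternative == "two.sided") return(p_two)
  if (r >= 0) p_two / 2 else 1 - p_two / 2
}

#' Classify one sample by centroid correlation
#'
#' Computes the Pearson correlation of the sample's per-gene log-ratios
#' with each subtype centroid over their common genes and assigns the
#' subtype with the greatest significant positive correlation
#' (one-sided `p < alpha`). Samples with no significant positive subtype
#' are labeled `UNCLASSIFIED`. Exact ties in `r` are broken by centroid
#' column order.
#'
#' @param sample_lr Named numeric vector of per-gene log-ratios, or a
#'   one-sample wide tibble (`gene` + one value column).
#' @param centroids Centroid tibble (`gene` + subtype columns).
#' @param alpha Significance level (default 0.05).
#' @return Tibble with one row per subtype: `sample`, `subtype`, `r`,
#'   `p`, `assigned` (logical), `label`, `n_genes`.
#' @export
classify_subtype <- function(sample_lr, centroids, alpha = 0.05) {
  if (is.data.frame(sample_lr)) {
    stopifnot(ncol(sample_lr) == 2, names(sample_lr)[1] == "gene")
    v <- stats::setNames(sample_lr[[2]], sample_lr$gene)
    sample_id <- names(sample_lr)[2]
  } else {
    v <- sample_lr
    sample_id <- "sample"
  }
  common <- intersect_signature(names(v), centroids$gene)
  if (length(common$genes) < 3) {
    abort_astro("need at least three common genes", "astronet_config_error")
  }
  x <- v[common$genes]
  if (stats::sd(x) == 0) {
    abort_astro("sample vector is constant; correlation undefined",
                "astronet_config_error")
  }
  subtypes <- setdiff(names(centroids), "gene")
  cen <- centroids[match(common$genes, centroids$gene), subtypes,
                   drop = FALSE]
  r <- vapply(subtypes,
              function(s) stats::cor(x, cen[[s]]), numeric(1))
  p <- vapply(r, correlation_pvalue, numeric(1), n = length(x))
  eligible <- which(p < alpha & r > 0)
  label <- if (length(eligible) == 0) {
    "UNCLASSIFIED"
  } else {
    # max r among significant; ties broken by centroid column order
    subtypes[eligible[which.max(r[eligible])]]
  }
  tibble::tibble(sample = sample_id, subtype = subtypes, r = unname(r),
                 p = unname(p), assigned = subtypes == label &
                   label != "UNCLASSIFIED",
                 label = label, n_genes = length(x))
}

#' Classify every sample of a log-ratio table
#'
#' @param lr Wide log-ratio tibble (`gene` + sample columns).
#' @param centroids Centroid tibble.
#' @param alpha Significance level.
#' @return Tibble with one row per sample x subtype (see
#'   [classify_subtype()]).
#' @export
classify_subtypes <- function(lr, centroids, alpha = 0.05) {
  samples <- setdiff(names(lr), "gene")
  purrr::map_dfr(samples, function(s) {
    out <- classify_subtype(lr[c("gene", s)], centroids, alpha)
    out$sample <- s
    out
  })
}

#' One call-per-sample summary of subtype classifications
#'
#' @param calls Output of [classify_subtypes()].
#' @return Tibble with columns `sample`, `label`, `r`, `p` (the assigned
#'   subtype's values; `NA` for unclassified samples).
#' @export
subtype_labels <- function(calls) {
  calls |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(
      label = .data$label[1],
      r = ifelse(any(.data$assigned), .data$r[.data$assigned][1], NA_real_),
      p = ifelse(any(.data$assigned), .data$p[.data$assigned][1], NA_real_),
      .groups = "drop"
    )
}

#' Correlation between two per-gene expression profiles
#'
#' Pearson correlation over the shared genes of two named profiles —
#' used for signature probes such as the hypermethylator-subtype
#' signature or average microglia/macrophage marker profiles.
#'
#' @param profile_a,profile_b Named numeric vectors (names are genes).
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @return Tibble with columns `r`, `p`, `n_genes`.
#' @export
signature_correlation <- function(profile_a, profile_b,
                                  alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  shared <- intersect(names(profile_a), names(profile_b))
  if (length(shared) < 3) {
    abort_astro("need at least three shared genes", "astronet_config_error")
  }
  r <- stats::cor(profile_a[shared], profile_b[shared])
  p <- correlation_pvalue(r, length(shared), alternative = alternative)
  tibble::tibble(r = r, p = p, n_genes = length(shared))
}
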