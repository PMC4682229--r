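#' Welch's unequal-variance t-test for two groups of log2 values
#'
#' Two-sided test with Welch–Satterthwaite degrees of freedom. Degenerate
#' inputs follow fixed conventions: zero variance in both groups with
#' equal means gives `p = 1`; zero variance with unequal means gives
#' `p = 0` and is flagged.
#'
#' @param group_a,group_b Numeric vectors (each of length >= 2).
#' @return Tibble with columns `t`, `df`, `p`, `flagged`.
#' @export
welch_t <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  row_welch(matrix(group_a, nrow = 1), matrix(group_b, nrow = 1))
}

# Vectorized Welch test over matrix rows (genes). Returns a tibble with
# one row per input row.
row_welch <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  zero_var <- se2 == 0
  flagged <- zero_var
  if (any(zero_var)) {
    eq <- zero_var & (ma == mb)
    t[eq] <- 0; p[eq] <- 1; df[zero_var] <- NA_real_
    ne <- zero_var & (ma != mb)
    t[ne] <- sign(ma - mb)[ne] * Inf; p[ne] <- 0
  }
  tibble::tibble(t = t, df = df, p = p, flagged = flagged)
}

#' FDR adjustment of p-values
#'
#' Benjamini–Hochberg step-up by default; a simple Storey-type estimate
#' (`pi0` from the density of p-values above `lambda`) is available as an
#' alternative.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method `"BH"` (default) or `"storey"`.
#' @param lambda Tuning point for the Storey pi0 estimate.
#' @return Vector of q-values, same length and order as `p`.
#' @export
adjust_fdr <- function(p, method = c("BH", "storey"), lambda = 0.5) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort_astro("p-values must lie in [0, 1]", "astronet_config_error")
  }
  q <- stats::p.adjust(p, method = "BH")
  if (method == "storey") {
    pi0 <- min(1, mean(p > lambda) / (1 - lambda))
    q <- pmin(1, q * pi0)
  }
  q
}

#' Call per-gene expression states for one tumor grade
#'
#' Tests every gene's tumor log2 values against the reference log2 values
#' (Welch test), adjusts over the grade's full gene list, and assigns a
#' discrete state: `OVER` if `q < q_threshold` and the mean log-ratio is
#' positive, `UNDER` if negative, otherwise `UNCHANGED`. Zero-variance
#' genes are flagged and left `UNCHANGED`.
#'
#' @param expr Wide expression tibble (`gene` + sample columns).
#' @param metadata Sample metadata (`sample`, `grade`).
#' @param grade Tumor grade to test (`PA1`, `AS2`, `AS3` or `GBM4`).
#' @param reference_grade Reference grade (default `"NORMAL"`).
#' @param q_threshold Significance threshold on the q-value
#'   (default `1e-4`).
#' @param method FDR method passed to [adjust_fdr()].
#' @return Tibble with columns `gene`, `grade`, `t`, `p`, `q`,
#'   `mean_log_ratio`, `state`, `flagged`.
#' @export
call_states <- function(expr, metadata, grade, reference_grade = "NORMAL",
                        q_threshold = 1e-4, method = "BH") {
  check_metadata(expr, metadata)
  m <- expr_to_matrix(expr)
  tum <- samples_of_grade(metadata, grade, colnames(m))
  ref <- samples_of_grade(metadata, reference_grade, colnames(m))
  if (length(tum) < 2 || length(ref) < 2) {
    abort_astro("need at least two tumor and two reference samples",
                "astronet_consistency_error")
  }
  res <- row_welch(m[, tum, drop = FALSE], m[, ref, drop = FALSE])
  mean_lr <- rowMeans(m[, tum, drop = FALSE]) -
    rowMeans(m[, ref, drop = FALSE])
  q <- rep(NA_real_, nrow(res))
  ok <- !res$flagged
  q[ok] <- adjust_fdr(res$p[ok], method = method)
  state <- rep("UNCHANGED", nrow(res))
  state[ok & q < q_threshold & mean_lr > 0] <- "OVER"
  state[ok & q < q_threshold & mean_lr < 0] <- "UNDER"
  tibble::tibble(gene = rownames(m), grade = grade, t = res$t, p = res$p,
                 q = q, mean_log_ratio = unname(mean_lr), state = state,
                 flagged = res$flagged)
}

#' Call states for all four tumor grades
#'
#' @inheritParams call_states
#' @return One tibble stacking the four per-grade state tables.
#' @export
call_states_all <- function(expr, metadata, reference_grade = "NORMAL",
                            q_threshold = 1e-4, method = "BH") {
  purrr::map_dfr(tumor_grades(), function(g) {
    call_states(expr, metadata, g, reference_grade, q_threshold, method)
  })
}

#' Exclusive grade-subset partition of direction-consistent genes
#'
#' Venn-style partition: each gene showing `direction` (`OVER` or
#' `UNDER`) in at least one grade is assigned to exactly the subset of
#' grades where it shows that direction. Subsets are disjoint by
#' construction and cover all direction-positive genes.
#'
#' @param states Stacked state table from [call_states_all()].
#' @param direction `"OVER"` or `"UNDER"`.
#' @return Tibble with columns `gene`, `subset` (grade labels joined by
#'   `+`), `n_grades`.
#' @export
exclusive_subsets <- function(states, direction = c("OVER", "UNDER")) {
  direction <- match.arg(direction)
  universes <- lapply(split(states$gene, states$grade), sort)
  if (length(unique(universes)) != 1) {
    abort_astro("state tables cover different gene universes",
                "astronet_consistency_error")
  }
  hit <- states[states$state == direction, c("gene", "grade")]
  if (nrow(hit) == 0) {
    return(tibble::tibble(gene = character(), subset = character(),
                          n_grades = integer()))
  }
  hit |>
    dplyr::mutate(grade = factor(.data$grade, levels = tumor_grades())) |>
    dplyr::arrange(.data$gene, .data$grade) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(subset = paste(.data$grade, collapse = "+"),
                     n_grades = dplyr::n(), .groups = "drop")
}

#' Count genes in each exclusive subset
#'
#' @param partition Output of [exclusive_subsets()].
#' @return Tibble with columns `subset`, `n`.
#' @export
subset_counts <- function(partition) {
  dplyr::count(partition, .data$subset, name = "n")
}

#' One-sided Fisher over-representation p-value
#'
#' Probability of observing `k` or more category members in a set of size
#' `n` drawn from a universe of `N` genes of which `K` are in the
#' category (hypergeometric upper tail).
#'
#' @param k Observed hits in the set.
#' @param n Set size.
#' @param K Category size in the universe.
#' @param N Universe size.
#' @return The p-value `P(X >= k)`.
#' @export
enrichment_fisher <- function(k, n, K, N) {
  if (k < 0 || n < 0 || K < 0 || N < 0 || k > min(n, K) || n > N || K > N) {
    abort_astro("inconsistent enrichment counts", "astronet_config_error")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Enrichment of annotation categories in per-grade DE sets
#'
#' For each grade and annotation category, counts the overlap of the
#' grade's differentially expressed genes (optionally restricted to one
#' direction) with the category and computes the one-sided Fisher
#' p-value against the full measured-gene universe.
#'
#' @param states Stacked state table from [call_states_all()].
#' @param annotations Named list of gene sets (see [read_annotations()]).
#' @param direction `"any"`, `"OVER"` or `"UNDER"`.
#' @return Tibble with columns `grade`, `category`, `k`, `n`, `K`, `N`,
#'   `p`.
#' @export
enrichment_by_grade <- function(states, annotations,
                                direction = c("any", "OVER", "UNDER")) {
  direction <- match.arg(direction)
  universe <- unique(states$gene)
  N <- length(universe)
  purrr::map_dfr(tumor_grades(), function(g) {
    st <- states[states$grade == g, ]
    de <- if (direction == "any") {
      st$gene[st$state != "UNCHANGED"]
    } else st$gene[st$state == direction]
    purrr::map_dfr(names(annotations), function(cat) {
      K <- length(intersect(annotations[[cat]], universe))
      k <- length(intersect(annotations[[cat]], de))
      tibble::tibble(grade = g, category = cat, k = k, n = length(de),
                     K = K, N = N,
                     p = enrichment_fisher(k, length(de), K, N))
    })
  })
}

#' Pearson correlation of DE counts with WHO grade
#'
#' Tests whether the number of differentially expressed genes increases
#' with the numeric WHO grade (1 through 4).
#'
#' @param counts Per-grade counts, in grade order PA1, AS2, AS3, GBM4
#'   (or any length >= 3 with matching `grades`).
#' @param grades Numeric grades (default `1:4`).
#' @return Tibble with columns `r` and `p` (two-sided).
#' @export
grade_trend <- function(counts, grades = seq_along(counts)) {
  if (length(counts) < 3) {
    abort_astro("need at least three grades", "astronet_config_error")
  }
  if (stats::sd(counts) == 0) {
    abort_astro("correlation undefined for constant counts",
                "astronet_config_error")
  }
  ct <- stats::cor.test(as.numeric(counts), as.numeric(grades),
                        method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value)
}
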