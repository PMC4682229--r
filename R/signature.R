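#' Does a gene's grade-state pattern separate PA I from the higher grades?
#'
#' A gene qualifies when its expression state in PA I (under, unchanged
#' or over) is not shared by the higher grades AS II, AS III and GBM IV.
#' Six criteria are recorded for provenance: (i)-(iii) the gene is
#' under-/unchanged/overexpressed in PA I but not in AS II, AS III or
#' GBM IV; (iv)-(vi) the reverse direction, a higher grade shows a state
#' PA I does not. Under the default disjunctive reading ("or") the gene
#' qualifies as soon as one higher grade differs from PA I; the strict
#' mode requires all three higher grades to differ.
#'
#' @param states Named character vector or one-row list with states for
#'   `PA1`, `AS2`, `AS3`, `GBM4` (values `UNDER`, `UNCHANGED`, `OVER`).
#' @param strict If `TRUE`, require the PA I state to differ from every
#'   higher grade; default `FALSE` (differ from at least one).
#' @return List with `match` (logical) and `criteria` (character vector
#'   among `"i"`..`"vi"`; empty when no criterion fires).
#' @export
matches_criteria <- function(states, strict = FALSE) {
  needed <- tumor_grades()
  if (!all(needed %in% names(states))) {
    abort_astro(paste0("missing grade state(s): ",
                       paste(setdiff(needed, names(states)), collapse = ", ")),
                "astronet_config_error")
  }
  st <- unlist(states[needed])
  ok <- st %in% c("UNDER", "UNCHANGED", "OVER")
  if (!all(ok)) {
    abort_astro("states must be UNDER, UNCHANGED or OVER",
                "astronet_config_error")
  }
  pa <- st[["PA1"]]
  high <- st[c("AS2", "AS3", "GBM4")]
  differs <- high != pa
  match <- if (strict) all(differs) else any(differs)
  criteria <- character()
  if (match) {
    # forward criteria: PA I state not shared by (some/all) higher grades
    fwd <- c(UNDER = "i", UNCHANGED = "ii", OVER = "iii")[[pa]]
    criteria <- c(criteria, fwd)
    # reverse criteria: a higher-grade state PA I does not show
    rev_states <- unique(high[differs])
    criteria <- c(criteria,
                  unname(c(UNDER = "iv", UNCHANGED = "v",
                           OVER = "vi")[rev_states]))
  }
  list(match = match, criteria = criteria)
}

#' Class-mean log-ratio difference between PA I and the higher grades
#'
#' Mean log-ratio over PA I samples minus mean log-ratio over the pooled
#' AS II + AS III + GBM IV samples, per gene.
#'
#' @param lr Wide log-ratio tibble (`gene` + tumor sample columns).
#' @param metadata Sample metadata (`sample`, `grade`).
#' @return Tibble with columns `gene`, `mean_pa1`, `mean_high`,
#'   `difference`.
#' @export
class_difference <- function(lr, metadata) {
  m <- expr_to_matrix(lr)
  pa <- samples_of_grade(metadata, "PA1", colnames(m))
  high <- samples_of_grade(metadata, c("AS2", "AS3", "GBM4"), colnames(m))
  if (length(pa) == 0 || length(high) == 0) {
    abort_astro("need samples in both the PA I and the pooled higher-grade class",
                "astronet_consistency_error")
  }
  mean_pa1 <- rowMeans(m[, pa, drop = FALSE])
  mean_high <- rowMeans(m[, high, drop = FALSE])
  tibble::tibble(gene = rownames(m), mean_pa1 = unname(mean_pa1),
                 mean_high = unname(mean_high),
                 difference = unname(mean_pa1 - mean_high))
}

#' Derive the gene signature separating PA I from the higher grades
#'
#' Applies [matches_criteria()] to each gene's four grade states and
#' keeps genes whose absolute class-mean log-ratio difference is at least
#' `lfc_threshold` (inclusive boundary; the default of 2 log2 units
#' corresponds to a four-fold expression difference between classes).
#'
#' @param states Stacked state table from [call_states_all()].
#' @param lr Wide log-ratio tibble of all tumor samples.
#' @param metadata Sample metadata.
#' @param lfc_threshold Minimum absolute class difference, log2 units
#'   (default 2).
#' @param strict Criteria quantifier, see [matches_criteria()].
#' @return Tibble with one row per signature gene: `gene`, the four
#'   per-grade states, `mean_pa1`, `mean_high`, `difference`,
#'   `criteria` (collapsed labels).
#' @export
derive_signature <- function(states, lr, metadata, lfc_threshold = 2,
                             strict = FALSE) {
  wide <- states |>
    dplyr::select("gene", "grade", "state") |>
    tidyr::pivot_wider(names_from = "grade", values_from = "state")
  if (!all(tumor_grades() %in% names(wide))) {
    abort_astro("state table must cover all four tumor grades",
                "astronet_consistency_error")
  }
  crit <- purrr::pmap(wide[tumor_grades()], function(PA1, AS2, AS3, GBM4) {
    matches_criteria(c(PA1 = PA1, AS2 = AS2, AS3 = AS3, GBM4 = GBM4),
                     strict = strict)
  })
  wide$match <- purrr::map_lgl(crit, "match")
  wide$criteria <- purrr::map_chr(crit, function(x) {
    paste(x$criteria, collapse = ",")
  })
  diff <- class_difference(lr, metadata)
  out <- wide |>
    dplyr::inner_join(diff, by = "gene") |>
    dplyr::filter(.data$match, abs(.data$difference) >= lfc_threshold) |>
    dplyr::select("gene", dplyr::all_of(tumor_grades()), "mean_pa1",
                  "mean_high", "difference", "criteria") |>
    dplyr::arrange(.data$gene)
  out
}

#' Composition of a signature with respect to annotation categories
#'
#' Counts how many signature genes fall in each annotation category and
#' expresses the overlap as a percentage of the signature size.
#'
#' @param signature_genes Character vector of signature genes.
#' @param annotations Named list of gene sets.
#' @return Tibble with columns `category`, `k`, `n`, `percent`
#'   (`100 * k / n`).
#' @export
signature_composition <- function(signature_genes, annotations) {
  n <- length(signature_genes)
  purrr::map_dfr(names(annotations), function(cat) {
    k <- length(intersect(annotations[[cat]], signature_genes))
    tibble::tibble(category = cat, k = k, n = n, percent = 100 * k / n)
  })
}
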