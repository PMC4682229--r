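#' Bar chart of differential-expression counts per grade
#'
#' Mirrors the grade-wise overview plot: numbers of under- and
#' overexpressed genes per WHO grade.
#'
#' @param states Stacked state table from [call_states_all()].
#' @return A ggplot object.
#' @export
plot_state_counts <- function(states) {
  counts <- states |>
    dplyr::filter(.data$state != "UNCHANGED") |>
    dplyr::count(.data$grade, .data$state) |>
    dplyr::mutate(grade = factor(.data$grade, levels = tumor_grades()))
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = .data$grade, y = .data$n,
                               fill = .data$state)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(UNDER = "#3366aa",
                                          OVER = "#cc4433")) +
    ggplot2::labs(x = "WHO grade", y = "differentially expressed genes",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Per-sample subtype correlation profiles
#'
#' One line per sample across the subtype centroids, with the assigned
#' subtype highlighted — the per-patient classification view.
#'
#' @param calls Output of [classify_subtypes()].
#' @return A ggplot object.
#' @export
plot_subtype_calls <- function(calls) {
  ggplot2::ggplot(calls,
                  ggplot2::aes(x = .data$subtype, y = .data$r,
                               group = .data$sample)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::geom_point(data = calls[calls$assigned, ],
                        color = "grey30", size = 2) +
    ggplot2::labs(x = NULL, y = "Pearson r with centroid") +
    ggplot2::theme_minimal()
}

#' Expression-versus-mutation deviation plane
#'
#' Scatter of per-TF mean expression change against mutation change,
#' colored by deviation category, with the threshold box drawn.
#'
#' @param assoc Output of [mutation_expression_map()].
#' @param deviation_threshold Threshold used for the categories.
#' @return A ggplot object.
#' @export
plot_mutation_map <- function(assoc, deviation_threshold = 1) {
  ggplot2::ggplot(assoc,
                  ggplot2::aes(x = .data$expr, y = .data$mutation,
                               color = .data$category)) +
    ggplot2::geom_hline(yintercept = c(-1, 1) * deviation_threshold,
                        linetype = "dashed", color = "grey70") +
    ggplot2::geom_vline(xintercept = c(-1, 1) * deviation_threshold,
                        linetype = "dashed", color = "grey70") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "mean expression log-ratio",
                  y = paste0("mean ", unique(assoc$layer), " log-ratio")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Out-degree distribution of a regulatory network
#'
#' @param object An `astro_network`.
#' @param ... Unused.
#' @return A ggplot object: TFs ranked by outgoing links, split into
#'   links to TFs and to non-TF signature genes.
#' @method autoplot astro_network
#' @export
autoplot.astro_network <- function(object, ...) {
  rep <- hub_ranking(object)
  long <- rep |>
    dplyr::mutate(other = .data$out_degree - .data$out_degree_tf) |>
    tidyr::pivot_longer(c("out_degree_tf", "other"),
                        names_to = "kind", values_to = "n") |>
    dplyr::mutate(kind = ifelse(.data$kind == "out_degree_tf",
                                "to TFs", "to other signature genes"))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = stats::reorder(.data$tf,
                                                  -.data$n,
                                                  FUN = sum),
                               y = .data$n, fill = .data$kind)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "outgoing regulatory links", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Coefficient trajectories of a lasso path
#'
#' @param object An `astro_lasso_path`.
#' @param ... Unused.
#' @return A ggplot object of standardized coefficients against the
#'   penalty.
#' @method autoplot astro_lasso_path
#' @export
autoplot.astro_lasso_path <- function(object, ...) {
  if (length(object$knots) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void())
  }
  df <- tibble::as_tibble(t(object$beta))
  df$lambda <- object$knots
  long <- tidyr::pivot_longer(df, -"lambda", names_to = "predictor",
                              values_to = "coefficient")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$lambda, y = .data$coefficient,
                               color = .data$predictor)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = expression(lambda), y = "standardized coefficient") +
    ggplot2::theme_minimal()
}
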