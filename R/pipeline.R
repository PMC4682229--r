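#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis: the q-value cutoff
#' for differential expression (default `1e-4`), the absolute class
#' log-ratio difference for signature membership (default 2 log2 units),
#' the subtype-assignment significance level (default 0.05), the
#' covariance-test threshold for regulatory links (default `5e-5`), the
#' deviation threshold of the mutation map (default 1 log2 unit), and
#' the run seed. Input paths are optional; when absent the simulate
#' stage generates the cohort.
#'
#' @param q_threshold DE q-value cutoff, in (0, 1).
#' @param lfc_threshold Signature class-difference cutoff, > 0.
#' @param subtype_alpha Subtype significance level, in (0, 1).
#' @param network_p_threshold Covariance-test cutoff, in (0, 1).
#' @param deviation_threshold Mutation-map deviation cutoff, > 0.
#' @param seed Integer run seed.
#' @param expression_path,metadata_path Optional input TSVs; when `NULL`
#'   a cohort is simulated with `sim`.
#' @param centroid_path Optional centroid TSV (synthetic centroids are
#'   generated otherwise).
#' @param annotation_path Optional annotation TSV (the simulated TF set
#'   is used otherwise).
#' @param sim A [sim_config()] for the simulate stage.
#' @param out_dir Output directory for stage files.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(q_threshold = 1e-4, lfc_threshold = 2,
                            subtype_alpha = 0.05,
                            network_p_threshold = 5e-5,
                            deviation_threshold = 1, seed = 1L,
                            expression_path = NULL, metadata_path = NULL,
                            centroid_path = NULL, annotation_path = NULL,
                            sim = NULL, out_dir = tempfile("astronet_run_")) {
  probs <- c(q_threshold, subtype_alpha, network_p_threshold)
  if (any(probs <= 0 | probs >= 1)) {
    abort_astro("probability thresholds must lie in (0, 1)",
                "astronet_config_error")
  }
  if (lfc_threshold <= 0 || deviation_threshold <= 0) {
    abort_astro("lfc_threshold and deviation_threshold must be positive",
                "astronet_config_error")
  }
  if (is.null(sim)) sim <- sim_config(seed = seed)
  structure(list(q_threshold = q_threshold, lfc_threshold = lfc_threshold,
                 subtype_alpha = subtype_alpha,
                 network_p_threshold = network_p_threshold,
                 deviation_threshold = deviation_threshold,
                 seed = as.integer(seed), expression_path = expression_path,
                 metadata_path = metadata_path,
                 centroid_path = centroid_path,
                 annotation_path = annotation_path, sim = sim,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Write or read a flat key:value pipeline-config file
#'
#' Scalar threshold fields are stored one per line as `key: value`.
#'
#' @param config A [pipeline_config()].
#' @param path Text file path.
#' @return `read_pipeline_config()` returns a `pipeline_config`;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  keys <- c("q_threshold", "lfc_threshold", "subtype_alpha",
            "network_p_threshold", "deviation_threshold", "seed")
  lines <- vapply(keys, function(k) {
    paste0(k, ": ", format(config[[k]], digits = 15))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, ":", fixed = TRUE)
  vals <- stats::setNames(
    lapply(kv, function(x) as.numeric(trimws(paste(x[-1], collapse = ":")))),
    vapply(kv, function(x) trimws(x[1]), character(1))
  )
  do.call(pipeline_config, vals)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> differential expression -> subtype
#' classification -> signature derivation -> regulatory network
#' inference -> hub/hierarchy/mutation analysis -> cross-cohort
#' validation, writing each stage's outputs as TSV under
#' `config$out_dir` and returning a manifest with the config snapshot,
#' per-file MD5 digests and the headline counts. Reruns with an
#' identical config and seed reproduce the manifest exactly.
#'
#' @param config A [pipeline_config()].
#' @return A `run_manifest` list: `config`, `seed`, `stages`, `digests`
#'   (named MD5 strings), `counts` (list of summary counts) and `paths`.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  stages <- character(0)
  truth <- NULL

  # --- stage: input ---------------------------------------------------
  if (is.null(config$expression_path)) {
    sim <- simulate_cohort(config$sim)
    expr <- sim$expr; metadata <- sim$metadata; truth <- sim$truth
    write_expression(expr, out("expression.tsv"), metadata,
                     out("metadata.tsv"))
    readr::write_tsv(truth$de_sets, out("truth_de_sets.tsv"),
                     progress = FALSE)
    readr::write_tsv(matrix_to_expr(truth$coeff_matrix),
                     out("truth_coefficients.tsv"), progress = FALSE)
    stages <- c(stages, "simulate")
  } else {
    loaded <- read_expression(config$expression_path, config$metadata_path)
    expr <- loaded$expr; metadata <- loaded$metadata
    stages <- c(stages, "load")
  }
  write_pipeline_config(config, out("config.txt"))

  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      abort_astro(paste0("stage '", name, "' failed: ",
                         conditionMessage(e)),
                  "astronet_stage_error")
    })
  }

  # --- stage: differential expression ---------------------------------
  states <- run_stage("de", function() {
    st <- call_states_all(expr, metadata, q_threshold = config$q_threshold)
    readr::write_tsv(st, out("state_table.tsv"), progress = FALSE)
    for (dir in c("OVER", "UNDER")) {
      part <- exclusive_subsets(st, dir)
      readr::write_tsv(part, out(paste0("subsets_",
                                        tolower(dir), ".tsv")),
                       progress = FALSE)
    }
    st
  })
  stages <- c(stages, "de")
  de_counts <- states |>
    dplyr::filter(.data$state != "UNCHANGED") |>
    dplyr::count(.data$grade) |>
    (\(d) stats::setNames(d$n, d$grade))()
  de_counts <- de_counts[tumor_grades()]
  de_counts[is.na(de_counts)] <- 0
  names(de_counts) <- tumor_grades()
  trend <- if (stats::sd(de_counts) > 0) {
    grade_trend(de_counts, 1:4)
  } else tibble::tibble(r = NA_real_, p = NA_real_)

  lr <- to_log_ratios(expr, metadata, "NORMAL")

  # --- stage: subtype --------------------------------------------------
  centroids <- if (!is.null(config$centroid_path)) {
    read_centroids(config$centroid_path)
  } else {
    make_synthetic_centroids(
      n_genes = min(200, nrow(expr)),
      separation = config$sim$centroid_separation
    )
  }
  calls <- run_stage("subtype", function() {
    shared <- intersect(centroids$gene, lr$gene)
    if (length(shared) < 3) return(NULL)   # no centroid overlap: skip
    cl <- classify_subtypes(lr[lr$gene %in% shared, , drop = FALSE],
                            centroids, config$subtype_alpha)
    readr::write_tsv(cl, out("subtype_calls.tsv"), progress = FALSE)
    cl
  })
  stages <- c(stages, "subtype")

  # --- stage: signature ------------------------------------------------
  signature <- run_stage("signature", function() {
    sig <- derive_signature(states, lr, metadata, config$lfc_threshold)
    readr::write_tsv(sig, out("signature.tsv"), progress = FALSE)
    sig
  })
  stages <- c(stages, "signature")

  # --- stage: network --------------------------------------------------
  tf_universe <- if (!is.null(config$annotation_path)) {
    read_annotations(config$annotation_path)$TF
  } else if (!is.null(truth)) {
    rownames(truth$coeff_matrix)
  } else character(0)
  tf_set <- intersect(tf_universe, signature$gene)
  network <- run_stage("network", function() {
    net <- infer_network(signature$gene, lr, tf_set,
                         config$network_p_threshold)
    write_edge_list(net, out("edges.tsv"))
    net
  })
  stages <- c(stages, "network")

  # --- stage: analyze --------------------------------------------------
  hubs <- run_stage("analyze", function() {
    h <- hub_ranking(network, lr, metadata)
    readr::write_tsv(h, out("hubs.tsv"), progress = FALSE)
    readr::write_tsv(tf_hierarchy(network), out("tf_hierarchy.tsv"),
                     progress = FALSE)
    h
  })
  if (!is.null(truth)) {
    for (layer in c("methylation", "copy_number")) {
      mut <- simulate_mutation_layer(truth, layer, expr, metadata,
                                     seed = config$seed + 17L)
      contrast <- stats::setNames(hubs$expr_contrast, hubs$tf)
      assoc <- mutation_expression_map(contrast, mut,
                                       config$deviation_threshold)
      readr::write_tsv(assoc, out(paste0("mutation_map_", layer, ".tsv")),
                       progress = FALSE)
    }
  }
  stages <- c(stages, "analyze")

  # --- stage: validate -------------------------------------------------
  validation <- NULL
  if (!is.null(truth) && nrow(network$edges) > 0) {
    validation <- run_stage("validate", function() {
      cfg2 <- config$sim
      cfg2$seed <- config$sim$seed + 1000L
      cohort2 <- simulate_cohort(cfg2, truth = truth)
      lr2 <- to_log_ratios(cohort2$expr, cohort2$metadata, "NORMAL")
      pred <- predict_expression(network, lr2)
      vs <- validation_summary(pred$gene_cor)
      readr::write_tsv(pred$gene_cor, out("validation_gene_cor.tsv"),
                       progress = FALSE)
      vs
    })
    stages <- c(stages, "validate")
  }

  files <- sort(list.files(config$out_dir, full.names = TRUE))
  digests <- tools::md5sum(files)
  names(digests) <- basename(files)

  gl <- glance.astro_network(network)
  counts <- list(
    de_per_grade = de_counts,
    grade_trend_r = trend$r,
    grade_trend_p = trend$p,
    signature_size = nrow(signature),
    n_tfs = length(tf_set),
    possible_links = gl$possible_links,
    selected_links = gl$n_edges,
    n_activator = gl$n_activator,
    n_repressor = gl$n_repressor,
    genes_without_regulators = gl$n_genes_without_regulators,
    tfs_without_targets = gl$n_tfs_without_targets,
    validation_median_r = if (is.null(validation)) NA_real_ else
      validation$median_r
  )
  stopifnot(counts$selected_links <= counts$possible_links)

  structure(list(config = config, seed = config$seed, stages = stages,
                 digests = digests, counts = counts,
                 paths = stats::setNames(files, basename(files)),
                 states = states, signature = signature,
                 network = network, subtype_calls = calls, truth = truth),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("astronet pipeline run (seed ", x$seed, ")\n", sep = "")
  cat("  stages: ", paste(x$stages, collapse = " -> "), "\n", sep = "")
  cat("  DE genes per grade: ",
      paste(sprintf("%s=%d", names(x$counts$de_per_grade),
                    x$counts$de_per_grade), collapse = ", "), "\n",
      sep = "")
  cat(sprintf("  signature: %d genes (%d TFs)\n", x$counts$signature_size,
              x$counts$n_tfs))
  cat(sprintf("  network: %d of %d possible links (%d activator / %d repressor)\n",
              x$counts$selected_links, x$counts$possible_links,
              x$counts$n_activator, x$counts$n_repressor))
  invisible(x)
}
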