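#' Configuration for the synthetic astrocytoma cohort simulator
#'
#' The simulator emulates the statistical structure the analysis pipeline
#' assumes: a normal-brain baseline, grade-specific differential-expression
#' effects whose number grows with WHO grade, TF-driven signature-gene
#' expression through a sparse linear coefficient matrix, subtype labels,
#' and mutation layers coupled to TF expression.
#'
#' Gene universe layout: the first `n_tfs` genes are transcription factors
#' (`TF001`, ...), the next `n_targets` genes are TF-driven signature
#' targets (`TG001`, ...), and the remainder (`G0001`, ...) are free genes
#' that may carry planted grade-specific effects.
#'
#' @param n_genes Total number of genes (TFs + targets + free genes).
#' @param n_tfs Number of transcription factors.
#' @param n_targets Number of TF-driven signature target genes.
#' @param n_per_grade Tumor samples per grade (named or unnamed length-4,
#'   or a single count recycled).
#' @param n_ref Normal reference samples.
#' @param de_counts Planted differentially expressed free genes per grade,
#'   in grade order PA1, AS2, AS3, GBM4; defaults increase with grade to
#'   mirror the grade-wise trend observed in astrocytomas.
#' @param effect_range Range (log2 units) of planted effect magnitudes.
#' @param tf_effect_range Range of grade-specific TF expression shifts;
#'   signature TFs are differentially expressed by construction, so the
#'   default matches `effect_range`. Set to `c(0, 0)` for a global null.
#' @param density Probability that a given TF regulates a given target.
#' @param coef_range Range of absolute regulatory coefficient values.
#' @param noise_sd Gaussian expression noise, log2 units.
#' @param tf_biological_sd Per-sample biological variability of TF
#'   expression in tumors (log2 units), independent of grade; tumors
#'   are heterogeneous, and this patient-level TF variation is what
#'   propagates through the coefficient matrix to the target genes and
#'   makes the planted network identifiable.
#' @param n_subtypes Number of molecular subtypes for label assignment.
#' @param centroid_separation Log2 distance scale separating synthetic
#'   subtype centroids (used by [make_synthetic_centroids()]).
#' @param coupling_prob Probability a TF is coupled to a mutation layer.
#' @param coupling_strength_range Range of mutation-coupling strengths.
#' @param mutation_noise_sd Noise of the simulated mutation log-ratios.
#' @param seed Integer seed; all draws derive from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000, n_tfs = 20, n_targets = 200,
                       n_per_grade = 30, n_ref = 20,
                       de_counts = c(PA1 = 50, AS2 = 100, AS3 = 150,
                                     GBM4 = 300),
                       effect_range = c(1.5, 3), tf_effect_range = effect_range,
                       density = 0.02, coef_range = c(1, 3), noise_sd = 0.5,
                       tf_biological_sd = 1,
                       n_subtypes = 4, centroid_separation = 2,
                       coupling_prob = 0.5,
                       coupling_strength_range = c(1, 2),
                       mutation_noise_sd = 0.2, seed = 1L) {
  if (length(n_per_grade) == 1) n_per_grade <- rep(n_per_grade, 4)
  n_per_grade <- stats::setNames(as.integer(n_per_grade), tumor_grades())
  de_counts <- stats::setNames(as.integer(de_counts), tumor_grades())
  cfg <- list(
    n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
    n_targets = as.integer(n_targets), n_per_grade = n_per_grade,
    n_ref = as.integer(n_ref), de_counts = de_counts,
    effect_range = effect_range, tf_effect_range = tf_effect_range,
    density = density, coef_range = coef_range, noise_sd = noise_sd,
    tf_biological_sd = tf_biological_sd,
    n_subtypes = as.integer(n_subtypes),
    centroid_separation = centroid_separation,
    coupling_prob = coupling_prob,
    coupling_strength_range = coupling_strength_range,
    mutation_noise_sd = mutation_noise_sd, seed = as.integer(seed)
  )
  if (cfg$n_tfs >= cfg$n_genes) {
    abort_astro("n_tfs must be smaller than n_genes", "astronet_config_error")
  }
  if (cfg$n_tfs + cfg$n_targets > cfg$n_genes) {
    abort_astro("n_tfs + n_targets exceeds n_genes", "astronet_config_error")
  }
  n_free <- cfg$n_genes - cfg$n_tfs - cfg$n_targets
  if (any(cfg$de_counts > n_free)) {
    abort_astro("de_counts exceed the number of free (non-TF, non-target) genes",
                "astronet_config_error")
  }
  if (any(c(cfg$n_per_grade, cfg$n_ref, cfg$n_genes) < 1)) {
    abort_astro("all sample and gene counts must be positive",
                "astronet_config_error")
  }
  structure(cfg, class = "sim_config")
}

sim_gene_names <- function(cfg) {
  n_free <- cfg$n_genes - cfg$n_tfs - cfg$n_targets
  c(sprintf("TF%03d", seq_len(cfg$n_tfs)),
    sprintf("TG%03d", seq_len(cfg$n_targets)),
    if (n_free > 0) sprintf("G%04d", seq_len(n_free)))
}

#' Simulate an astrocytoma cohort with known ground truth
#'
#' Draws, in a documented order from a single seeded stream: (1) baseline
#' gene means `N(7, 2^2)` log2 units, (2) grade-specific TF shifts,
#' (3) planted DE gene sets per grade, (4) the sparse TF-by-target
#' coefficient matrix, (5) the expression noise matrix, (6) subtype labels
#' and mutation couplings. Normal samples are baseline plus noise; tumor
#' samples add their grade's planted effects; signature-target log-ratios
#' equal the coefficient matrix (transposed) times the TF log-ratios plus
#' noise, the generative analogue of the linear regulatory model.
#'
#' @param config A [sim_config()].
#' @param truth Optional ground truth from a previous run; when supplied,
#'   baselines, effects, coefficients, labels and couplings are reused and
#'   only sampling noise is redrawn (use a different `config$seed` to get
#'   an independent cohort from the same planted network).
#' @return List with `expr` (wide tibble), `metadata` (tibble) and
#'   `truth` (list: `baseline`, `tf_grade_effects`, `de_sets` tibble,
#'   `coeff_matrix` TF x target, `subtype_labels`, `mutation_couplings`,
#'   `noise_sd`, `seed`).
#' @export
simulate_cohort <- function(config, truth = NULL) {
  cfg <- config
  genes <- sim_gene_names(cfg)
  tf_genes <- genes[seq_len(cfg$n_tfs)]
  target_genes <- genes[cfg$n_tfs + seq_len(cfg$n_targets)]
  free_genes <- setdiff(genes, c(tf_genes, target_genes))

  samples <- c(
    sprintf("REF_%02d", seq_len(cfg$n_ref)),
    unlist(lapply(tumor_grades(), function(g) {
      sprintf("%s_%02d", g, seq_len(cfg$n_per_grade[[g]]))
    }))
  )
  grades <- c(rep("NORMAL", cfg$n_ref),
              rep(tumor_grades(), times = cfg$n_per_grade))
  metadata <- tibble::tibble(sample = samples, grade = grades,
                             cohort = "synthetic")

  set.seed(cfg$seed)

  if (is.null(truth)) {
    baseline <- stats::setNames(stats::rnorm(cfg$n_genes, 7, 2), genes)
    # grade-specific TF shifts: signature TFs are DE across grades
    tf_eff <- matrix(
      stats::runif(cfg$n_tfs * 4, cfg$tf_effect_range[1],
                   cfg$tf_effect_range[2]) *
        sample(c(-1, 1), cfg$n_tfs * 4, replace = TRUE),
      nrow = cfg$n_tfs, ncol = 4,
      dimnames = list(tf_genes, tumor_grades())
    )
    de_sets <- purrr::map_dfr(tumor_grades(), function(g) {
      k <- cfg$de_counts[[g]]
      if (k == 0) return(tibble::tibble(grade = character(), gene = character(),
                                        direction = character(),
                                        effect = numeric()))
      gs <- sample(free_genes, k)
      dir <- sample(c("OVER", "UNDER"), k, replace = TRUE)
      eff <- stats::runif(k, cfg$effect_range[1], cfg$effect_range[2])
      tibble::tibble(grade = g, gene = gs, direction = dir,
                     effect = ifelse(dir == "OVER", eff, -eff))
    })
    coeff <- matrix(0, cfg$n_tfs, cfg$n_targets,
                    dimnames = list(tf_genes, target_genes))
    mask <- matrix(stats::runif(length(coeff)) < cfg$density, nrow(coeff))
    nz <- sum(mask)
    coeff[mask] <- stats::runif(nz, cfg$coef_range[1], cfg$coef_range[2]) *
      sample(c(-1, 1), nz, replace = TRUE)
    subtype_labels <- stats::setNames(
      sample(paste0("S", seq_len(cfg$n_subtypes)),
             sum(cfg$n_per_grade), replace = TRUE),
      samples[grades != "NORMAL"]
    )
    couplings <- purrr::map_dfr(c("methylation", "copy_number"), function(ly) {
      coupled <- stats::runif(cfg$n_tfs) < cfg$coupling_prob
      strength <- ifelse(
        coupled,
        stats::runif(cfg$n_tfs, cfg$coupling_strength_range[1],
                     cfg$coupling_strength_range[2]),
        0
      )
      tibble::tibble(tf = tf_genes, layer = ly,
                     sign = ifelse(ly == "methylation", -1, 1),
                     strength = strength)
    })
    truth <- list(baseline = baseline, tf_grade_effects = tf_eff,
                  de_sets = de_sets, coeff_matrix = coeff,
                  subtype_labels = subtype_labels,
                  mutation_couplings = couplings,
                  noise_sd = cfg$noise_sd,
                  mutation_noise_sd = cfg$mutation_noise_sd, seed = cfg$seed)
  } else {
    baseline <- truth$baseline
    tf_eff <- truth$tf_grade_effects
    de_sets <- truth$de_sets
    coeff <- truth$coeff_matrix
  }

  n_samp <- length(samples)
  noise <- matrix(stats::rnorm(cfg$n_genes * n_samp, 0, cfg$noise_sd),
                  cfg$n_genes, n_samp, dimnames = list(genes, samples))

  expr <- matrix(baseline[genes], cfg$n_genes, n_samp,
                 dimnames = list(genes, samples)) + noise

  # patient-level biological TF variation in tumors (drawn after the
  # noise matrix so the stream order stays documented and reproducible)
  tumor_idx <- which(grades != "NORMAL")
  tf_bio <- matrix(stats::rnorm(cfg$n_tfs * length(tumor_idx), 0,
                                cfg$tf_biological_sd),
                   cfg$n_tfs, length(tumor_idx))
  expr[tf_genes, tumor_idx] <- expr[tf_genes, tumor_idx] + tf_bio

  # grade effects: planted DE genes and TF shifts on tumor columns
  for (g in tumor_grades()) {
    cols <- samples[grades == g]
    dg <- de_sets[de_sets$grade == g, , drop = FALSE]
    if (nrow(dg) > 0) {
      expr[dg$gene, cols] <- expr[dg$gene, cols] + dg$effect
    }
    expr[tf_genes, cols] <- expr[tf_genes, cols] + tf_eff[, g]
  }

  # signature targets: linear in the realized TF log-ratios
  ref_cols <- samples[grades == "NORMAL"]
  tumor_cols <- samples[grades != "NORMAL"]
  tf_lr <- expr[tf_genes, tumor_cols, drop = FALSE] -
    rowMeans(expr[tf_genes, ref_cols, drop = FALSE])
  expr[target_genes, tumor_cols] <-
    matrix(baseline[target_genes], cfg$n_targets, length(tumor_cols)) +
    t(coeff) %*% tf_lr + noise[target_genes, tumor_cols]

  list(expr = matrix_to_expr(expr), metadata = metadata, truth = truth)
}

#' Build well-separated synthetic subtype centroids
#'
#' Centroid vectors are orthogonal block patterns: each subtype elevates
#' its own block of genes by `separation` log2 units and leaves the rest
#' at zero, giving mutually near-orthogonal profiles.
#'
#' @param n_genes Number of centroid genes.
#' @param subtypes Character vector of subtype names.
#' @param separation Block height in log2 units.
#' @return Wide tibble (`gene` + one column per subtype).
#' @export
make_synthetic_centroids <- function(n_genes = 200,
                                     subtypes = c("Neural", "Proneural",
                                                  "Classical", "Mesenchymal"),
                                     separation = 2) {
  k <- length(subtypes)
  stopifnot(k >= 2, n_genes >= k)
  block <- rep(seq_len(k), length.out = n_genes)
  m <- sapply(seq_len(k), function(j) ifelse(block == j, separation, 0))
  colnames(m) <- subtypes
  dplyr::bind_cols(tibble::tibble(gene = sprintf("CG%04d", seq_len(n_genes))),
                   tibble::as_tibble(m))
}

#' Simulate samples around a subtype centroid
#'
#' Each simulated sample is the chosen centroid profile plus iid Gaussian
#' noise over genes — the generative model the centroid-correlation
#' classifier assumes.
#'
#' @param centroids Centroid tibble (`gene` + subtype columns).
#' @param label Subtype to draw from (must be a centroid column).
#' @param noise_sd Gaussian noise, log2 units.
#' @param n Number of samples.
#' @param seed Integer seed.
#' @param prefix Sample-name prefix.
#' @return Wide log-ratio tibble (`gene` + `n` sample columns).
#' @export
simulate_centroid_samples <- function(centroids, label, noise_sd, n, seed,
                                      prefix = label) {
  subtypes <- setdiff(names(centroids), "gene")
  if (!label %in% subtypes) {
    abort_astro(paste0("unknown subtype label: ", label),
                "astronet_config_error")
  }
  set.seed(seed)
  mu <- centroids[[label]]
  m <- matrix(stats::rnorm(length(mu) * n, 0, noise_sd), length(mu), n) + mu
  colnames(m) <- sprintf("%s_%03d", prefix, seq_len(n))
  rownames(m) <- centroids$gene
  matrix_to_expr(m)
}

#' Simulate a mutation layer coupled to TF expression
#'
#' For TFs coupled to the layer the mutation log-ratio equals
#' `sign * strength * mean TF expression log-ratio` plus noise; uncoupled
#' TFs are pure noise around zero. Methylation couplings are
#' sign-inverted (promoter hypermethylation goes with underexpression),
#' copy-number couplings are same-sign.
#'
#' @param truth Ground truth from [simulate_cohort()].
#' @param layer `"methylation"` or `"copy_number"`.
#' @param expr,metadata The simulated cohort (used to compute mean TF
#'   expression log-ratios).
#' @param seed Integer seed for the mutation noise.
#' @return Tibble with columns `gene`, `log_ratio`, `layer`.
#' @export
simulate_mutation_layer <- function(truth, layer = c("methylation",
                                                     "copy_number"),
                                    expr, metadata, seed = truth$seed + 1L) {
  layer <- match.arg(layer)
  lr <- to_log_ratios(expr, metadata, "NORMAL")
  m <- expr_to_matrix(lr)
  cp <- truth$mutation_couplings
  cp <- cp[cp$layer == layer, , drop = FALSE]
  mean_lr <- rowMeans(m[cp$tf, , drop = FALSE])
  set.seed(seed)
  noise_sd <- truth$mutation_noise_sd %||% 0.2
  vals <- cp$sign * cp$strength * mean_lr +
    stats::rnorm(nrow(cp), 0, noise_sd)
  tibble::tibble(gene = cp$tf, log_ratio = as.numeric(vals), layer = layer)
}
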