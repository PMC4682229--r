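toy_network <- function(edges) {
  tfs <- c("A", "B")
  genes <- c("A", "B", "g1", "g2")
  astronet:::new_astro_network(edges, genes, tfs)
}

test_that("hub ranking counts outgoing links and conserves the edge total", {
  edges <- tibble::tibble(
    tf = c("A", "A", "A", "B"), target = c("g1", "g2", "B", "g1"),
    coefficient = c(1, 2, 0.5, -1),
    sign = c("activator", "activator", "activator", "repressor"),
    p_value = rep(1e-6, 4)
  )
  net <- toy_network(edges)
  hubs <- hub_ranking(net)
  expect_equal(hubs$out_degree[hubs$tf == "A"], 3)
  expect_equal(hubs$out_degree[hubs$tf == "B"], 1)
  expect_equal(hubs$out_degree_tf[hubs$tf == "A"], 1)
  expect_equal(sum(hubs$out_degree), nrow(edges))
  expect_true(all(hubs$out_degree_tf <= hubs$out_degree))
  # empty network: all zeros
  empty <- toy_network(edges[0, ])
  expect_equal(hub_ranking(empty)$out_degree, c(0, 0))
})

test_that("TF hierarchy uses a strict threshold and matches a recount", {
  mk_edges <- function(n_tf_targets) {
    tibble::tibble(
      tf = "A",
      target = c(paste0("T", seq_len(n_tf_targets)), "g1"),
      coefficient = 1, sign = "activator", p_value = 1e-6
    )
  }
  tfs <- c("A", paste0("T", 1:6))
  net5 <- astronet:::new_astro_network(mk_edges(5), c(tfs, "g1"), tfs)
  expect_equal(nrow(tf_hierarchy(net5)), 0)     # exactly 5: excluded
  net6 <- astronet:::new_astro_network(mk_edges(6), c(tfs, "g1"), tfs)
  hi <- tf_hierarchy(net6)
  expect_equal(hi$tf, "A")
  expect_equal(hi$out_degree_tf, 6)
  # random toy network: equals brute-force count of TF-targeted edges
  set.seed(23)
  tfs <- paste0("F", 1:6)
  genes <- c(tfs, paste0("g", 1:10))
  edges <- tibble::tibble(
    tf = sample(tfs, 40, TRUE), target = sample(genes, 40, TRUE),
    coefficient = 1, sign = "activator", p_value = 1e-6
  )
  edges <- edges[edges$tf != edges$target, ]
  net <- astronet:::new_astro_network(edges, genes, tfs)
  for (th in 0:4) {
    manual <- table(factor(edges$tf[edges$target %in% tfs], levels = tfs))
    expect_setequal(tf_hierarchy(net, th)$tf,
                    names(manual)[manual > th])
  }
})

test_that("predicted expression follows the linear model and its contracts", {
  samples <- paste0("S", 1:8)
  set.seed(24)
  tfv <- rnorm(8)
  m <- rbind(TF1 = tfv, g1 = tfv, g2 = rnorm(8))
  colnames(m) <- samples
  lr <- tibble::as_tibble(m, rownames = "gene")
  edges <- tibble::tibble(tf = "TF1", target = "g1", coefficient = 1,
                          sign = "activator", p_value = 1e-9)
  net <- astronet:::new_astro_network(edges, c("g1", "g2"), "TF1")
  pred <- predict_expression(net, lr)
  # single unit edge: prediction is the TF profile, r = 1
  expect_equal(pred$gene_cor$r[pred$gene_cor$gene == "g1"], 1)
  expect_equal(pred$n_unregulated, 1)   # g2 counted separately
  expect_false("g2" %in% pred$predicted$gene)
  # missing TF: error names the affected genes
  expect_error(predict_expression(net, lr[lr$gene != "TF1", ]),
               "g1", class = "astronet_consistency_error")
})

test_that("noiseless synthetic data is reproduced exactly by the true network", {
  cfg <- sim_config(n_genes = 80, n_tfs = 4, n_targets = 12,
                    n_per_grade = 6, n_ref = 4, de_counts = c(2, 2, 2, 2),
                    noise_sd = 0, density = 0.5, seed = 25)
  sim <- simulate_cohort(cfg)
  lr <- to_log_ratios(sim$expr, sim$metadata)
  A <- sim$truth$coeff_matrix
  idx <- which(A != 0, arr.ind = TRUE)
  edges <- tibble::tibble(
    tf = rownames(A)[idx[, 1]], target = colnames(A)[idx[, 2]],
    coefficient = A[idx],
    sign = ifelse(A[idx] > 0, "activator", "repressor"),
    p_value = 1e-9
  )
  net <- astronet:::new_astro_network(edges, colnames(A), rownames(A))
  pred <- predict_expression(net, lr)
  m <- expr_to_matrix_test(lr)
  pm <- expr_to_matrix_test(pred$predicted)
  for (g in rownames(pm)) {
    expect_equal(pm[g, ], m[g, colnames(pm)], tolerance = 1e-10)
  }
})

test_that("mutation-expression categories follow the threshold and sign rules", {
  expr <- c(A = 0, B = 3, C = 0.2, D = 3, E = 3, F = -2)
  mut_cn <- tibble::tibble(gene = names(expr),
                           log_ratio = c(0, 0.1, 2, 2, -2, -1.5),
                           layer = "copy_number")
  got <- mutation_expression_map(expr, mut_cn, deviation_threshold = 1)
  expect_equal(got$category,
               c("CENTER", "EXPR_ONLY", "MUT_ONLY", "CONCORDANT",
                 "DISCORDANT", "CONCORDANT"))
  # methylation flips the expected coupling sign
  mut_me <- tibble::tibble(gene = c("D", "E"), log_ratio = c(2, -2),
                           layer = "methylation")
  got_me <- mutation_expression_map(expr[c("D", "E")], mut_me)
  expect_equal(got_me$category, c("DISCORDANT", "CONCORDANT"))
  # missing TFs are skipped with a message
  expect_message(
    skipped <- mutation_expression_map(expr, mut_me),
    "skipping"
  )
  expect_equal(nrow(skipped), 2)
})

test_that("stronger couplings drive coupled TFs toward concordance", {
  frac_conc <- sapply(c(0.5, 2, 4), function(strength) {
    cfg <- sim_config(n_genes = 150, n_tfs = 10, n_targets = 15,
                      n_per_grade = 10, n_ref = 8,
                      de_counts = c(3, 3, 3, 3), coupling_prob = 1,
                      coupling_strength_range = c(strength, strength),
                      mutation_noise_sd = 0.2, seed = 26)
    sim <- simulate_cohort(cfg)
    mut <- simulate_mutation_layer(sim$truth, "copy_number",
                                   sim$expr, sim$metadata)
    lr <- to_log_ratios(sim$expr, sim$metadata)
    m <- expr_to_matrix_test(lr)
    tfs <- rownames(sim$truth$coeff_matrix)
    contrast <- rowMeans(m[tfs, , drop = FALSE])
    got <- mutation_expression_map(contrast, mut)
    # concordance can only be judged where the expression deviation is
    # itself strong; restrict to those TFs
    strong <- got[abs(got$expr) >= 1, ]
    mean(strong$category == "CONCORDANT")
  })
  expect_true(all(diff(frac_conc) >= 0))
  expect_gt(frac_conc[3], 0.9)
})
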