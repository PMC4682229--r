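test_that("Welch test matches its closed form and stats::t.test", {
  # identical groups: t = 0, p = 1
  r <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  # frozen closed-form case: equal variances 1, mean difference 3
  r <- welch_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, -3 / sqrt(2 / 3), tolerance = 1e-10)  # = -3.674
  expect_equal(r$df, 4, tolerance = 1e-10)
  expect_equal(r$p, 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-12)

  # swapping groups negates t, p unchanged
  r2 <- welch_t(c(4, 5, 6), c(1, 2, 3))
  expect_equal(r2$t, -r$t)
  expect_equal(r2$p, r$p)

  # random cases against the base-R oracle
  set.seed(5)
  for (i in 1:20) {
    a <- rnorm(sample(3:15, 1)); b <- rnorm(sample(3:15, 1), mean = 0.5)
    got <- welch_t(a, b)
    ref <- t.test(a, b)
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$df, unname(ref$parameter), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }

  # degenerate conventions
  expect_equal(welch_t(c(1, 1), c(1, 1))$p, 1)
  zv <- welch_t(c(2, 2), c(1, 1))
  expect_equal(zv$p, 0)
  expect_true(zv$flagged)
})

test_that("FDR adjustment matches a manual step-up and handles edge cases", {
  expect_equal(adjust_fdr(0.03), 0.03)
  expect_equal(adjust_fdr(rep(0.2, 5)), rep(0.2, 5))

  p <- c(0.001, 0.01, 0.02, 0.8)
  # independent brute-force step-up: q_(i) = min over j >= i of p_(j)*n/j
  n <- length(p)
  ord <- order(p)
  q_manual <- numeric(n)
  for (i in seq_len(n)) {
    rank_i <- which(ord == i)
    q_manual[i] <- min(sapply(rank_i:n, function(j) {
      min(1, p[ord[j]] * n / j)
    }))
  }
  expect_equal(adjust_fdr(p), q_manual)
  expect_equal(adjust_fdr(p), c(0.004, 0.02, 8 / 300, 0.8))

  expect_error(adjust_fdr(c(0.1, 1.2)), class = "astronet_config_error")
  # Storey variant never exceeds BH and stays in [0, 1]
  set.seed(8)
  ps <- runif(50)
  qs <- adjust_fdr(ps, method = "storey")
  expect_true(all(qs <= adjust_fdr(ps) + 1e-12))
  expect_true(all(qs >= 0 & qs <= 1))
})

test_that("state calls respect the q-threshold and log-ratio sign", {
  cfg <- sim_config(n_genes = 400, n_tfs = 4, n_targets = 10,
                    n_per_grade = 20, n_ref = 20,
                    de_counts = c(20, 20, 20, 20),
                    effect_range = c(2, 2), noise_sd = 0.3, seed = 31)
  sim <- simulate_cohort(cfg)
  st <- call_states(sim$expr, sim$metadata, "PA1")
  de <- sim$truth$de_sets
  planted <- de[de$grade == "PA1", ]
  hit <- st[match(planted$gene, st$gene), ]
  # planted genes recovered with the right direction
  expect_gt(mean(hit$state == planted$direction), 0.9)
  # state definition: OVER/UNDER require q below threshold and the sign
  called <- st[st$state != "UNCHANGED", ]
  expect_true(all(called$q < 1e-4))
  expect_true(all(sign(called$mean_log_ratio) ==
                    ifelse(called$state == "OVER", 1, -1)))
  uncalled <- st[st$state == "UNCHANGED" & !st$flagged, ]
  expect_true(all(uncalled$q >= 1e-4))
})

test_that("state calling is invariant to gene and sample order", {
  toy <- toy_cohort(n_genes = 30, n_ref = 5, n_tum = 6, seed = 14)
  st <- call_states(toy$expr, toy$metadata, "PA1", q_threshold = 0.5)
  perm_genes <- sample(nrow(toy$expr))
  perm_cols <- c("gene", sample(setdiff(names(toy$expr), "gene")))
  st2 <- call_states(toy$expr[perm_genes, perm_cols],
                     toy$metadata[sample(nrow(toy$metadata)), ],
                     "PA1", q_threshold = 0.5)
  st2 <- st2[match(st$gene, st2$gene), ]
  expect_equal(st$t, st2$t, tolerance = 1e-12)
  expect_equal(st$q, st2$q, tolerance = 1e-12)
  expect_equal(st$state, st2$state)
})

test_that("exclusive subsets equal brute-force enumeration over all 15 cells", {
  set.seed(17)
  genes <- paste0("g", 1:50)
  st_mat <- matrix(sample(c("OVER", "UNDER", "UNCHANGED"), 200, TRUE,
                          prob = c(0.4, 0.2, 0.4)),
                   50, 4, dimnames = list(genes, tumor_grades()))
  states <- state_table_fixture(st_mat)
  for (dir in c("OVER", "UNDER")) {
    part <- exclusive_subsets(states, dir)
    # brute force: for each gene, collect exactly the grades with dir
    expected <- lapply(genes, function(g) {
      tumor_grades()[st_mat[g, ] == dir]
    })
    names(expected) <- genes
    expected <- expected[lengths(expected) > 0]
    expect_setequal(part$gene, names(expected))
    for (g in part$gene) {
      expect_equal(part$subset[part$gene == g],
                   paste(expected[[g]], collapse = "+"))
    }
    # partition cells are disjoint and cover all direction-positive genes
    expect_equal(anyDuplicated(part$gene), 0)
    expect_equal(sum(subset_counts(part)$n), length(expected))
  }
})

test_that("fixed state patterns land in the expected Venn cells", {
  st_mat <- matrix("UNCHANGED", 2, 4,
                   dimnames = list(c("gA", "gB"), tumor_grades()))
  st_mat["gA", ] <- "UNDER"                      # all four grades
  st_mat["gB", c("PA1", "GBM4")] <- "OVER"       # PA1 and GBM4 only
  states <- state_table_fixture(st_mat)
  expect_equal(exclusive_subsets(states, "UNDER")$subset,
               "PA1+AS2+AS3+GBM4")
  expect_equal(exclusive_subsets(states, "OVER")$subset, "PA1+GBM4")
})

test_that("Fisher enrichment equals exhaustive hypergeometric enumeration", {
  expect_equal(enrichment_fisher(0, 5, 3, 10), 1)
  expect_equal(enrichment_fisher(5, 5, 5, 5), 1)
  # N=10, K=5, n=5, k=5 -> 1/choose(10,5) = 1/252
  expect_equal(enrichment_fisher(5, 5, 5, 10), 1 / 252, tolerance = 1e-12)
  # exhaustive enumeration for all consistent configurations with N <= 20
  for (N in c(6, 11, 20)) {
    for (K in c(2, floor(N / 2))) {
      for (n in c(3, N - 2)) {
        for (k in 0:min(n, K)) {
          # oracle: sum the point probabilities of the tail directly
          tail <- sum(sapply(k:min(n, K), function(x) {
            choose(K, x) * choose(N - K, n - x) / choose(N, n)
          }))
          expect_equal(enrichment_fisher(k, n, K, N), tail,
                       tolerance = 1e-10)
        }
      }
    }
  }
  expect_error(enrichment_fisher(6, 5, 5, 10),
               class = "astronet_config_error")
})

test_that("grade trend reproduces Pearson correlation on counts", {
  expect_equal(grade_trend(c(10, 20, 30, 40))$r, 1)
  expect_equal(grade_trend(c(40, 30, 20, 10))$r, -1)
  # hand-computed covariance / variance ratio
  counts <- c(100, 180, 190, 400)
  g <- 1:4
  r_manual <- sum((counts - mean(counts)) * (g - mean(g))) /
    sqrt(sum((counts - mean(counts))^2) * sum((g - mean(g))^2))
  tr <- grade_trend(counts)
  expect_equal(tr$r, r_manual, tolerance = 1e-12)
  expect_equal(round(tr$r, 3), 0.917)
  expect_error(grade_trend(c(5, 5, 5, 5)), class = "astronet_config_error")
})

test_that("category enrichment counts overlaps against the full universe", {
  st_mat <- matrix("UNCHANGED", 20, 4,
                   dimnames = list(paste0("g", 1:20), tumor_grades()))
  st_mat[1:5, "GBM4"] <- "OVER"
  states <- state_table_fixture(st_mat)
  ann <- list(TF = paste0("g", 1:4), kinase = paste0("g", 10:12))
  enr <- enrichment_by_grade(states, ann, "OVER")
  gbm_tf <- enr[enr$grade == "GBM4" & enr$category == "TF", ]
  expect_equal(gbm_tf$k, 4)
  expect_equal(gbm_tf$n, 5)
  expect_equal(gbm_tf$p, enrichment_fisher(4, 5, 4, 20))
  expect_equal(enr$k[enr$grade == "PA1" & enr$category == "TF"], 0)
})
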