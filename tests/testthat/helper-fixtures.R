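# Small fixtures built in code, shared across test files.

# Wide tibble (gene + sample columns) to matrix, independent of the
# package's own converter.
expr_to_matrix_test <- function(x) {
  m <- as.matrix(x[setdiff(names(x), "gene")])
  rownames(m) <- x$gene
  m
}

# A tiny deterministic expression cohort: `genes` x (refs + tumors).
toy_cohort <- function(n_genes = 5, n_ref = 3, n_tum = 4,
                       grade = "PA1", seed = 1) {
  set.seed(seed)
  genes <- paste0("g", seq_len(n_genes))
  samples <- c(paste0("N", seq_len(n_ref)), paste0("T", seq_len(n_tum)))
  m <- matrix(rnorm(n_genes * length(samples), 7, 1), n_genes,
              dimnames = list(genes, samples))
  expr <- tibble::as_tibble(m, rownames = "gene")
  metadata <- tibble::tibble(
    sample = samples,
    grade = c(rep("NORMAL", n_ref), rep(grade, n_tum))
  )
  list(expr = expr, metadata = metadata)
}

# Hand-assembled state table over all four grades for a set of genes.
state_table_fixture <- function(states_by_grade) {
  genes <- rownames(states_by_grade)
  purrr::map_dfr(colnames(states_by_grade), function(g) {
    tibble::tibble(gene = genes, grade = g, t = 0, p = 1, q = 1,
                   mean_log_ratio = 0,
                   state = states_by_grade[, g], flagged = FALSE)
  })
}

# Orthonormal design with n rows and p columns (Q from a QR decomposition).
orthonormal_design <- function(n, p, seed = 1) {
  set.seed(seed)
  # center before the QR so the columns are orthonormal AND orthogonal
  # to the intercept: the path's internal response centering is then a
  # no-op and inner products are preserved exactly
  M <- scale(matrix(rnorm(n * p), n, p), center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(M))
  colnames(Q) <- paste0("x", seq_len(p))
  Q
}

# Exhaustive six-criteria oracle for signature membership, written
# criterion by criterion. Forward criteria (one per PA I state s):
# PA I shows s and at least one higher grade does not (strict: no
# higher grade does). Reverse criteria: a higher grade shows a state s
# that PA I does not (strict: every higher grade shows a state PA I
# does not, which the forward criteria already imply).
criteria_oracle <- function(pa1, as2, as3, gbm4, strict = FALSE) {
  high <- c(as2, as3, gbm4)
  states <- c("UNDER", "UNCHANGED", "OVER")
  fwd <- vapply(states, function(s) {
    if (strict) pa1 == s && all(high != s) else pa1 == s && any(high != s)
  }, logical(1))
  rev <- vapply(states, function(s) {
    if (strict) pa1 != s && all(high == s) else pa1 != s && any(high == s)
  }, logical(1))
  any(fwd) || any(rev)
}
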