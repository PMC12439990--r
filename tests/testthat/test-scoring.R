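make_counts <- function(values, gene_ids, cell_ids) {
  matrix(values, nrow = length(gene_ids),
         dimnames = list(gene_ids, cell_ids))
}

test_that("qc_filter applies strict thresholds and reports per rule", {
  # three cells with 150 / 300 / 6000 detected genes
  set.seed(1)
  n_g <- 7000
  m <- Matrix::Matrix(0, n_g, 3, sparse = TRUE,
                      dimnames = list(sprintf("GENE%04d", 1:n_g), c("a", "b", "c")))
  m[1:150, 1] <- 1; m[1:300, 2] <- 1; m[1:6000, 3] <- 1
  res <- qc_filter(m, min_features = 200, max_features = 5000)
  expect_equal(colnames(res$counts), "b")
  expect_equal(res$report$removed_per_rule[["min_features"]], 1L)
  expect_equal(res$report$removed_per_rule[["max_features"]], 1L)

  # disabled thresholds: identity
  res0 <- qc_filter(m)
  expect_identical(res0$counts, m)

  # strict "less than" on the mitochondrial fraction
  m2 <- make_counts(c(10, 90, 4.9, 95.1), c("MT-ND1", "OTHER"),
                    c("mito10", "mito049"))
  res2 <- qc_filter(m2, max_mito_frac = 0.05)
  expect_equal(colnames(res2$counts), "mito049")

  # idempotence
  resA <- qc_filter(m, min_features = 200, max_features = 5000)
  resB <- qc_filter(resA$counts, min_features = 200, max_features = 5000)
  expect_identical(as.matrix(resA$counts), as.matrix(resB$counts))

  expect_error(qc_filter(m, min_features = 10, max_features = 5), "min_features")
})

test_that("CP10K normalization matches the closed form and preserves zeros", {
  m <- make_counts(c(10, 9990, 0, 5, 5, 0), c("g1", "g2", "g3"),
                   c("c1", "c2"))
  norm <- normalize_cp10k(m)
  expect_equal(norm["g1", "c1"], log(1 + 10), tolerance = 1e-12)
  expect_equal(norm["g3", "c1"], 0)
  # scale invariance: doubling a cell's counts leaves its profile unchanged
  m2 <- m; m2[, 1] <- m[, 1] * 2
  expect_equal(normalize_cp10k(m2)[, 1], norm[, 1], tolerance = 1e-12)
  # sparse input: sparsity pattern preserved
  sp <- Matrix::Matrix(m, sparse = TRUE)
  nsp <- normalize_cp10k(sp)
  expect_s4_class(nsp, "CsparseMatrix")
  expect_equal(as.matrix(nsp != 0), as.matrix(m != 0))
  # zero-total cell is named in the error
  m3 <- cbind(m, empty = c(0, 0, 0))
  expect_error(normalize_cp10k(m3), "empty")
})

test_that("module score is zero on a constant matrix and deterministic", {
  m <- matrix(2, 50, 8, dimnames = list(sprintf("G%02d", 1:50),
                                        sprintf("C%d", 1:8)))
  gs <- gene_set("p", c("G01", "G05", "G09"))
  s <- module_score(m, gs, n_bins = 5, seed = 1)
  expect_true(all(s$score == 0))
  s2 <- module_score(m, gs, n_bins = 5, seed = 1)
  expect_identical(s$score, s2$score)
  expect_error(module_score(m, gs, n_bins = 100, seed = 1), "n_bins")
  expect_error(module_score(m, gene_set("q", "ABSENT"), n_bins = 5, seed = 1),
               "present")
  expect_warning(module_score(m, gene_set("r", c("G01", "ABSENT")),
                              n_bins = 5, seed = 1), "dropped")
})

test_that("module score recovers a uniform shift against matched controls", {
  delta <- 0.5
  fx <- build_shift_matrix(delta)
  gs <- gene_set("prog", fx$prog)
  s <- module_score(fx$m, gs, n_bins = 10, seed = 11)
  expect_lt(abs(mean(s$score) - delta), 0.05 * delta)
  # sampling-free oracle: exhaustive control pool
  se <- module_score(fx$m, gs, n_bins = 10, seed = 11,
                     exhaustive_controls = TRUE)
  expect_lt(max(abs(s$score - se$score)), 0.03)
  # location equivariance: a global constant cancels between program and
  # controls
  s3 <- module_score(fx$m + 3, gs, n_bins = 10, seed = 11)
  expect_equal(s3$score, s$score, tolerance = 1e-12)
})

test_that("no-signal matrices score near zero", {
  set.seed(21)
  m <- matrix(rnorm(400 * 60, 5, 1), 400, 60,
              dimnames = list(sprintf("G%03d", 1:400), sprintf("C%02d", 1:60)))
  gs <- gene_set("null", sample(rownames(m), 25))
  s <- module_score(m, gs, seed = 2)
  expect_lt(abs(mean(s$score)), 0.02)
})

test_that("co-expression score is the cell-wise minimum", {
  mk <- function(x, nm) structure(
    list(score = x, score_name = nm, n_bins = 24L, n_ctrl = 100L,
         control_seed = 0L), class = "module_score")
  a <- mk(c(c1 = 0.5, c2 = -0.3, c3 = 0.1), "a")
  b <- mk(c(c1 = 0.2, c2 = 0.4, c3 = 0.1), "b")
  co <- coexpression_score(a, b)
  expect_equal(unname(co$score), c(0.2, -0.3, 0.1))
  expect_true(all(co$score <= a$score & co$score <= b$score))
  expect_equal(coexpression_score(a, a)$score, a$score)
  b_mis <- mk(c(x1 = 0.2, x2 = 0.4, x3 = 0.1), "b")
  expect_error(coexpression_score(a, b_mis), "different cells")
})

test_that("intermediate gating is strict at the cutoff and counts per subject", {
  vals <- rbind(ACTA2 = c(1.6, 1.5, 2.0, 0.0, 1.51, 3.0),
                CSPG4 = c(1.7, 2.0, 1.2, 2.0, 1.6, 0.1))
  colnames(vals) <- sprintf("c%d", 1:6)
  cells <- data.frame(cell_id = colnames(vals),
                      subject_id = rep("S01", 6))
  g <- gate_intermediate(vals, cells)
  # hand count: c1 (1.6, 1.7) and c5 (1.51, 1.6); c2 fails the strict cutoff
  expect_equal(unname(g$positive), c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(g$subject_counts$numerator, 2L)
  expect_equal(g$subject_counts$denominator, 6L)

  # invariance to column order
  perm <- c(4, 2, 6, 1, 3, 5)
  g2 <- gate_intermediate(vals[, perm], cells)
  expect_equal(g2$subject_counts, g$subject_counts)
  expect_error(gate_intermediate(vals, cells, gene_a = "MISSING"), "MISSING")
})

test_that("gene ranking is the signed -log10 p, deterministically ordered", {
  de <- data.frame(gene = c("B", "A", "C", "D"),
                   avg_log2FC = c(-2, 0.5, 0, 1),
                   p_value = c(0.01, 0.001, 0.5, 0.1))
  r <- rank_genes(de)
  expect_equal(r$rank_score[r$gene == "B"], -2)
  expect_equal(r$rank_score[r$gene == "A"], 3)
  expect_equal(r$rank_score[r$gene == "C"], 0)
  # zero-logFC genes rank after all positives, before negatives
  expect_equal(r$gene, c("A", "D", "C", "B"))
  # lexicographic tie-break
  de2 <- data.frame(gene = c("Z", "M"), avg_log2FC = c(1, 1),
                    p_value = c(0.1, 0.1))
  expect_equal(rank_genes(de2)$gene, c("M", "Z"))
  expect_error(rank_genes(data.frame(gene = "A", avg_log2FC = 1, p_value = 0)),
               "floor")
})
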