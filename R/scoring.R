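#' Quality-control filter on a raw count matrix
#'
#' Retains cells passing every enabled threshold.  All comparisons are strict
#' ("more than" / "less than"): a cell passes `min_features` with strictly
#' more detected genes, and passes `max_mito_frac` with a mitochondrial read
#' fraction strictly below the cutoff.  A `NULL` threshold is disabled.  A
#' cell failing several rules is attributed to each rule in the report.
#'
#' @param counts genes x cells matrix (dense or sparse) with dimnames.
#' @param min_features,max_features strict bounds on detected genes per cell.
#' @param max_mito_frac,max_ribo_frac strict upper bounds on the fraction of
#'   counts from mitochondrial / ribosomal genes.
#' @param min_counts strict lower bound on total counts per cell.
#' @param mito_prefix,ribo_prefix identifier prefixes marking mitochondrial
#'   and ribosomal genes.
#' @return list with `counts` (filtered matrix), `keep` (logical per input
#'   cell) and `report` (cells removed per rule plus totals).
#' @export
qc_filter <- function(counts, min_features = NULL, max_features = NULL,
                      max_mito_frac = NULL, max_ribo_frac = NULL,
                      min_counts = NULL,
                      mito_prefix = "MT-", ribo_prefix = c("RPL", "RPS")) {
  if (!is.null(min_features) && !is.null(max_features) &&
      min_features > max_features)
    stop_config("min_features exceeds max_features", "min_features")
  n_features <- Matrix::colSums(counts > 0)
  totals <- Matrix::colSums(counts)

  gene_ids <- rownames(counts)
  has_prefix <- function(prefixes)
    Reduce(`|`, lapply(prefixes, function(p) startsWith(gene_ids, p)),
           accumulate = FALSE)
  frac_of <- function(prefixes) {
    sel <- has_prefix(prefixes)
    if (!any(sel)) return(rep(0, ncol(counts)))
    Matrix::colSums(counts[sel, , drop = FALSE]) / pmax(totals, 1)
  }

  fail <- list()
  if (!is.null(min_features)) fail$min_features <- !(n_features > min_features)
  if (!is.null(max_features)) fail$max_features <- !(n_features < max_features)
  if (!is.null(max_mito_frac))
    fail$max_mito_frac <- !(frac_of(mito_prefix) < max_mito_frac)
  if (!is.null(max_ribo_frac))
    fail$max_ribo_frac <- !(frac_of(ribo_prefix) < max_ribo_frac)
  if (!is.null(min_counts)) fail$min_counts <- !(totals > min_counts)

  keep <- if (length(fail)) !Reduce(`|`, fail) else rep(TRUE, ncol(counts))
  report <- list(
    n_input = ncol(counts),
    n_retained = sum(keep),
    removed_per_rule = vapply(fail, sum, integer(1))
  )
  list(counts = counts[, keep, drop = FALSE], keep = keep, report = report)
}

#' Depth-normalize counts (log CP10K)
#'
#' Per-cell depth normalization: `ln(1 + count / cell_total * scale_factor)`.
#' A column-only operation, so the sparsity pattern is preserved and zeros
#' map to zeros.
#'
#' @param counts genes x cells matrix, every cell with total count > 0.
#' @param scale_factor target depth (default 10,000).
#' @return normalized matrix of the same shape and dimnames (sparse in,
#'   sparse out).
#' @export
normalize_cp10k <- function(counts, scale_factor = 10000) {
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) {
    bad <- colnames(counts)[totals == 0]
    if (is.null(bad)) bad <- which(totals == 0)
    stop(sprintf("cell(s) with zero total count: %s",
                 paste(head(bad, 5), collapse = ", ")))
  }
  if (is(counts, "sparseMatrix")) {
    m <- as(counts, "CsparseMatrix")
    # x slot holds the nonzeros column by column; scale each by its column total
    col_of <- rep(seq_len(ncol(m)), diff(m@p))
    m@x <- log1p(m@x / totals[col_of] * scale_factor)
    m
  } else {
    log1p(sweep(counts, 2, totals, "/") * scale_factor)
  }
}

# Equal-count expression bins over the gene universe (ranked by per-gene mean
# expression, ties broken by order) -- the control-matching structure of the
# binned-control module score.
expression_bins <- function(gene_means, n_bins) {
  r <- rank(gene_means, ties.method = "first")
  as.integer(cut(r, breaks = seq(0.5, length(r) + 0.5, length.out = n_bins + 1)))
}

#' Binned-control gene-program score
#'
#' Per-cell program score with expression-matched controls: all genes are
#' binned into `n_bins` equal-count bins by average normalized expression;
#' for each program gene, `n_ctrl` control genes are sampled from its bin
#' (without replacement when the bin is large enough, with replacement
#' otherwise); the score is the mean over program genes minus the mean over
#' the pooled control genes, per cell.  Matching controls on expression
#' removes the depth/abundance component that a raw program mean would carry.
#'
#' @param norm normalized genes x cells matrix with gene dimnames.
#' @param geneset a [gene_set()]; genes absent from the matrix are dropped
#'   with a warning.
#' @param n_bins number of expression bins (default 24).
#' @param n_ctrl control genes sampled per program gene (default 100).
#' @param seed integer controlling control sampling.
#' @param exhaustive_controls if `TRUE`, use every gene in each program
#'   gene's bin as control (no sampling); intended as a sampling-free
#'   reference.
#' @param cells optional character vector restricting scoring to a cell
#'   subset.
#' @return object of class `module_score`: `score` (named per-cell vector),
#'   `score_name`, `n_bins`, `n_ctrl`, `control_seed`.
#' @export
module_score <- function(norm, geneset, n_bins = 24, n_ctrl = 100, seed = 0L,
                         exhaustive_controls = FALSE, cells = NULL) {
  stopifnot(inherits(geneset, "gene_set"))
  if (!is.null(cells)) norm <- norm[, cells, drop = FALSE]
  universe <- rownames(norm)
  if (n_bins > nrow(norm))
    stop_config("n_bins exceeds the number of genes", "n_bins")
  present <- intersect(geneset$genes, universe)
  if (!length(present))
    stop(sprintf("no genes of set '%s' are present in the matrix", geneset$name))
  if (length(present) < length(geneset$genes))
    warning(sprintf("%d/%d genes of set '%s' absent from the matrix; dropped",
                    length(geneset$genes) - length(present),
                    length(geneset$genes), geneset$name))

  gene_means <- Matrix::rowMeans(norm)
  bins <- expression_bins(gene_means, n_bins)
  names(bins) <- universe

  set.seed(derive_seed(seed, paste0("module_score:", geneset$name)))
  ctrl <- character(0)
  for (g in present) {
    pool <- universe[bins == bins[[g]]]
    ctrl <- c(ctrl, if (exhaustive_controls) pool
              else sample(pool, n_ctrl, replace = length(pool) < n_ctrl))
  }
  prog_mean <- Matrix::colMeans(norm[present, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(norm[ctrl, , drop = FALSE])
  structure(list(
    score = setNames(as.numeric(prog_mean - ctrl_mean), colnames(norm)),
    score_name = geneset$name,
    n_bins = as.integer(n_bins),
    n_ctrl = as.integer(n_ctrl),
    control_seed = as.integer(seed)
  ), class = "module_score")
}

#' @export
print.module_score <- function(x, ...) {
  cat("module score '", x$score_name, "' over ", length(x$score),
      " cells (mean ", signif(mean(x$score), 3), ")\n", sep = "")
  invisible(x)
}

#' Co-expression score: per-cell minimum of two program scores
#'
#' High only where both programs are active, which is what distinguishes a
#' genuine myofibroblast-like state (contraction AND extracellular-matrix
#' programs on) from either canonical smooth-muscle state alone.
#'
#' @param score_a,score_b `module_score` objects over the same cells.
#' @return a `module_score` whose `score` is the cell-wise minimum.
#' @export
coexpression_score <- function(score_a, score_b) {
  stopifnot(inherits(score_a, "module_score"), inherits(score_b, "module_score"))
  if (!identical(names(score_a$score), names(score_b$score)))
    stop("component scores cover different cells; align them first")
  structure(list(
    score = pmin(score_a$score, score_b$score),
    score_name = paste0("min(", score_a$score_name, ",", score_b$score_name, ")"),
    n_bins = score_a$n_bins,
    n_ctrl = score_a$n_ctrl,
    control_seed = score_a$control_seed
  ), class = "module_score")
}

#' Gate double-positive (intermediate-state) cells
#'
#' A cell is called intermediate when its normalized expression of both
#' marker genes strictly exceeds the cutoff (default markers ACTA2 and
#' CSPG4, cutoff 1.5 on the log-normalized scale).  Per-subject numerators
#' (double-positive cells) and denominators (all cells of that subject in the
#' matrix) feed the subject-level proportion model.
#'
#' @param norm normalized genes x cells matrix.
#' @param cells cell table with `cell_id` and `subject_id` covering the
#'   matrix columns.
#' @param gene_a,gene_b marker genes (both required to be present).
#' @param cutoff strict threshold on the normalized value.
#' @return list with `positive` (named logical per cell) and
#'   `subject_counts` (`subject_id`, `numerator`, `denominator`).
#' @export
gate_intermediate <- function(norm, cells, gene_a = "ACTA2", gene_b = "CSPG4",
                              cutoff = 1.5) {
  for (g in c(gene_a, gene_b)) {
    if (!g %in% rownames(norm)) stop(sprintf("gene '%s' not in the matrix", g))
  }
  pos <- as.numeric(norm[gene_a, ]) > cutoff & as.numeric(norm[gene_b, ]) > cutoff
  names(pos) <- colnames(norm)
  subj <- cells$subject_id[match(colnames(norm), cells$cell_id)]
  if (anyNA(subj)) stop("cell table does not cover every matrix column")
  counts <- data.frame(
    subject_id = sort(unique(subj)),
    stringsAsFactors = FALSE
  )
  counts$numerator <- as.integer(tapply(pos, subj, sum)[counts$subject_id])
  counts$denominator <- as.integer(table(subj)[counts$subject_id])
  list(positive = pos, subject_counts = counts)
}

#' Rank genes for enrichment analysis
#'
#' Signed significance ranking: `score = sign(avg_log2FC) * -log10(p_value)`,
#' sorted decreasing with lexicographic gene-identifier tie-breaks so the
#' ordering is deterministic.
#'
#' @param de data frame with columns `gene`, `avg_log2FC`, `p_value`
#'   (p-values in (0, 1\]).
#' @return the data frame with a `rank_score` column, sorted for input to a
#'   pre-ranked enrichment tool.
#' @export
rank_genes <- function(de) {
  stopifnot(all(c("gene", "avg_log2FC", "p_value") %in% names(de)))
  if (any(de$p_value <= 0))
    stop("p_value of 0 encountered; floor p-values (e.g. at the machine minimum) before ranking")
  if (any(de$p_value > 1)) stop("p_value above 1 encountered")
  de$rank_score <- sign(de$avg_log2FC) * (-log10(de$p_value))
  de[order(-de$rank_score, de$gene), , drop = FALSE]
}
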