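#' Configuration for the synthetic single-cell cohort generator
#'
#' Bundles and validates every parameter of the synthetic-data generator:
#' cohort layout, the genotype effect on lineage membership, the gene-program
#' signal along pseudotime, and the negative-binomial noise model.
#'
#' @param n_subjects_per_genotype subjects per genotype group (two groups:
#'   0 = reference, 1 = risk).
#' @param cells_per_subject_range integer pair; per-subject cell counts are
#'   drawn uniformly from this range (inclusive).
#' @param n_genes size of the gene universe; program genes are carved out of
#'   it and the remainder stay flat along pseudotime.
#' @param program_sizes named integer vector of program sizes.  Recognised
#'   names: `pericyte`, `contraction`, `ecm`, `myofibroblast`, `tgfb`.
#'   Programs are disjoint.
#' @param effect_beta_genotype log-odds shift, for genotype 1, of membership
#'   in the myofibroblast lineage (0 = null).
#' @param program_amplitude log-scale expression shift of program genes across
#'   the full pseudotime range (0 = no trajectory signal).
#' @param nb_dispersion negative-binomial size parameter shared by all genes;
#'   variance is `mu + mu^2 / nb_dispersion`, so large values approach
#'   Poisson noise.
#' @param baseline_log_mean_range range (natural log scale) of per-gene
#'   baseline mean counts.
#' @param age_range subject age range in years.
#' @param seed integer seed; the generator is fully deterministic given the
#'   config.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_subjects_per_genotype = 20,
                         cells_per_subject_range = c(20L, 60L),
                         n_genes = 300,
                         program_sizes = c(pericyte = 20, contraction = 20,
                                           ecm = 20, myofibroblast = 20,
                                           tgfb = 10),
                         effect_beta_genotype = 0,
                         program_amplitude = 1,
                         nb_dispersion = 2,
                         baseline_log_mean_range = c(-2, 1.5),
                         age_range = c(60, 95),
                         seed = 1L) {
  # tolerate YAML round-trips, which deserialize vectors as lists
  program_sizes <- unlist(program_sizes)
  cells_per_subject_range <- unlist(cells_per_subject_range)
  baseline_log_mean_range <- unlist(baseline_log_mean_range)
  age_range <- unlist(age_range)
  check_scalar_number(n_subjects_per_genotype, "n_subjects_per_genotype",
                      lower = 1, integerish = TRUE)
  if (length(cells_per_subject_range) != 2L ||
      any(cells_per_subject_range < 1) ||
      cells_per_subject_range[1] > cells_per_subject_range[2])
    stop_config("'cells_per_subject_range' must be an increasing positive pair",
                "cells_per_subject_range")
  check_scalar_number(n_genes, "n_genes", lower = 1, integerish = TRUE)
  if (is.null(names(program_sizes)) || any(!nzchar(names(program_sizes))))
    stop_config("'program_sizes' must be a named vector", "program_sizes")
  known <- c("pericyte", "contraction", "ecm", "myofibroblast", "tgfb")
  bad <- setdiff(names(program_sizes), known)
  if (length(bad))
    stop_config(sprintf("unknown program name(s): %s", paste(bad, collapse = ", ")),
                "program_sizes")
  if (any(program_sizes < 1))
    stop_config("all program sizes must be strictly positive", "program_sizes")
  if (sum(program_sizes) > n_genes)
    stop_config("program genes exceed the gene universe", "program_sizes")
  check_scalar_number(effect_beta_genotype, "effect_beta_genotype")
  check_scalar_number(program_amplitude, "program_amplitude")
  check_scalar_number(nb_dispersion, "nb_dispersion", lower = 0,
                      strict_lower = TRUE)
  if (length(baseline_log_mean_range) != 2L ||
      baseline_log_mean_range[1] > baseline_log_mean_range[2])
    stop_config("'baseline_log_mean_range' must be a non-decreasing pair",
                "baseline_log_mean_range")
  if (length(age_range) != 2L || age_range[1] > age_range[2])
    stop_config("'age_range' must be a non-decreasing pair", "age_range")
  check_scalar_number(seed, "seed", integerish = TRUE)

  structure(list(
    n_subjects_per_genotype = as.integer(n_subjects_per_genotype),
    cells_per_subject_range = as.integer(cells_per_subject_range),
    n_genes = as.integer(n_genes),
    program_sizes = setNames(as.integer(program_sizes), names(program_sizes)),
    effect_beta_genotype = effect_beta_genotype,
    program_amplitude = program_amplitude,
    nb_dispersion = nb_dispersion,
    baseline_log_mean_range = as.numeric(baseline_log_mean_range),
    age_range = as.numeric(age_range),
    seed = as.integer(seed)
  ), class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("synthetic cohort config:",
      2L * x$n_subjects_per_genotype, "subjects,",
      x$n_genes, "genes;",
      "beta_genotype =", x$effect_beta_genotype,
      "| amplitude =", x$program_amplitude,
      "| NB size =", x$nb_dispersion, "\n")
  invisible(x)
}

#' Generate a synthetic subject cohort and cell skeleton
#'
#' Draws subjects for two genotype groups with age, sex and dataset
#' covariates, then assigns each subject its cells.  The returned cell table
#' has no pseudotime or lineage weights yet; see
#' [generate_lineage_weights()].
#'
#' @param config a [synth_config()] object.
#' @return list with `subjects` (one row per subject: `subject_id`,
#'   `genotype`, `age`, `sex`, `dataset`, `n_cells`) and `cells` (one row per
#'   cell: `cell_id`, `subject_id`, plus subject covariates).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synth_config"))
    stop_config("'config' must be a synth_config object", "config")
  set.seed(derive_seed(config$seed, "cohort"))
  n <- 2L * config$n_subjects_per_genotype
  subjects <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    genotype = rep(c(0L, 1L), each = config$n_subjects_per_genotype),
    age = runif(n, config$age_range[1], config$age_range[2]),
    sex = sample(c("F", "M"), n, replace = TRUE),
    dataset = sample(paste0("D", 1:3), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  rng <- config$cells_per_subject_range
  subjects$n_cells <- sample(seq(rng[1], rng[2]), n, replace = TRUE)

  cells <- data.frame(
    cell_id = sprintf("C%06d", seq_len(sum(subjects$n_cells))),
    subject_id = rep(subjects$subject_id, subjects$n_cells),
    stringsAsFactors = FALSE
  )
  idx <- match(cells$subject_id, subjects$subject_id)
  cells$genotype <- subjects$genotype[idx]
  cells$age <- subjects$age[idx]
  cells$sex <- subjects$sex[idx]
  cells$dataset <- subjects$dataset[idx]
  list(subjects = subjects, cells = cells)
}

#' Assign pseudotime and lineage curve weights to synthetic cells
#'
#' Each cell is assigned latent membership in the pericyte-to-myofibroblast
#' lineage with probability `plogis(alpha + effect_beta_genotype * genotype)`
#' (`alpha = 0`, so reference-genotype cells split 50/50).  The myofibroblast
#' curve weight is drawn from Beta(8, 2) for member cells and Beta(2, 8)
#' otherwise, the pericyte-lineage weight is its complement, and pseudotime
#' is uniform on \[0, 1\].  Positive `effect_beta_genotype` therefore biases
#' genotype-1 cells toward the myofibroblast lineage, mimicking
#' genotype-linked lineage bias.
#'
#' @param cells cell table from [generate_cohort()] (must carry `genotype`).
#' @param config a [synth_config()] object.
#' @return the cell table with `pseudotime`, `weight_lineage_myo`,
#'   `weight_lineage_peri` and the latent `lineage_membership` appended.
#' @export
generate_lineage_weights <- function(cells, config) {
  if (!inherits(config, "synth_config"))
    stop_config("'config' must be a synth_config object", "config")
  if (is.null(cells$genotype))
    stop_config("'cells' must carry a genotype column", "cells")
  set.seed(derive_seed(config$seed, "lineage"))
  n <- nrow(cells)
  p_myo <- plogis(0 + config$effect_beta_genotype * cells$genotype)
  m <- rbinom(n, 1L, p_myo)
  w <- ifelse(m == 1L, rbeta(n, 8, 2), rbeta(n, 2, 8))
  cells$pseudotime <- runif(n)
  cells$weight_lineage_myo <- w
  cells$weight_lineage_peri <- 1 - w
  cells$lineage_membership <- m
  cells
}

# Program direction along the effective myofibroblast pseudotime: the
# transition turns contraction/ECM/myofibroblast/TGF-beta programs on and the
# pericyte identity program off.
program_direction <- c(pericyte = -1, contraction = 1, ecm = 1,
                       myofibroblast = 1, tgfb = 1)

#' Simulate negative-binomial counts with trajectory-linked gene programs
#'
#' Gene `g` in program `P` has log mean `mu_g + amplitude * dir_P * t_eff`
#' where `t_eff = pseudotime * weight_myo / (weight_myo + weight_peri)` is
#' the effective progress along the myofibroblast lineage;
#' contraction/ECM/myofibroblast/TGF-beta programs increase along it and the
#' pericyte program decreases.  Non-program genes are flat.  A per-cell
#' size factor `~ LogNormal(0, 0.3)` scales every mean so depth normalization
#' downstream is non-trivial, and counts are negative binomial with the
#' shared dispersion in the config.
#'
#' @param cells cell table carrying `pseudotime` and both lineage weights.
#' @param config a [synth_config()] object.
#' @return list with `counts` (a sparse `dgCMatrix`, genes x cells, with
#'   gene/cell dimnames), `gene_programs` (named list of [gene_set()]s), and
#'   `t_eff` (per-cell effective pseudotime).
#' @export
generate_counts <- function(cells, config) {
  if (!inherits(config, "synth_config"))
    stop_config("'config' must be a synth_config object", "config")
  need <- c("pseudotime", "weight_lineage_myo", "weight_lineage_peri")
  if (!all(need %in% names(cells)))
    stop_config("'cells' must carry pseudotime and lineage weights", "cells")
  set.seed(derive_seed(config$seed, "counts"))

  n_cells <- nrow(cells)
  gene_ids <- sprintf("G%04d", seq_len(config$n_genes))
  sizes <- config$program_sizes
  # carve disjoint program gene sets off the front of the universe
  bounds <- cumsum(c(0L, sizes))
  gene_programs <- lapply(seq_along(sizes), function(i)
    gene_set(names(sizes)[i], gene_ids[(bounds[i] + 1L):bounds[i + 1L]]))
  names(gene_programs) <- names(sizes)

  w_tot <- cells$weight_lineage_myo + cells$weight_lineage_peri
  t_eff <- cells$pseudotime * cells$weight_lineage_myo / w_tot

  mu0 <- runif(config$n_genes, config$baseline_log_mean_range[1],
               config$baseline_log_mean_range[2])
  dir_g <- numeric(config$n_genes)
  for (p in names(sizes)) {
    dir_g[match(gene_programs[[p]]$genes, gene_ids)] <- program_direction[[p]]
  }
  size_factor <- rlnorm(n_cells, 0, 0.3)

  # genes x cells mean matrix on the log scale, then NB draws
  log_mu <- outer(mu0, rep(1, n_cells)) +
    config$program_amplitude * outer(dir_g, t_eff)
  mu <- exp(log_mu) * rep(size_factor, each = config$n_genes)
  counts <- matrix(
    rnbinom(length(mu), size = config$nb_dispersion, mu = mu),
    nrow = config$n_genes,
    dimnames = list(gene_ids, cells$cell_id)
  )
  list(counts = as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
       gene_programs = gene_programs,
       t_eff = t_eff)
}

#' Simulate subject-level cell-state proportions with age confounding
#'
#' Companion generator for calibrating the binomial proportion model: for each
#' subject the number of transitioned cells is binomial with success
#' probability `plogis(intercept + beta_genotype * genotype + f(age) +
#' beta_sex * (sex == "M"))`, where `f` is a smooth nonlinear age effect.
#' Setting `confound_age_shift > 0` makes genotype-1 subjects older, so the
#' genotype effect is only recoverable with the age term in the model.
#'
#' @param subjects subject table from [generate_cohort()].
#' @param beta_genotype true genotype log-odds ratio.
#' @param intercept baseline log odds.
#' @param beta_sex log-odds shift for males.
#' @param age_fun function of age (years) giving the log-odds contribution;
#'   default is a centered quadratic, a mild nonlinear effect.
#' @param confound_age_shift years added to genotype-1 ages (creates
#'   confounding between genotype and age).
#' @param seed integer.
#' @return the subject table with `denominator` (its `n_cells`),
#'   `numerator`, and `ad_status` appended.
#' @export
simulate_proportion_cohort <- function(subjects, beta_genotype = 1.7,
                                       intercept = -2,
                                       beta_sex = 0.3,
                                       age_fun = function(a) 0.5 * ((a - 75) / 10)^2,
                                       confound_age_shift = 5,
                                       seed = 1L) {
  set.seed(derive_seed(seed, "proportions"))
  subjects$age <- subjects$age + confound_age_shift * subjects$genotype
  subjects$ad_status <- rbinom(nrow(subjects), 1L, 0.4)
  eta <- intercept + beta_genotype * subjects$genotype +
    age_fun(subjects$age) + beta_sex * (subjects$sex == "M")
  subjects$denominator <- subjects$n_cells
  subjects$numerator <- rbinom(nrow(subjects), subjects$denominator, plogis(eta))
  subjects
}

#' Named gene set
#'
#' @param name program name.
#' @param genes character vector of gene identifiers.
#' @return object of class `gene_set`.
#' @export
gene_set <- function(name, genes) {
  if (!length(genes)) stop_config("gene set must be non-empty", name)
  if (anyDuplicated(genes)) stop_config("gene set has duplicate genes", name)
  structure(list(name = name, genes = as.character(genes)), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene set '", x$name, "': ", length(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' Write a synthetic dataset to disk in standard exchange formats
#'
#' Counts go out as matrix-market coordinate integers with `genes.tsv` and
#' `barcodes.tsv` sidecars, tables as TSV with header, and the config as
#' YAML, so any downstream toolchain can consume the dataset.
#'
#' @param dataset list with `counts`, `cells`, `subjects`, and optionally
#'   `gene_programs` and `config`.
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
write_synth_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  p <- file.path(dir, "matrix.mtx")
  Matrix::writeMM(dataset$counts, p)
  paths <- c(paths, p)
  p <- file.path(dir, "genes.tsv")
  write.table(data.frame(gene_id = rownames(dataset$counts)), p,
              sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "barcodes.tsv")
  write.table(data.frame(cell_id = colnames(dataset$counts)), p,
              sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  for (nm in c("cells", "subjects")) {
    if (is.null(dataset[[nm]])) next
    p <- file.path(dir, paste0(nm, ".tsv"))
    write.table(dataset[[nm]], p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(dataset$gene_programs)) {
    for (gs in dataset$gene_programs) {
      p <- file.path(dir, paste0("geneset_", gs$name, ".txt"))
      writeLines(gs$genes, p)
      paths <- c(paths, p)
    }
  }
  if (!is.null(dataset$config)) {
    p <- file.path(dir, "config.yaml")
    yaml::write_yaml(unclass(dataset$config), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a count matrix written by [write_synth_dataset()]
#'
#' @param dir directory holding `matrix.mtx`, `genes.tsv`, `barcodes.tsv`.
#' @return sparse `dgCMatrix` with gene/cell dimnames.
#' @export
read_counts_mtx <- function(dir) {
  m <- as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  genes <- read.table(file.path(dir, "genes.tsv"), header = TRUE, sep = "\t")
  cells <- read.table(file.path(dir, "barcodes.tsv"), header = TRUE, sep = "\t")
  dimnames(m) <- list(genes[[1]], cells[[1]])
  m
}

#' Generate a complete synthetic dataset in one call
#'
#' Convenience wrapper chaining [generate_cohort()],
#' [generate_lineage_weights()] and [generate_counts()].
#'
#' @param config a [synth_config()] object.
#' @return list with `subjects`, `cells`, `counts`, `gene_programs`,
#'   `t_eff`, and the `config`.
#' @export
generate_dataset <- function(config) {
  cohort <- generate_cohort(config)
  cells <- generate_lineage_weights(cohort$cells, config)
  cm <- generate_counts(cells, config)
  list(subjects = cohort$subjects, cells = cells, counts = cm$counts,
       gene_programs = cm$gene_programs, t_eff = cm$t_eff, config = config)
}
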