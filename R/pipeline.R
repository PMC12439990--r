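pipeline_stage_order <- c("synth", "score", "gate", "trajtest", "glm",
                          "match", "spatial")

#' Demo pipeline configuration
#'
#' A small end-to-end configuration (every stage enabled, modest sizes) used
#' by the bundled demo and the determinism checks.
#'
#' @param out_dir output directory.
#' @param seed global seed; per-stage seeds are derived from it.
#' @return a config list for [run_pipeline()].
#' @export
pipeline_demo_config <- function(out_dir = tempfile("pmt_demo_"), seed = 7L) {
  list(
    out_dir = out_dir,
    seed = as.integer(seed),
    stages = pipeline_stage_order,
    synth = list(n_subjects_per_genotype = 8, cells_per_subject_range = c(15, 30),
                 n_genes = 200,
                 program_sizes = list(pericyte = 15, contraction = 15,
                                      ecm = 15, myofibroblast = 15,
                                      tgfb = 10),
                 effect_beta_genotype = 1.5, program_amplitude = 1.5,
                 nb_dispersion = 2),
    trajtest = list(n_perm = 100, score = "coexpression"),
    gate = list(cutoff = 1.5),
    glm = list(age_df = 3),
    match = list(covariates = c("age", "sex", "total_cell_count")),
    spatial = list(n_cells = 24)
  )
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes the enabled stages in dependency order: `synth` (generate the
#' cohort, counts, pseudotime, lineage weights), `score` (normalize and
#' compute contraction/ECM/co-expression program scores), `gate` (mark
#' double-positive intermediate cells and count them per subject),
#' `trajtest` (delta-AUC permutation test of the chosen score between
#' lineages), `glm` (binomial logit model of the gated proportions),
#' `match` (propensity matching with balance report), and `spatial`
#' (synthetic tissue image, state classification, vessel distances).  Every
#' stage seeds its own random stream via [derive_seed()] from the global
#' seed, all tabular outputs are TSV and all statistical results also JSON,
#' and the manifest records parameters, seeds and MD5 hashes of every output
#' so identical configs yield identical runs.
#'
#' @param config config list (see [pipeline_demo_config()]) or path to a
#'   YAML file with the same structure.
#' @return invisibly, the run manifest (also written as `manifest.json`).
#'   On stage failure the manifest marks the stage failed, downstream stages
#'   are skipped, and an error is raised after the manifest is written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_config("config file not found", "config")
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$out_dir)) stop_config("config lacks out_dir", "out_dir")
  if (is.null(config$seed)) stop_config("config lacks seed", "seed")
  stages <- config$stages %||% pipeline_stage_order
  unknown <- setdiff(stages, pipeline_stage_order)
  if (length(unknown))
    stop_config(sprintf("unknown stage(s): %s", paste(unknown, collapse = ", ")),
                "stages")
  stages <- pipeline_stage_order[pipeline_stage_order %in% stages]
  # validate referenced inputs before anything runs
  if (!("synth" %in% stages)) {
    if (is.null(config$input_dir) || !dir.exists(config$input_dir))
      stop_config("without the synth stage, config$input_dir must point at an existing dataset",
                  "input_dir")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(config = config, stages = list())
  state <- new.env(parent = emptyenv())
  record <- function(stage, status, seed = NULL, outputs = character(0),
                     info = NULL) {
    manifest$stages[[stage]] <<- list(
      status = status, seed = seed,
      outputs = as.list(tools::md5sum(outputs)),
      info = info
    )
  }

  runners <- list(
    synth = function(seed) {
      cfg_args <- config$synth %||% list()
      cfg_args$seed <- seed
      sc <- do.call(synth_config, cfg_args)
      ds <- generate_dataset(sc)
      ds$config <- sc
      dir <- file.path(config$out_dir, "synth")
      files <- write_synth_dataset(ds, dir)
      state$dataset <- ds
      files
    },
    score = function(seed) {
      ds <- state$dataset
      norm <- normalize_cp10k(ds$counts)
      s_con <- module_score(norm, ds$gene_programs$contraction, seed = seed)
      s_ecm <- module_score(norm, ds$gene_programs$ecm, seed = seed)
      s_co <- coexpression_score(s_con, s_ecm)
      state$norm <- norm
      state$scores <- list(contraction = s_con, ecm = s_ecm,
                           coexpression = s_co)
      tab <- data.frame(cell_id = names(s_co$score),
                        contraction = as.numeric(s_con$score),
                        ecm = as.numeric(s_ecm$score),
                        coexpression = as.numeric(s_co$score))
      write_tsv(tab, file.path(config$out_dir, "scores.tsv"))
    },
    gate = function(seed) {
      ds <- state$dataset
      # markers: a contraction-program gene and a pericyte-program gene
      # stand in for ACTA2 / CSPG4 in the synthetic gene universe
      ga <- config$gate$gene_a %||% ds$gene_programs$contraction$genes[1]
      gb <- config$gate$gene_b %||% ds$gene_programs$pericyte$genes[1]
      g <- gate_intermediate(state$norm, ds$cells, gene_a = ga, gene_b = gb,
                             cutoff = config$gate$cutoff %||% 1.5)
      state$gate <- g
      write_tsv(g$subject_counts,
                file.path(config$out_dir, "gate_subject_counts.tsv"))
    },
    trajtest = function(seed) {
      ds <- state$dataset
      score_name <- config$trajtest$score %||% "coexpression"
      res <- delta_auc_test(ds$cells, state$scores[[score_name]]$score,
                            n_perm = config$trajtest$n_perm %||% 1000,
                            seed = seed)
      bias <- lineage_bias_test(ds$cells, n_perm = config$trajtest$n_perm_bias %||% 500,
                                seed = seed)
      write_json(list(
        score = score_name,
        auc_myo = res$auc_myo, auc_peri = res$auc_peri,
        delta_auc = res$delta_auc,
        p_two_sided = res$p_two_sided, p_smoothed = res$p_smoothed,
        n_perm = res$n_perm, perm_deltas = res$perm_deltas,
        lineage_bias = list(statistic = bias$statistic,
                            p_two_sided = bias$p_two_sided,
                            n_perm = bias$n_perm)
      ), file.path(config$out_dir, "trajtest.json"))
    },
    glm = function(seed) {
      ds <- state$dataset
      subjects <- merge(ds$subjects, state$gate$subject_counts,
                        by = "subject_id")
      subjects <- subjects[order(subjects$subject_id), ]
      fit <- fit_proportion_glm(subjects,
                                age_df = config$glm$age_df %||% 3)
      preds <- predict_proportions(fit, subjects)
      check <- residual_check(fit, subjects, seed = seed)
      f1 <- write_json(list(
        coefficients = as.list(fit$coefficients),
        odds_ratios = fit$odds_ratios,
        converged = fit$converged,
        residual_ks_p = check$p_value
      ), file.path(config$out_dir, "glm.json"))
      f2 <- write_tsv(data.frame(subject_id = subjects$subject_id,
                                 observed = subjects$numerator / subjects$denominator,
                                 predicted = preds),
                      file.path(config$out_dir, "glm_predictions.tsv"))
      c(f1, f2)
    },
    match = function(seed) {
      ds <- state$dataset
      subjects <- ds$subjects
      subjects$total_cell_count <- subjects$n_cells
      # make 1:1 matching feasible per dataset: drop datasets lacking a
      # genotype group, and deterministically trim excess treated subjects
      # (highest subject_id first) where treated outnumber controls
      keep <- unlist(lapply(split(seq_len(nrow(subjects)), subjects$dataset),
        function(idx) {
          g <- subjects$genotype[idx]
          if (!any(g == 1) || !any(g == 0)) return(integer(0))
          excess <- sum(g == 1) - sum(g == 0)
          if (excess > 0) {
            treated <- idx[g == 1]
            drop <- treated[order(subjects$subject_id[treated],
                                  decreasing = TRUE)][seq_len(excess)]
            idx <- setdiff(idx, drop)
          }
          idx
        }))
      subjects <- subjects[sort(keep), , drop = FALSE]
      if (!nrow(subjects)) stop("no dataset allows 1:1 matching")
      m <- propensity_match(subjects,
                            covariates = config$match$covariates %||%
                              c("age", "sex", "total_cell_count"))
      f1 <- write_tsv(m$balance, file.path(config$out_dir, "match_balance.tsv"))
      f2 <- write_tsv(m$pairs, file.path(config$out_dir, "match_pairs.tsv"))
      c(f1, f2)
    },
    spatial = function(seed) {
      sp <- generate_tissue_image(n_cells = config$spatial$n_cells %||% 24,
                                  seed = seed)
      cls <- classify_cell_states(sp$image,
                                  thresholds = config$spatial$thresholds %||%
                                    list(ng2 = 0.5, asma = 0.5))
      acc <- mean(cls$calls$state[sp$truth$cell_label] == sp$truth$state)
      f1 <- write_tsv(cls$calls, file.path(config$out_dir, "spatial_calls.tsv"))
      f2 <- write_json(list(proportions = as.list(cls$proportions),
                            accuracy_vs_truth = acc),
                       file.path(config$out_dir, "spatial.json"))
      c(f1, f2)
    }
  )

  failed <- NULL
  for (stage in pipeline_stage_order) {
    if (!(stage %in% stages)) next
    if (!is.null(failed)) {
      record(stage, "skipped")
      next
    }
    seed <- derive_seed(config$seed, stage)
    res <- tryCatch(runners[[stage]](seed), error = function(e) e)
    if (inherits(res, "error")) {
      record(stage, "failed", seed, info = conditionMessage(res))
      failed <- stage
    } else {
      record(stage, "ok", seed, outputs = res)
    }
  }
  write_json(manifest, file.path(config$out_dir, "manifest.json"))
  if (!is.null(failed))
    stop(sprintf("pipeline stage '%s' failed: %s", failed,
                 manifest$stages[[failed]]$info))
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
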