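#' Assemble and validate an experiment configuration
#'
#' Bundles the parameters of every stage of the evaluation workflow:
#' synthetic cohort (manifest, phenotypes, technical artifacts), pipeline
#' grid axes, predictor configs, reliability and association options, plus a
#' global seed. Defaults give a desk-scale experiment (2,000 probes, 50
#' replicate pairs, 500 general samples, 5 synthetic predictors) whose
#' structure mirrors a full cohort study.
#'
#' @param n_probes,type2_fraction,n_neighbor_pairs,n_control_pairs,n_negative_controls
#'   manifest parameters (see [generate_manifest()]).
#' @param n_general number of non-replicate subjects.
#' @param n_replicate_pairs number of technical replicate pairs.
#' @param pheno a [pheno_config()].
#' @param tech a [tech_config()].
#' @param grid named list of grid axes (`bg`, `dye`, `norm`, `probe`).
#' @param predictors list of predictor configs for [make_weight_tables()].
#' @param conf_level confidence level for ICC intervals.
#' @param standardize_cox report Cox hazard ratios per predictor SD.
#' @param seed global seed; all stage sub-streams derive from it.
#' @param out_dir optional output directory; when set, [run_experiment()]
#'   serializes all tables there.
#' @return a validated list of class `experiment_config`.
#' @export
experiment_config <- function(n_probes = 2000,
                              type2_fraction = 0.84,
                              n_neighbor_pairs = 150,
                              n_control_pairs = 85,
                              n_negative_controls = 100,
                              n_general = 500,
                              n_replicate_pairs = 50,
                              pheno = pheno_config(),
                              tech = tech_config(),
                              grid = list(bg = c("none", "oob"),
                                          dye = c("none", "relic"),
                                          norm = c("none", "q1"),
                                          probe = c("none", "rcp")),
                              predictors = list(
                                list(name = "SynthClock", n_probes = 353,
                                     target = "age", transform = "horvath_age"),
                                list(name = "SynthClockLinear", n_probes = 100,
                                     target = "age"),
                                list(name = "SynthScore", n_probes = 150,
                                     target = "latent_score"),
                                list(name = "SynthScoreSmall", n_probes = 30,
                                     target = "latent_score"),
                                list(name = "NoiseScore", n_probes = 100,
                                     target = "random")),
                              conf_level = 0.95,
                              standardize_cox = FALSE,
                              seed = 1L,
                              out_dir = NULL) {
  if (!inherits(pheno, "pheno_config")) pheno <- do.call(pheno_config, pheno)
  if (!inherits(tech, "tech_config")) tech <- do.call(tech_config, tech)
  stopifnot(n_general >= 1, n_replicate_pairs >= 3,
            all(names(grid) %in% c("bg", "dye", "norm", "probe")))
  for (cf in predictors)
    stopifnot(!is.null(cf$name), !is.null(cf$n_probes), !is.null(cf$target))
  structure(list(n_probes = n_probes, type2_fraction = type2_fraction,
                 n_neighbor_pairs = n_neighbor_pairs,
                 n_control_pairs = n_control_pairs,
                 n_negative_controls = n_negative_controls,
                 n_general = n_general,
                 n_replicate_pairs = n_replicate_pairs,
                 pheno = pheno, tech = tech, grid = grid,
                 predictors = predictors, conf_level = conf_level,
                 standardize_cox = standardize_cox,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "experiment_config")
}

#' Run the full replicate-based evaluation experiment
#'
#' Orchestrates: simulate cohort -> sample QC -> preprocess through every
#' grid pipeline -> predictor estimates -> ICC reliability on the replicate
#' subset -> distribution/age/Cox associations on the disjoint general
#' subset -> pipeline ranking and ICC-vs-statistic correlations. The
#' replicate and general subsets are disjoint by subject (asserted).
#' Deterministic for a fixed config seed.
#'
#' @param config an [experiment_config()].
#' @param verbose print stage progress.
#' @return an `experiment_bundle`: list with `manifest`, `truth`, `qc`,
#'   `models`, `grid_labels`, `estimates` (per pipeline), `icc_table` (long,
#'   all six ICC types per predictor x pipeline), `icc_matrix`
#'   (predictors x pipelines, ICC(2,1)), `ranking`, `association_table`,
#'   `icc_stat_correlations`, `batch`, and `config`.
#' @export
run_experiment <- function(config = experiment_config(), verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (verbose) message(...)
  seed <- config$seed

  say("simulating cohort")
  manifest <- generate_manifest(config$n_probes, config$type2_fraction,
                                config$n_neighbor_pairs,
                                config$n_control_pairs,
                                config$n_negative_controls, seed = seed)
  n_subjects <- config$n_general + config$n_replicate_pairs
  truth <- simulate_truth(manifest, n_subjects,
                          config$n_replicate_pairs, config$pheno,
                          seed = seed)
  ds <- simulate_intensities(truth, manifest, config$tech, seed = seed)

  say("sample QC")
  pvals <- detection_pvalues(ds, manifest)
  qc <- sample_qc(ds, pvals, manifest = manifest)
  ds <- apply_qc(ds, qc)

  models <- make_weight_tables(manifest, truth, config$predictors,
                               seed = seed)

  specs <- do.call(enumerate_grid, config$grid)
  say("running ", length(specs), " pipelines")
  estimates <- lapply(specs, function(sp) {
    beta <- run_pipeline(ds, sp, manifest)
    suppressMessages(apply_predictor(beta, models))
  })

  sheet <- ds$sample_sheet
  rep_sheet <- sheet[!is.na(sheet$replicate_pair_id), , drop = FALSE]
  gen_sheet <- sheet[is.na(sheet$replicate_pair_id), , drop = FALSE]
  stopifnot(!any(gen_sheet$subject_id %in% rep_sheet$subject_id))

  pred_names <- names(models)
  labels <- names(specs)

  say("reliability on ", nrow(rep_sheet) / 2, " replicate pairs")
  icc_rows <- list()
  icc_matrix <- matrix(NA_real_, length(pred_names), length(labels),
                       dimnames = list(pred_names, labels))
  replicate_tables <- list()
  for (lab in labels) {
    for (pn in pred_names) {
      tb <- suppressMessages(
        replicate_table(estimates[[lab]], rep_sheet, pn))
      replicate_tables[[paste(pn, lab, sep = "|")]] <- tb
      res <- tryCatch(icc(tb, conf_level = config$conf_level),
                      error = function(e) NULL)
      if (is.null(res)) next
      icc_matrix[pn, lab] <- res$icc[["ICC(2,1)"]]
      icc_rows[[paste(pn, lab)]] <- data.frame(
        predictor = pn, pipeline = lab, t(res$icc),
        f = unname(res$fvalue["twoway"]),
        p = unname(res$p_value["twoway"]),
        ci_lower = res$ci["ICC(2,1)", "lower"],
        ci_upper = res$ci["ICC(2,1)", "upper"],
        n_pairs = res$n, check.names = FALSE, stringsAsFactors = FALSE)
    }
  }
  icc_table <- do.call(rbind, icc_rows)
  rownames(icc_table) <- NULL
  ranking <- rank_pipelines(icc_matrix)

  say("associations on ", nrow(gen_sheet), " general samples")
  assoc_rows <- list()
  for (lab in labels) {
    est <- estimates[[lab]]
    gen <- est[match(gen_sheet$array_id, est$array_id), , drop = FALSE]
    summ <- summarize_distribution(gen)
    for (pn in pred_names) {
      v <- gen[[pn]]
      age_r <- cor(v, gen_sheet$age)
      cx <- tryCatch(
        cox_mortality(v, gen_sheet$survival_time, gen_sheet$event,
                      covariates = data.frame(age = gen_sheet$age),
                      standardize = config$standardize_cox),
        error = function(e) NULL)
      assoc_rows[[paste(pn, lab)]] <- data.frame(
        predictor = pn, pipeline = lab,
        mean = summ$mean[summ$predictor == pn],
        sd = summ$sd[summ$predictor == pn],
        cv = summ$cv[summ$predictor == pn],
        age_r = age_r,
        hr = if (is.null(cx)) NA_real_ else cx$hr,
        hr_se = if (is.null(cx)) NA_real_ else cx$hr_se,
        z = if (is.null(cx)) NA_real_ else cx$z,
        cox_p = if (is.null(cx)) NA_real_ else cx$cox_p,
        stringsAsFactors = FALSE)
    }
  }
  association_table <- do.call(rbind, assoc_rows)
  rownames(association_table) <- NULL

  ## ICC vs downstream statistic, per predictor across pipelines
  stat_cols <- c("mean", "sd", "age_r", "hr", "z")
  icc_stat <- list()
  for (pn in pred_names) {
    at <- association_table[association_table$predictor == pn, ]
    at <- at[match(labels, at$pipeline), ]
    for (sc in stat_cols) {
      r <- tryCatch(
        icc_statistic_correlation(icc_matrix[pn, labels], at[[sc]],
                                  statistic = sc),
        error = function(e) list(statistic = sc, rho = NA_real_,
                                 p = NA_real_, n = NA, undefined = TRUE))
      icc_stat[[paste(pn, sc)]] <- data.frame(
        predictor = pn, statistic = sc, rho = r$rho, p = r$p,
        undefined = isTRUE(r$undefined), stringsAsFactors = FALSE)
    }
  }
  icc_stat_correlations <- do.call(rbind, icc_stat)
  rownames(icc_stat_correlations) <- NULL

  ## batch variance over all arrays, per predictor, raw pipeline
  raw_lab <- "bg=none,dye=none,norm=none,probe=none"
  batch <- NULL
  if (raw_lab %in% labels) {
    batch <- lapply(setNames(pred_names, pred_names), function(pn)
      tryCatch(batch_variance_explained(estimates[[raw_lab]], sheet,
                                        predictor = pn),
               error = function(e) NULL))
  }

  bundle <- structure(list(
    manifest = manifest, truth = truth, qc = qc, models = models,
    grid_labels = labels, estimates = estimates,
    replicate_tables = replicate_tables,
    icc_table = icc_table, icc_matrix = icc_matrix, ranking = ranking,
    association_table = association_table,
    icc_stat_correlations = icc_stat_correlations,
    batch = batch, config = config
  ), class = "experiment_bundle")
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

#' Pairwise rank concordance of the six ICC types
#'
#' Across all predictor-by-pipeline cells of a bundle (or a cells x 6
#' matrix), computes the 6 x 6 symmetric matrix of Spearman correlations
#' between ICC types. High off-diagonal values mean the choice of ICC form
#' barely affects pipeline comparisons.
#'
#' @param x an `experiment_bundle` or numeric matrix cells x 6 (columns =
#'   ICC types).
#' @return list with `rho` (6 x 6 matrix, unit diagonal) and
#'   `mean_off_diagonal`.
#' @export
compare_icc_types <- function(x) {
  types <- c("ICC(1,1)", "ICC(2,1)", "ICC(3,1)",
             "ICC(1,k)", "ICC(2,k)", "ICC(3,k)")
  m <- if (inherits(x, "experiment_bundle"))
    as.matrix(x$icc_table[, types]) else as.matrix(x)
  if (ncol(m) != 6) stop("expected 6 ICC-type columns")
  colnames(m) <- types
  keep <- complete.cases(m)
  m <- m[keep, , drop = FALSE]
  if (nrow(m) < 10) stop("need >= 10 complete cells")
  rho <- diag(6)
  for (i in 1:5) for (j in (i + 1):6) {
    rho[i, j] <- rho[j, i] <- spearman_cor(m[, i], m[, j])$rho
  }
  dimnames(rho) <- list(types, types)
  list(rho = rho,
       mean_off_diagonal = mean(rho[upper.tri(rho)]),
       n_cells = nrow(m))
}

#' Serialize an experiment bundle to a directory
#'
#' Writes all result tables as TSV, the sample sheet and QC report as CSV,
#' predictor models as CSV, the configuration as YAML, and a `MANIFEST`
#' file of md5 checksums for audit/restartability.
#'
#' @param bundle an `experiment_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir` invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(bundle$icc_table, "icc_table.tsv")
  wt(bundle$association_table, "association_table.tsv")
  wt(bundle$icc_stat_correlations, "icc_stat_correlations.tsv")
  wt(bundle$ranking$best, "ranking_best.tsv")
  wt(data.frame(pipeline = names(bundle$ranking$median_rank),
                median_rank = bundle$ranking$median_rank), "ranking_median.tsv")
  write_manifest_tsv(bundle$manifest, file.path(dir, "manifest.tsv"))
  write_sample_sheet(bundle$truth$sample_sheet,
                     file.path(dir, "sample_sheet.csv"))
  utils::write.csv(bundle$qc, file.path(dir, "qc_report.csv"),
                   row.names = FALSE)
  mdir <- file.path(dir, "models")
  dir.create(mdir, showWarnings = FALSE)
  for (m in bundle$models)
    write_predictor_model(m, file.path(mdir, paste0(m$name, ".csv")))
  cfg <- bundle$config
  cfg_list <- lapply(unclass(cfg), function(x)
    if (inherits(x, c("pheno_config", "tech_config"))) unclass(x) else x)
  yaml::write_yaml(cfg_list, file.path(dir, "config.yaml"))
  files <- setdiff(list.files(dir, recursive = TRUE), "MANIFEST")
  sums <- tools::md5sum(file.path(dir, files))
  writeLines(paste(unname(sums), files), file.path(dir, "MANIFEST"))
  invisible(dir)
}
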