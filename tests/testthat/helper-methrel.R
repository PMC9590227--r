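# Shared fixtures and independent oracles for the test suite.

# Small cohort: manifest + truth + intensities with configurable artifacts.
make_cohort <- function(seed = 1, n_probes = 400, n_neighbor_pairs = 40,
                        n_subjects = 30, n_replicate_pairs = 10,
                        tech = tech_config(), pheno = pheno_config()) {
  man <- generate_manifest(n_probes, n_neighbor_pairs = n_neighbor_pairs,
                           n_control_pairs = 85, n_negative_controls = 100,
                           seed = seed)
  tr <- simulate_truth(man, n_subjects, n_replicate_pairs, pheno, seed = seed)
  ds <- simulate_intensities(tr, man, tech, seed = seed)
  list(man = man, tr = tr, ds = ds)
}

# A tech config with every artifact off and no noise at all.
tech_silent <- function(...) {
  base <- list(bg_mean = c(red = 0, green = 0), bg_sd = 0, bg_array_sd = 0,
               dye_bias_sd = 0, type2_compression = 1,
               type2_compression_sd = 0,
               batch_sds = c(chip = 0, position = 0, plate = 0, well = 0),
               occasion_shift_sd = 0, signal_sdlog = 0, signal_noise_sd = 0)
  do.call(tech_config, utils::modifyList(base, list(...)))
}

# Baseline probe-level noise, no array-level artifact classes.
tech_baseline <- function(...) {
  base <- list(dye_bias_sd = 0, bg_array_sd = 0, type2_compression_sd = 0,
               batch_sds = c(chip = 0, position = 0, plate = 0, well = 0),
               occasion_shift_sd = 0)
  do.call(tech_config, utils::modifyList(base, list(...)))
}

# Independent ICC oracle: mean squares via stats::aov on the long layout,
# the six coefficients assembled directly from the Shrout-Fleiss formulas.
icc_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  long <- data.frame(y = as.vector(m),
                     subject = factor(rep(seq_len(n), k)),
                     occasion = factor(rep(seq_len(k), each = n)))
  ms2 <- summary(stats::aov(y ~ subject + occasion, data = long))[[1]]
  MSR <- ms2["subject", "Mean Sq"]
  MSC <- ms2["occasion", "Mean Sq"]
  MSE <- ms2["Residuals", "Mean Sq"]
  ms1 <- summary(stats::aov(y ~ subject, data = long))[[1]]
  MSW <- ms1["Residuals", "Mean Sq"]
  c("ICC(1,1)" = (MSR - MSW) / (MSR + (k - 1) * MSW),
    "ICC(2,1)" = (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n),
    "ICC(3,1)" = (MSR - MSE) / (MSR + (k - 1) * MSE),
    "ICC(1,k)" = (MSR - MSW) / MSR,
    "ICC(2,k)" = (MSR - MSE) / (MSR + (MSC - MSE) / n),
    "ICC(3,k)" = (MSR - MSE) / MSR)
}

# Two-way random-effects replicate data with fixed occasion offsets whose
# realized variance is var_c.
make_two_way <- function(n, var_u, var_c, var_e) {
  u <- rnorm(n, 0, sqrt(var_u))
  cc <- c(-1, 1) * sqrt(var_c / 2)
  outer(u, c(1, 1)) + outer(rep(1, n), cc) +
    matrix(rnorm(2 * n, 0, sqrt(var_e)), n, 2)
}

# ICC(2,1) of a clock predictor on a cohort under one pipeline.
pipeline_icc <- function(cohort, spec, model) {
  beta <- run_pipeline(cohort$ds, spec, cohort$man)
  est <- suppressMessages(apply_predictor(beta, model))
  sheet <- cohort$ds$sample_sheet
  tb <- suppressMessages(
    replicate_table(est, sheet[!is.na(sheet$replicate_pair_id), ],
                    model$name))
  icc(tb)$icc[["ICC(2,1)"]]
}

# One clock model trained on a cohort's truth.
make_clock <- function(cohort, n_probes = 120, seed = 1) {
  make_weight_tables(cohort$man, cohort$tr,
                     list(list(name = "clk", n_probes = n_probes,
                               target = "age")),
                     seed = seed)$clk
}
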