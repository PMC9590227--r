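#' Phenotype / ground-truth configuration
#'
#' Default parameters describe a middle-aged population cohort: age about
#' N(56.1, 12.4^2) years, roughly 15% mortality over a 10-year follow-up, and
#' a subset of CpGs whose methylation drifts log-linearly with age.
#'
#' @param age_mean,age_sd mean and SD of chronological age in years.
#' @param aging_cpg_fraction fraction of CpG probes designated as aging CpGs.
#' @param aging_slope_per_year mean absolute drift of an aging CpG on the
#'   logit-beta scale per year of age.
#' @param subject_sd SD of stable subject-level deviations on the logit scale.
#' @param mortality_log_hr log hazard ratio of death per SD of the latent
#'   aging score.
#' @param baseline_hazard exponential baseline hazard per year (default
#'   0.0163, giving ~15% events at 10 years of follow-up).
#' @param censoring_time administrative censoring time in years.
#' @return a named list of class `pheno_config`.
#' @export
pheno_config <- function(age_mean = 56.1,
                         age_sd = 12.4,
                         aging_cpg_fraction = 0.10,
                         aging_slope_per_year = 0.02,
                         subject_sd = 0.5,
                         mortality_log_hr = 0.5,
                         baseline_hazard = 0.0163,
                         censoring_time = 10) {
  if (age_sd <= 0) stop("age_sd must be positive")
  if (baseline_hazard <= 0) stop("baseline_hazard must be positive")
  if (aging_cpg_fraction < 0 || aging_cpg_fraction > 1)
    stop("aging_cpg_fraction must lie in [0,1]")
  structure(list(age_mean = age_mean, age_sd = age_sd,
                 aging_cpg_fraction = aging_cpg_fraction,
                 aging_slope_per_year = aging_slope_per_year,
                 subject_sd = subject_sd,
                 mortality_log_hr = mortality_log_hr,
                 baseline_hazard = baseline_hazard,
                 censoring_time = censoring_time),
            class = "pheno_config")
}

#' Simulate ground-truth methylation, phenotypes, and array layout
#'
#' Per-probe population mean methylation is drawn from a three-class mixture
#' (hypo- / hemi- / hyper-methylated) on the logit scale; subjects deviate
#' from the probe mean by a stable logit-scale effect; a designated subset of
#' aging CpGs drifts linearly with age on the logit scale. The latent aging
#' score is the weighted sum of true betas over aging CpGs (the quantity an
#' ideal epigenetic clock would recover). Survival times follow an
#' exponential hazard `baseline_hazard * exp(log_hr * standardized score)`
#' censored administratively.
#'
#' The two arrays of a technical replicate pair share the same row of
#' `true_beta`; only technical draws differ downstream. Arrays are laid out
#' on chips of 8 (positions R01-R08) and plates of 96 (wells A01-H12);
#' second-occasion replicate arrays are appended after all first-occasion
#' arrays, so a pair lands on different chips by default
#' (`replicate_layout = "different_chip"`); `"adjacent"` instead co-locates
#' the pair on neighboring slots.
#'
#' @param manifest an `array_manifest`.
#' @param n_subjects number of subjects (>= n_replicate_pairs).
#' @param n_replicate_pairs number of subjects assayed twice.
#' @param pheno a `pheno_config`.
#' @param replicate_layout `"different_chip"` (default) or `"adjacent"`.
#' @param seed integer seed.
#' @return An object of class `ground_truth`: list with `true_beta`
#'   (subjects x CpG probes), `age`, `latent_aging_score`, `survival_time`,
#'   `event`, `aging_probes`, `aging_weights`, `variance_components`, and
#'   `sample_sheet` (one row per array: array_id, subject_id,
#'   replicate_pair_id, occasion, chip, position, plate, well, age,
#'   survival_time, event).
#' @export
simulate_truth <- function(manifest, n_subjects, n_replicate_pairs = 0,
                           pheno = pheno_config(),
                           replicate_layout = c("different_chip", "adjacent"),
                           seed = 1L) {
  stopifnot(inherits(manifest, "array_manifest"))
  replicate_layout <- match.arg(replicate_layout)
  if (n_replicate_pairs > n_subjects)
    stop("n_replicate_pairs must not exceed n_subjects")
  if (!inherits(pheno, "pheno_config")) pheno <- do.call(pheno_config, pheno)

  probes <- cpg_ids(manifest)
  n_probes <- length(probes)

  with_seed(stage_seed(seed, "truth"), {
    ## population probe means: logit-scale mixture hypo/hemi/hyper
    cls <- sample(1:3, n_probes, replace = TRUE, prob = c(0.40, 0.20, 0.40))
    mu <- rnorm(n_probes,
                mean = c(-2.5, 0, 2.5)[cls],
                sd = c(0.6, 0.4, 0.6)[cls])

    age <- rnorm(n_subjects, pheno$age_mean, pheno$age_sd)

    n_aging <- round(pheno$aging_cpg_fraction * n_probes)
    aging_idx <- sort(sample.int(n_probes, n_aging))
    ## per-CpG drift: a direction and a magnitude around aging_slope_per_year
    slope <- numeric(n_probes)
    direction <- integer(0)
    if (n_aging > 0) {
      direction <- sample(c(-1L, 1L), n_aging, replace = TRUE)
      slope[aging_idx] <- direction *
        pheno$aging_slope_per_year * (0.5 + rexp(n_aging))
    }

    dev <- matrix(rnorm(n_subjects * n_probes, sd = pheno$subject_sd),
                  n_subjects, n_probes)
    lb <- sweep(dev, 2, mu, "+") +
      outer(age - pheno$age_mean, slope)
    ## neighbor pairs share the same true methylation: copy the type-I
    ## member's profile onto its type-II partner
    cpg_rows <- cpg_index(manifest)
    npid <- manifest$neighbor_pair_id[cpg_rows]
    if (any(!is.na(npid))) {
      dt <- manifest$design_type[cpg_rows]
      ids <- unique(npid[!is.na(npid)])
      i1 <- match(ids, ifelse(dt == "I", npid, NA))
      i2 <- match(ids, ifelse(dt == "II", npid, NA))
      lb[, i2] <- lb[, i1]
      slope[i2] <- slope[i1]
    }
    true_beta <- inv_logit(lb)
    dimnames(true_beta) <- list(sprintf("S%05d", seq_len(n_subjects)), probes)

    ## latent aging score: weighted sum of true betas over aging CpGs,
    ## weights aligned with each CpG's drift direction (non-degenerate even
    ## at zero slope, so the null model stays testable)
    w <- numeric(n_aging)
    score <- numeric(n_subjects)
    if (n_aging > 0) {
      w <- direction * (1 + abs(rnorm(n_aging, sd = 0.3)))
      score <- drop(true_beta[, aging_idx, drop = FALSE] %*% w)
    }

    z <- if (stats::sd(score) > 0) (score - mean(score)) / stats::sd(score)
         else rep(0, n_subjects)
    hazard <- pheno$baseline_hazard * exp(pheno$mortality_log_hr * z)
    t_death <- rexp(n_subjects, rate = hazard)
    event <- as.integer(t_death <= pheno$censoring_time)
    survival_time <- pmin(t_death, pheno$censoring_time)

    ## array layout
    subj <- rownames(true_beta)
    pair_subj <- subj[seq_len(n_replicate_pairs)]
    if (replicate_layout == "different_chip") {
      arr_subj <- c(subj, pair_subj)
      occasion <- c(rep(1L, n_subjects), rep(2L, n_replicate_pairs))
    } else {
      ord <- c(rbind(seq_len(n_replicate_pairs), seq_len(n_replicate_pairs)))
      arr_subj <- c(pair_subj[ord],
                    subj[setdiff(seq_len(n_subjects), seq_len(n_replicate_pairs))])
      occasion <- c(rep(c(1L, 2L), n_replicate_pairs),
                    rep(1L, n_subjects - n_replicate_pairs))
    }
    n_arrays <- length(arr_subj)
    idx <- seq_len(n_arrays)
    wells <- sprintf("%s%02d", rep(LETTERS[1:8], each = 12), 1:12)
    sample_sheet <- data.frame(
      array_id = sprintf("A%05d", idx),
      subject_id = arr_subj,
      replicate_pair_id = ifelse(arr_subj %in% pair_subj,
                                 paste0("rp_", arr_subj), NA_character_),
      occasion = occasion,
      chip = sprintf("chip%03d", (idx - 1) %/% 8 + 1),
      position = sprintf("R%02d", (idx - 1) %% 8 + 1),
      plate = sprintf("plate%02d", (idx - 1) %/% 96 + 1),
      well = wells[(idx - 1) %% 96 + 1],
      stringsAsFactors = FALSE
    )
    m <- match(sample_sheet$subject_id, subj)
    sample_sheet$age <- age[m]
    sample_sheet$survival_time <- survival_time[m]
    sample_sheet$event <- event[m]

    structure(list(
      true_beta = true_beta,
      age = setNames(age, subj),
      latent_aging_score = setNames(score, subj),
      survival_time = setNames(survival_time, subj),
      event = setNames(event, subj),
      aging_probes = probes[aging_idx],
      aging_weights = if (n_aging > 0) setNames(w, probes[aging_idx]) else numeric(0),
      variance_components = c(subject = pheno$subject_sd^2, occasion = NA,
                              batch = NA, residual = NA),
      sample_sheet = sample_sheet,
      pheno = pheno,
      seed = seed
    ), class = "ground_truth")
  })
}

#' Technical-artifact configuration for intensity simulation
#'
#' Parameters of the intensity-level measurement model. All multiplicative
#' artifacts act on the log-intensity scale. Defaults give a realistic mix of
#' artifacts; each SD can be set to 0 to switch an artifact class off, or
#' raised to inject a single class in isolation.
#'
#' @param bg_mean named numeric `c(red=, green=)`, additive background mean
#'   per channel (intensity units).
#' @param bg_sd probe-level SD of the truncated-normal background draw.
#' @param bg_array_sd per-array log-scale SD of the background level (arrays
#'   differ in overall background; this is what background correction can
#'   remove).
#' @param dye_bias_sd per-array log-scale SD of the red-channel multiplier
#'   (the SD of control-pair log red/green ratios across arrays).
#' @param type2_compression mean linear compression of type-II betas toward
#'   0.5, in (0, 1]; 1 = no compression.
#' @param type2_compression_sd per-array SD of the compression factor
#'   (truncated to (0.05, 1]); per-array variation is what probe-type
#'   calibration can remove.
#' @param batch_sds named numeric `c(chip=, position=, plate=, well=)`,
#'   log-scale SD of per-level, per-channel batch effects.
#' @param occasion_shift_sd per-array log-scale SD of an overall intensity
#'   shift (both channels).
#' @param signal_meanlog,signal_sdlog lognormal parameters of per-probe total
#'   signal.
#' @param signal_noise_sd per-probe-per-array log-scale measurement noise.
#' @param control_meanlog,control_sdlog lognormal parameters of control-pair
#'   target intensities.
#' @return a named list of class `tech_config`.
#' @export
tech_config <- function(bg_mean = c(red = 500, green = 500),
                        bg_sd = 50,
                        bg_array_sd = 0.15,
                        dye_bias_sd = 0.08,
                        type2_compression = 0.85,
                        type2_compression_sd = 0.04,
                        batch_sds = c(chip = 0.090, position = 0.036,
                                      plate = 0.054, well = 0.036),
                        occasion_shift_sd = 0.05,
                        signal_meanlog = log(5000),
                        signal_sdlog = 0.25,
                        signal_noise_sd = 0.05,
                        control_meanlog = log(5000),
                        control_sdlog = 0.3) {
  if (type2_compression <= 0 || type2_compression > 1)
    stop("type2_compression must lie in (0, 1]")
  sds <- c(bg_sd, bg_array_sd, dye_bias_sd, type2_compression_sd,
           batch_sds, occasion_shift_sd, signal_sdlog, signal_noise_sd)
  if (any(sds < 0)) stop("artifact SDs must be non-negative")
  stopifnot(all(c("red", "green") %in% names(bg_mean)),
            all(c("chip", "position", "plate", "well") %in% names(batch_sds)))
  structure(list(bg_mean = bg_mean, bg_sd = bg_sd, bg_array_sd = bg_array_sd,
                 dye_bias_sd = dye_bias_sd,
                 type2_compression = type2_compression,
                 type2_compression_sd = type2_compression_sd,
                 batch_sds = batch_sds,
                 occasion_shift_sd = occasion_shift_sd,
                 signal_meanlog = signal_meanlog,
                 signal_sdlog = signal_sdlog,
                 signal_noise_sd = signal_noise_sd,
                 control_meanlog = control_meanlog,
                 control_sdlog = control_sdlog),
            class = "tech_config")
}

#' Simulate raw Infinium-style intensities from ground truth
#'
#' Measurement model per CpG probe p and array a with per-probe total signal
#' `S_p` (lognormal) and channel multiplier
#' `M_ac = dye_a[red only] * batch_a,c * occasion_a`:
#'
#' * type II: `meth = S * beta' * M_green + bg_green`,
#'   `unmeth = S * (1 - beta') * M_red + bg_red`, with
#'   `beta' = 0.5 + c_a (beta - 0.5)` (per-array compression `c_a`);
#' * type I (channel c): both alleles read in channel c, `beta' = beta`;
#'   an out-of-band draw from the opposite channel's pure background law is
#'   recorded per probe;
#' * control pairs: a fixed target intensity measured in both channels, so
#'   channel imbalance is identifiable;
#' * negative controls: pure background in both channels (`meth` holds the
#'   green read, `unmeth` the red read).
#'
#' Background is additive truncated-normal (at zero) per channel, its
#' per-array level jittered on the log scale by `bg_array_sd`; out-of-band
#' draws come from the same law, so they are an unbiased background sample.
#' Replicate arrays of a pair share `true_beta` but receive independent
#' technical draws.
#'
#' @param truth a `ground_truth`.
#' @param manifest the `array_manifest` used to build it.
#' @param tech a `tech_config`.
#' @param seed integer seed.
#' @return An object of class `intensity_dataset`: list with `meth`,
#'   `unmeth` (probes x arrays; control rows carry their channel read in
#'   `meth`/`unmeth` as described), `oob` (type-I probes x arrays),
#'   `sample_sheet`, and the `manifest` probe order.
#' @export
simulate_intensities <- function(truth, manifest, tech = tech_config(),
                                 seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(manifest, "array_manifest"))
  if (!inherits(tech, "tech_config")) tech <- do.call(tech_config, tech)
  sheet <- truth$sample_sheet
  n_arrays <- nrow(sheet)
  probes <- manifest$probe_id
  cpg <- cpg_index(manifest)
  type1 <- which(manifest$design_type == "I")
  type2 <- which(manifest$design_type == "II")
  ctl <- which(!is.na(manifest$control_pair_id))
  neg <- which(manifest$is_negative_control)

  with_seed(stage_seed(seed, "intensities"), {
    ## per-probe total signal (CpG probes), fixed across arrays
    S <- exp(rnorm(length(cpg), tech$signal_meanlog, tech$signal_sdlog))
    ## control targets, fixed across arrays
    ctl_ids <- unique(manifest$control_pair_id[ctl])
    C <- setNames(exp(rnorm(length(ctl_ids), tech$control_meanlog,
                            tech$control_sdlog)), ctl_ids)

    ## per-array artifacts (always drawn so streams align across configs)
    dye <- exp(rnorm(n_arrays, 0, 1) * tech$dye_bias_sd)          # red only
    occ <- exp(rnorm(n_arrays, 0, 1) * tech$occasion_shift_sd)
    bg_lvl <- exp(rnorm(n_arrays, 0, 1) * tech$bg_array_sd)
    c_a <- tech$type2_compression +
      rnorm(n_arrays, 0, 1) * tech$type2_compression_sd
    c_a <- pmin(pmax(c_a, 0.05), 1)

    ## batch effects: per level, per channel, per factor
    mult_red <- rep(1, n_arrays)
    mult_grn <- rep(1, n_arrays)
    for (f in c("chip", "position", "plate", "well")) {
      lev <- unique(sheet[[f]])
      eff_r <- setNames(rnorm(length(lev), 0, 1) * tech$batch_sds[[f]], lev)
      eff_g <- setNames(rnorm(length(lev), 0, 1) * tech$batch_sds[[f]], lev)
      mult_red <- mult_red * exp(eff_r[sheet[[f]]])
      mult_grn <- mult_grn * exp(eff_g[sheet[[f]]])
    }
    M_red <- dye * occ * mult_red
    M_grn <- occ * mult_grn

    subj_row <- match(sheet$subject_id, rownames(truth$true_beta))
    beta_arr <- t(truth$true_beta[subj_row, , drop = FALSE])  # CpG x arrays
    rownames(beta_arr) <- colnames(truth$true_beta)

    n_probes <- length(probes)
    meth <- matrix(NA_real_, n_probes, n_arrays,
                   dimnames = list(probes, sheet$array_id))
    unmeth <- meth

    ## per-probe-per-array noise
    eps <- matrix(exp(rnorm(length(cpg) * n_arrays, 0, 1) *
                        tech$signal_noise_sd), length(cpg), n_arrays)
    sig <- S * eps   # recycles S down columns

    bprime <- beta_arr
    if (length(type2) > 0) {
      t2 <- match(type2, cpg)
      bprime[t2, ] <- 0.5 + sweep(beta_arr[t2, , drop = FALSE] - 0.5, 2,
                                  c_a, "*")
    }

    ## truncated-normal background via inverse CDF; per-array level jitters
    ## the mean, truncation at zero stays exact
    bg_draw <- function(channel, n) {
      mu <- tech$bg_mean[[channel]]
      u <- matrix(runif(n * n_arrays), n, n_arrays)
      m <- matrix(NA_real_, n, n_arrays)
      for (a in seq_len(n_arrays)) {
        mean_a <- mu * bg_lvl[a]
        if (tech$bg_sd == 0) {
          m[, a] <- mean_a
        } else {
          lo <- pnorm(0, mean_a, tech$bg_sd)
          m[, a] <- qnorm(lo + u[, a] * (1 - lo), mean_a, tech$bg_sd)
        }
      }
      m
    }

    ## type II: meth green, unmeth red
    if (length(type2) > 0) {
      t2 <- match(type2, cpg)
      meth[type2, ] <- sweep(sig[t2, , drop = FALSE] *
                               bprime[t2, , drop = FALSE], 2, M_grn, "*") +
        bg_draw("green", length(type2))
      unmeth[type2, ] <- sweep(sig[t2, , drop = FALSE] *
                                 (1 - bprime[t2, , drop = FALSE]), 2, M_red, "*") +
        bg_draw("red", length(type2))
    }

    ## type I: both reads in the probe's channel; oob from the other channel
    oob <- NULL
    if (length(type1) > 0) {
      t1 <- match(type1, cpg)
      ch <- manifest$channel[type1]
      Mch <- rbind(red = M_red, green = M_grn)
      Mmat <- Mch[ch, , drop = FALSE]               # type-I probes x arrays
      bg_r <- bg_draw("red", length(type1))
      bg_g <- bg_draw("green", length(type1))
      bg_in <- ifelse(ch == "red", 1, 0) * bg_r +
        ifelse(ch == "green", 1, 0) * bg_g
      bg_in2 <- bg_draw("red", length(type1)) * (ch == "red") +
        bg_draw("green", length(type1)) * (ch == "green")
      meth[type1, ] <- sig[t1, , drop = FALSE] *
        bprime[t1, , drop = FALSE] * Mmat + bg_in
      unmeth[type1, ] <- sig[t1, , drop = FALSE] *
        (1 - bprime[t1, , drop = FALSE]) * Mmat + bg_in2
      ## out-of-band: pure background from the opposite channel
      oob <- bg_draw("red", length(type1)) * (ch == "green") +
        bg_draw("green", length(type1)) * (ch == "red")
      dimnames(oob) <- list(manifest$probe_id[type1], sheet$array_id)
    }

    ## control pairs: fixed target in the row's channel
    if (length(ctl) > 0) {
      tgt <- C[manifest$control_pair_id[ctl]]
      ch <- manifest$channel[ctl]
      Mch <- rbind(red = M_red, green = M_grn)
      meth[ctl, ] <- tgt * Mch[ch, , drop = FALSE] +
        bg_draw("red", length(ctl)) * (ch == "red") +
        bg_draw("green", length(ctl)) * (ch == "green")
    }

    ## negative controls: background only; meth = green read, unmeth = red
    if (length(neg) > 0) {
      meth[neg, ] <- bg_draw("green", length(neg))
      unmeth[neg, ] <- bg_draw("red", length(neg))
    }

    structure(list(meth = meth, unmeth = unmeth, oob = oob,
                   sample_sheet = sheet, probe_ids = probes,
                   tech = tech, seed = seed),
              class = "intensity_dataset")
  })
}
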