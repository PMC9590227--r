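test_that("background correction removes a known injected background", {
  co <- make_cohort(seed = 1, n_probes = 400, n_subjects = 30,
                    n_replicate_pairs = 0,
                    tech = tech_baseline(bg_mean = c(red = 500, green = 500),
                                         bg_sd = 30))
  neg <- which(co$man$is_negative_control)
  for (method in c("oob", "neg")) {
    cor_ds <- background_correct(co$ds, method, co$man)
    ## background-only probes (negative controls) should drop to ~the floor:
    ## residual bias below 5% of the injected 500
    expect_lt(mean(cor_ds$meth[neg, ]) - 1, 0.05 * 500)
    expect_true(all(cor_ds$meth[neg, ] >= 1))
  }
  ## the two estimators agree when both sources draw from the same law
  d_oob <- background_correct(co$ds, "oob", co$man)
  d_neg <- background_correct(co$ds, "neg", co$man)
  cpg <- which(!is.na(co$man$design_type))
  expect_lt(mean(abs(d_oob$meth[cpg, ] - d_neg$meth[cpg, ])), 10)
})

test_that("background correction is the identity when no background is injected", {
  co <- make_cohort(seed = 2, n_probes = 300, n_subjects = 15,
                    n_replicate_pairs = 0,
                    tech = tech_baseline(bg_mean = c(red = 0, green = 0),
                                         bg_sd = 0))
  cor_ds <- background_correct(co$ds, "oob", co$man, floor = 0)
  cpg <- which(!is.na(co$man$design_type))
  expect_equal(cor_ds$meth[cpg, ], co$ds$meth[cpg, ], tolerance = 1e-12)
})

test_that("dye correction neutralizes a known multiplicative imbalance", {
  for (d in c(0.5, 2)) {
    man <- generate_manifest(150, n_neighbor_pairs = 0, seed = 3)
    tr <- simulate_truth(man, 30, 0, seed = 3)
    ds <- simulate_intensities(tr, man, tech_silent(), seed = 3)
    ## inject an exact factor d on every red-channel measurement
    red <- methrel:::red_measurements(man)
    ds$meth[red$meth, ] <- ds$meth[red$meth, ] * d
    ds$unmeth[red$unmeth, ] <- ds$unmeth[red$unmeth, ] * d
    for (method in c("mean", "relic")) {
      out <- dye_correct(ds, method, man)
      ctl_r <- which(!is.na(man$control_pair_id) & man$channel == "red")
      ctl_g <- which(!is.na(man$control_pair_id) & man$channel == "green")
      ctl_g <- ctl_g[match(man$control_pair_id[ctl_r],
                           man$control_pair_id[ctl_g])]
      lr <- log(out$meth[ctl_r, ] / out$meth[ctl_g, ])
      expect_lt(max(abs(colMeans(lr))), 0.01)
    }
  }
})

test_that("dye correction is a near-identity when channels are balanced", {
  co <- make_cohort(seed = 4, n_probes = 200, n_neighbor_pairs = 20,
                    n_subjects = 20, n_replicate_pairs = 0,
                    tech = tech_silent())
  out <- dye_correct(co$ds, "relic", co$man)
  cpg <- which(!is.na(co$man$design_type))
  expect_equal(out$meth[cpg, ], co$ds$meth[cpg, ], tolerance = 1e-6)
  ## mean and relic coincide for a purely multiplicative bias
  ds <- co$ds
  red <- methrel:::red_measurements(co$man)
  ds$meth[red$meth, ] <- ds$meth[red$meth, ] * 1.7
  ds$unmeth[red$unmeth, ] <- ds$unmeth[red$unmeth, ] * 1.7
  m1 <- dye_correct(ds, "mean", co$man)
  m2 <- dye_correct(ds, "relic", co$man)
  expect_equal(m1$unmeth[cpg, ], m2$unmeth[cpg, ], tolerance = 1e-6)
})

test_that("quantile normalization equalizes distributions within strata", {
  co <- make_cohort(seed = 5, n_probes = 300, n_subjects = 12,
                    n_replicate_pairs = 0)
  for (method in c("q1", "q2", "q3")) {
    out <- quantile_normalize(co$ds, method, co$man)
    strata <- switch(method,
      q1 = {
        t1 <- which(co$man$design_type == "I")
        t2 <- which(co$man$design_type == "II")
        list(m1 = out$meth[t1, ], m2 = out$meth[t2, ],
             u1 = out$unmeth[t1, ], u2 = out$unmeth[t2, ])
      },
      q2 = {
        cpg <- which(!is.na(co$man$design_type))
        list(m = out$meth[cpg, ], u = out$unmeth[cpg, ])
      },
      q3 = {
        cpg <- which(!is.na(co$man$design_type))
        list(all = rbind(out$meth[cpg, ], out$unmeth[cpg, ]))
      })
    for (s in strata) {
      sorted <- apply(s, 2, sort)
      expect_lt(max(abs(sorted - sorted[, 1])), 1e-9)
    }
  }
  ## idempotent on identical columns
  ds <- co$ds
  for (a in 2:ncol(ds$meth)) {
    ds$meth[, a] <- ds$meth[, 1]
    ds$unmeth[, a] <- ds$unmeth[, 1]
  }
  out <- quantile_normalize(ds, "q2", co$man)
  expect_equal(out$meth, ds$meth, tolerance = 1e-12)
  ## q1 and q3 differ when type-II intensities are compressed
  co2 <- make_cohort(seed = 6, n_probes = 300, n_subjects = 12,
                     n_replicate_pairs = 0,
                     tech = tech_baseline(type2_compression = 0.7))
  o1 <- quantile_normalize(co2$ds, "q1", co2$man)
  o3 <- quantile_normalize(co2$ds, "q3", co2$man)
  expect_gt(max(abs(o1$meth[which(!is.na(co2$man$design_type)), ] -
                      o3$meth[which(!is.na(co2$man$design_type)), ])), 1)
})

test_that("beta computation follows the offset convention", {
  man <- generate_manifest(100, type2_fraction = 1, n_control_pairs = 0,
                           n_negative_controls = 0, seed = 1)
  ds <- structure(list(
    meth = matrix(100, 100, 2, dimnames = list(man$probe_id, c("a", "b"))),
    unmeth = matrix(100, 100, 2, dimnames = list(man$probe_id, c("a", "b"))),
    oob = NULL, sample_sheet = data.frame(array_id = c("a", "b"))),
    class = "intensity_dataset")
  expect_equal(unname(compute_beta(ds, offset = 100)$values[1, 1]), 1 / 3)
  expect_equal(unname(compute_beta(ds, offset = 0)$values[1, 1]), 0.5)
  ds$meth[] <- 0; ds$unmeth[] <- 0
  expect_equal(unname(compute_beta(ds, offset = 0)$values[1, 1]), 0)
  ds$meth[] <- -1
  expect_error(compute_beta(ds), "negative")
})

test_that("probe-type calibration inverts a linear compression exactly", {
  co <- make_cohort(seed = 7, n_probes = 500, n_neighbor_pairs = 60,
                    n_subjects = 10, n_replicate_pairs = 0,
                    tech = tech_silent(type2_compression = 0.8))
  beta <- compute_beta(co$ds, offset = 0, manifest = co$man)
  fixed <- rcp_correct(beta, co$man)
  truth_arr <- t(co$tr$true_beta[match(co$ds$sample_sheet$subject_id,
                                       rownames(co$tr$true_beta)), ])
  t2 <- co$man$probe_id[which(co$man$design_type == "II")]
  expect_lt(max(abs(fixed$values[t2, ] - truth_arr[t2, ])), 1e-6)
  ## without compression the correction is a near-identity
  co1 <- make_cohort(seed = 8, n_probes = 500, n_neighbor_pairs = 60,
                     n_subjects = 10, n_replicate_pairs = 0,
                     tech = tech_silent(type2_compression = 1))
  b1 <- compute_beta(co1$ds, offset = 0, manifest = co1$man)
  f1 <- rcp_correct(b1, co1$man)
  expect_lt(max(abs(f1$values - b1$values)), 1e-6)
})

test_that("calibration reduces type-II vs type-I disagreement under noise", {
  improved <- vapply(1:20, function(s) {
    co <- make_cohort(seed = s, n_probes = 300, n_neighbor_pairs = 40,
                      n_subjects = 8, n_replicate_pairs = 0,
                      tech = tech_baseline(type2_compression = 0.8))
    beta <- compute_beta(co$ds, manifest = co$man)
    fixed <- rcp_correct(beta, co$man)
    truth_arr <- t(co$tr$true_beta[match(co$ds$sample_sheet$subject_id,
                                         rownames(co$tr$true_beta)), ])
    t2 <- co$man$probe_id[which(co$man$design_type == "II")]
    before <- mean(abs(beta$values[t2, ] - truth_arr[t2, ]))
    after <- mean(abs(fixed$values[t2, ] - truth_arr[t2, ]))
    after < before
  }, logical(1))
  expect_gte(mean(improved), 0.9)
})

test_that("rcp refuses to run with too few neighbor pairs", {
  co <- make_cohort(seed = 9, n_probes = 300, n_neighbor_pairs = 5,
                    n_subjects = 5, n_replicate_pairs = 0)
  beta <- compute_beta(co$ds, manifest = co$man)
  expect_error(rcp_correct(beta, co$man), ">= 10 neighbor pairs")
})
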