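test_that("predictor application is the documented linear combination", {
  beta <- matrix(c(0.5, 0.5, 0.2, 0.8), 2, 2,
                 dimnames = list(c("p1", "p2"), c("a1", "a2")))
  m <- predictor_model("toy", 0.5, c(p1 = 2, p2 = -1))
  est <- apply_predictor(beta, m)
  expect_equal(est$toy, c(0.5 + 2 * 0.5 - 0.5, 0.5 + 2 * 0.2 - 0.8))
  ## all-zero weights give the constant intercept
  m0 <- predictor_model("const", 3.2, c(p1 = 0, p2 = 0))
  expect_equal(apply_predictor(beta, m0)$const, c(3.2, 3.2))
  ## linearity on the identity transform
  b2 <- beta * 0.3 + 0.1
  a <- 0.4
  mix <- apply_predictor(a * beta + (1 - a) * b2, m)$toy
  expect_equal(mix, a * apply_predictor(beta, m)$toy +
                 (1 - a) * apply_predictor(b2, m)$toy)
})

test_that("missing probes follow the configured policy", {
  beta <- matrix(0.5, 1, 2, dimnames = list("p1", c("a1", "a2")))
  m_err <- predictor_model("strict", 0, c(p1 = 1, p2 = 1),
                           missing_policy = "error")
  expect_error(apply_predictor(beta, m_err), "p2")
  m_imp <- predictor_model("lax", 0, c(p1 = 1, p2 = 1))
  expect_message(est <- apply_predictor(beta, m_imp), "mean-imputed")
  expect_equal(est$lax, c(1, 1))  # grand mean 0.5 fills p2
})

test_that("age-targeted synthetic clocks are exact on noise-free betas", {
  co <- make_cohort(seed = 1, n_probes = 600, n_neighbor_pairs = 50,
                    n_subjects = 40, n_replicate_pairs = 0,
                    tech = tech_silent())
  models <- make_weight_tables(co$man, co$tr, list(
    list(name = "SynthClock", n_probes = 353, target = "age",
         transform = "horvath_age"),
    list(name = "LinearClock", n_probes = 100, target = "age"),
    list(name = "Noise", n_probes = 50, target = "random")), seed = 1)
  expect_length(models$SynthClock$weights, 353)
  beta <- compute_beta(co$ds, offset = 0, manifest = co$man)
  est <- apply_predictor(beta, models)
  ages <- co$ds$sample_sheet$age
  expect_equal(est$SynthClock, ages, tolerance = 1e-6)
  expect_equal(est$LinearClock, ages, tolerance = 1e-6)
  ## independent re-fit of the least-squares construction
  ids <- names(models$LinearClock$weights)
  refit <- MASS::ginv(cbind(1, co$tr$true_beta[, ids])) %*% co$tr$age
  expect_equal(unname(models$LinearClock$intercept), refit[1],
               tolerance = 1e-8)
  expect_error(
    make_weight_tables(co$man, co$tr,
                       list(list(name = "x", n_probes = 10000,
                                 target = "age")), seed = 1),
    "only")
})

test_that("random-weight predictors are uncorrelated with age over seeds", {
  man <- generate_manifest(300, n_neighbor_pairs = 20, seed = 1)
  cors <- vapply(1:15, function(s) {
    tr <- simulate_truth(man, 120, 0, seed = s)
    m <- make_weight_tables(man, tr, list(list(name = "r", n_probes = 80,
                                               target = "random")), seed = s)
    cor(drop(m$r$intercept + tr$true_beta[, names(m$r$weights)] %*%
               m$r$weights), tr$age)
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.1)
})

test_that("the age calibration is an exact, monotone round trip", {
  expect_equal(horvath_inverse(0), 20)
  expect_equal(horvath_inverse(1), 41)
  ## independent forward oracle, composed both ways
  fwd <- function(age, A = 20)
    ifelse(age <= A, log(age + 1) - log(A + 1), (age - A) / (A + 1))
  for (age in c(0, 5, 20, 60, 100))
    expect_equal(horvath_inverse(fwd(age)), age, tolerance = 1e-12)
  s <- seq(-3, 3, by = 0.01)
  expect_true(all(diff(horvath_inverse(s)) > 0))
  ## continuity at the knot
  expect_equal(horvath_inverse(-1e-12), horvath_inverse(1e-12),
               tolerance = 1e-9)
})

test_that("predictor model CSV serialization round-trips and is strict", {
  m <- predictor_model("clock", 1.2345678901234,
                       c(cg0000001 = 0.5, cg0000002 = -2.25),
                       transform = "horvath_age", adult_age = 20)
  path <- withr::local_tempfile(fileext = ".csv")
  write_predictor_model(m, path)
  m2 <- read_predictor_model(path)
  expect_equal(m2$weights, m$weights)
  expect_equal(m2$intercept, m$intercept)
  expect_equal(m2$transform, "horvath_age")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# name=x", "# intercept=0", "probe_id,weight",
               "cg1,0.5", "cg2,abc"), bad)
  expect_error(read_predictor_model(bad), "line 5")
  writeLines(c("# name=x", "probe_id,weight", "cg1,0.5"), bad)
  expect_error(read_predictor_model(bad), "intercept")
})

test_that("cell-fraction deconvolution recovers known mixtures", {
  set.seed(42)
  ref <- matrix(runif(60 * 3), 60, 3,
                dimnames = list(sprintf("cg%07d", 1:60),
                                c("Tcell", "Bcell", "Mono")))
  ## vertex: observed = one reference column
  obs <- cbind(ref[, 2], 0.5 * ref[, 1] + 0.5 * ref[, 3])
  colnames(obs) <- c("a1", "a2")
  dec <- deconvolve_cell_fractions(obs, ref)
  expect_equal(unname(dec$fractions["a1", ]), c(0, 1, 0), tolerance = 1e-8)
  expect_equal(unname(dec$fractions["a2", ]), c(0.5, 0, 0.5),
               tolerance = 1e-8)

  ## noisy mixtures: mean absolute error under 0.03 at noise SD 0.02
  n_arr <- 100
  f_true <- t(apply(matrix(rexp(n_arr * 3), n_arr), 1,
                    function(x) x / sum(x)))
  obs <- ref %*% t(f_true) + matrix(rnorm(60 * n_arr, 0, 0.02), 60)
  colnames(obs) <- sprintf("s%03d", seq_len(n_arr))
  dec <- deconvolve_cell_fractions(obs, ref)
  expect_lt(mean(abs(dec$fractions - f_true)), 0.03)
  expect_true(all(dec$fractions >= 0 & dec$fractions <= 1))
  expect_true(all(rowSums(dec$fractions) <= 1 + 1e-8))
  ## renormalization forces the simplex
  dec2 <- deconvolve_cell_fractions(obs, ref, renormalize = TRUE)
  expect_equal(unname(rowSums(dec2$fractions)), rep(1, n_arr))
  ## collinear reference warns
  ref_bad <- cbind(ref[, 1], ref[, 1] * (1 + 1e-12))
  rownames(ref_bad) <- rownames(ref)
  expect_warning(deconvolve_cell_fractions(obs, ref_bad), "collinear")
})
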