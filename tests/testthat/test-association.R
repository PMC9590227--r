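test_that("distribution summaries follow the sample conventions", {
  est <- data.frame(array_id = c("a", "b"), p1 = c(1, 3), p2 = c(5, 5),
                    p3 = c(-1, 1))
  s <- summarize_distribution(est)
  expect_equal(s$mean, c(2, 5, 0))
  expect_equal(s$sd, c(sqrt(2), 0, sqrt(2)))
  expect_equal(s$cv, c(sqrt(2) / 2, 0, NA))
})

test_that("age acceleration residuals are mean-zero and orthogonal to age", {
  set.seed(1)
  age <- runif(50, 30, 80)
  ## exact linearity leaves no acceleration
  expect_equal(age_acceleration(2 * age + 5, age), rep(0, 50),
               ignore_attr = TRUE, tolerance = 1e-10)
  est <- 1.5 * age + rnorm(50, 0, 3)
  res <- age_acceleration(est, age)
  expect_lt(abs(sum(res * age)), 1e-8)
  expect_lt(abs(mean(res)), 1e-10)
  expect_error(age_acceleration(est, rep(50, 50)), "constant")
})

test_that("Cox coefficients match a 1-D partial-likelihood grid oracle", {
  ## 4-subject pattern, distinct event times, no ties, no separation
  time <- c(2, 5, 8, 11)
  event <- c(1, 1, 1, 1)
  x <- c(0.5, -1, 1, -0.2)
  fit <- cox_mortality(rep(x, 3), rep(time, 3) + rep(c(0, .01, .02), each = 4),
                       rep(event, 3))
  ## grid-search oracle on the replicated data (no ties by construction)
  t_all <- rep(time, 3) + rep(c(0, .01, .02), each = 4)
  x_all <- rep(x, 3)
  loglik <- function(b) {
    ord <- order(t_all)
    lp <- b * x_all
    sum(vapply(which(rep(event, 3)[ord] == 1), function(i) {
      risk <- ord[i:length(ord)]
      lp[ord[i]] - log(sum(exp(lp[risk])))
    }, numeric(1)))
  }
  grid <- seq(-3, 3, by = 1e-4)
  b_hat <- grid[which.max(vapply(grid, loglik, numeric(1)))]
  expect_equal(fit$coef, b_hat, tolerance = 1e-3)
  expect_equal(fit$hr, exp(b_hat), tolerance = 1e-3)
  expect_error(cox_mortality(x, time, c(1, 1, 0, 0)), ">= 10 events")
  expect_error(cox_mortality(x_all, t_all - 3, rep(event, 3)), "positive")
})

test_that("Cox coefficient is invariant to time units and covariate shifts", {
  set.seed(5)
  n <- 300
  x <- rnorm(n)
  age <- runif(n, 40, 70)
  tt <- rexp(n, 0.02 * exp(0.4 * x))
  ev <- as.integer(tt < 15)
  tt <- pmin(tt, 15)
  f1 <- cox_mortality(x, tt, ev, covariates = data.frame(age = age))
  f2 <- cox_mortality(x, tt * 365.25, ev,
                      covariates = data.frame(age = age + 100))
  expect_equal(f1$coef, f2$coef, tolerance = 1e-6)
  ## scaling the predictor by 1/a scales the coefficient by a
  f3 <- cox_mortality(x / 2, tt, ev, covariates = data.frame(age = age))
  expect_equal(f3$coef, 2 * f1$coef, tolerance = 1e-6)
})

test_that("spearman correlation handles monotonicity, ties, and small n", {
  expect_equal(spearman_cor(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_cor(1:10, -(1:10))$rho, -1)
  ## invariance to strictly monotone transforms
  set.seed(2)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(spearman_cor(x, y)$rho, spearman_cor(exp(x), y^3 + y)$rho)
  ## tied data against a brute-force ranking oracle
  xt <- c(1, 2, 2, 3, 4, 4, 4, 5, 6, 7, 8, 9)
  yt <- c(2, 1, 3, 3, 5, 4, 6, 7, 7, 8, 10, 9)
  rank_oracle <- function(v) {
    sapply(seq_along(v), function(i) {
      less <- sum(v < v[i]); eq <- sum(v == v[i])
      less + (eq + 1) / 2
    })
  }
  expect_equal(spearman_cor(xt, yt)$rho,
               cor(rank_oracle(xt), rank_oracle(yt)))
  ## exact permutation p at small n agrees with cor.test's exact method
  xs <- c(3, 1, 4, 1.5, 5, 9)
  ys <- c(2, 7, 1.8, 2.8, 8, 2.9)
  p_exact <- suppressWarnings(
    cor.test(xs, ys, method = "spearman", exact = TRUE)$p.value)
  expect_equal(spearman_cor(xs, ys)$p, p_exact, tolerance = 1e-10)
  ## degenerate input flags undefined
  out <- spearman_cor(rep(1, 6), 1:6)
  expect_true(out$undefined)
  expect_true(is.na(out$rho))
})

test_that("icc-statistic correlation records the statistic and flags constants", {
  r <- icc_statistic_correlation(c(0.9, 0.8, 0.95, 0.7), c(1, 2, 0.5, 3),
                                 statistic = "z")
  expect_equal(r$statistic, "z")
  expect_lt(r$rho, 0)
  r2 <- icc_statistic_correlation(c(0.9, 0.8, 0.95, 0.7), rep(2, 4))
  expect_true(r2$undefined)
})

test_that("pipeline ranking reproduces a hand-worked toy and is monotone", {
  m <- rbind(A = c(0.9, 0.8, 0.7), B = c(0.1, 0.3, 0.2))
  colnames(m) <- c("p1", "p2", "p3")
  rk <- rank_pipelines(m)
  expect_equal(unname(rk$ranks["A", ]), c(1, 2, 3))
  expect_equal(unname(rk$ranks["B", ]), c(3, 1, 2))
  expect_equal(unname(rk$median_rank), c(2, 1.5, 2.5))
  expect_equal(rk$best$best_pipeline, c("p1", "p2"))
  expect_equal(rk$best$median_icc, c(0.8, 0.2))
  ## single pipeline: every rank 1
  rk1 <- rank_pipelines(m[, 1, drop = FALSE])
  expect_true(all(rk1$ranks == 1))
  ## adding a dominated pipeline preserves the relative order of the others
  m2 <- cbind(m, worst = c(0.01, 0.01))
  rk2 <- rank_pipelines(m2)
  expect_equal(rk2$ranks[, 1:3], rk$ranks)
  ## degenerate NA cells rank last
  m3 <- m; m3["A", "p2"] <- NA
  rk3 <- rank_pipelines(m3)
  expect_equal(unname(rk3$ranks["A", ]), c(1, 3, 2))
})
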