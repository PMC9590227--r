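#' Assemble a replicate table from estimates and a sample sheet
#'
#' Builds the n_pairs x 2 matrix of predictor estimates (columns =
#' occasions) that the ICC machinery consumes. Pairs with a missing member
#' or missing estimate are dropped with a message.
#'
#' @param estimates a `predictor_estimates` or data frame with `array_id`.
#' @param sample_sheet data frame with `array_id`, `replicate_pair_id`, and
#'   (optionally) `occasion`.
#' @param predictor name of the estimate column.
#' @return matrix n_pairs x 2, rownames = pair IDs, of class
#'   `replicate_table`.
#' @export
replicate_table <- function(estimates, sample_sheet, predictor) {
  stopifnot(predictor %in% names(estimates))
  sheet <- sample_sheet[!is.na(sample_sheet$replicate_pair_id), ]
  v <- estimates[[predictor]][match(sheet$array_id, estimates$array_id)]
  keep <- !is.na(v)
  sheet <- sheet[keep, , drop = FALSE]
  v <- v[keep]
  occ <- if ("occasion" %in% names(sheet)) sheet$occasion
         else stats::ave(seq_along(v), sheet$replicate_pair_id,
                         FUN = seq_along)
  ids <- unique(sheet$replicate_pair_id)
  m <- matrix(NA_real_, length(ids), 2,
              dimnames = list(ids, c("occasion1", "occasion2")))
  m[cbind(match(sheet$replicate_pair_id, ids), occ)] <- v
  complete <- rowSums(is.na(m)) == 0
  if (any(!complete))
    message("dropping ", sum(!complete), " incomplete replicate pair(s)")
  m <- m[complete, , drop = FALSE]
  if (nrow(m) < 3) stop("replicate table needs >= 3 complete pairs")
  class(m) <- c("replicate_table", "matrix", "array")
  m
}

#' Two-way ANOVA mean squares for a replicate table
#'
#' Decomposes an n x k table (rows = subjects/pairs, columns = occasions)
#' into between-row (MSR), between-column (MSC), interaction/residual (MSE),
#' and within-row (MSW) mean squares -- the ingredients of the
#' Shrout-Fleiss intraclass correlations.
#'
#' @param pairs numeric matrix n x k, n >= 3.
#' @return list with `MSR`, `MSC`, `MSE`, `MSW`, `n`, `k`.
#' @export
two_way_anova <- function(pairs) {
  x <- unclass(pairs)
  stopifnot(is.matrix(x), nrow(x) >= 3, ncol(x) >= 2, !anyNA(x))
  n <- nrow(x); k <- ncol(x)
  gm <- mean(x)
  if (sum((x - gm)^2) < .Machine$double.eps * n * k * max(1, gm^2))
    stop("degenerate replicate data: zero total variance, ICC undefined")
  rm_ <- rowMeans(x)
  cm <- colMeans(x)
  SSR <- k * sum((rm_ - gm)^2)
  SSC <- n * sum((cm - gm)^2)
  SSE <- sum((x - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + gm)^2)
  SSW <- sum((x - rm_)^2)
  list(MSR = SSR / (n - 1),
       MSC = SSC / (k - 1),
       MSE = SSE / ((n - 1) * (k - 1)),
       MSW = SSW / (n * (k - 1)),
       n = n, k = k)
}

#' Intraclass correlations for technical replicate agreement
#'
#' Computes all six Shrout-Fleiss intraclass correlations from a replicate
#' table: ICC(1,1) and ICC(1,k) from the one-way random model, ICC(2,1) and
#' ICC(2,k) from the two-way random model (absolute agreement; occasion
#' variance penalizes), ICC(3,1) and ICC(3,k) from the two-way mixed model
#' (consistency; a constant occasion offset is invisible). The significance
#' test is F = MSR/MSE with (n-1, (n-1)(k-1)) degrees of freedom (F =
#' MSR/MSW with (n-1, n(k-1)) df for the one-way forms). Confidence
#' intervals follow the F-based Shrout-Fleiss constructions. Negative point
#' estimates are reported as computed, with `negative = TRUE` flagged.
#'
#' @param pairs numeric matrix n x k (use [replicate_table()]).
#' @param conf_level confidence level (default 0.95).
#' @return an `icc_result`: list with `icc` (named length-6 vector), `ms`,
#'   `fvalue`, `df`, `p_value`, `ci` (6 x 2 matrix), `n`, `k`,
#'   `conf_level`, `negative`.
#' @export
icc <- function(pairs, conf_level = 0.95) {
  ms <- two_way_anova(pairs)
  n <- ms$n; k <- ms$k
  MSR <- ms$MSR; MSC <- ms$MSC; MSE <- ms$MSE; MSW <- ms$MSW
  alpha <- 1 - conf_level

  icc11 <- (MSR - MSW) / (MSR + (k - 1) * MSW)
  icc21 <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  icc31 <- (MSR - MSE) / (MSR + (k - 1) * MSE)
  icc1k <- (MSR - MSW) / MSR
  icc2k <- (MSR - MSE) / (MSR + (MSC - MSE) / n)
  icc3k <- (MSR - MSE) / MSR
  est <- c("ICC(1,1)" = icc11, "ICC(2,1)" = icc21, "ICC(3,1)" = icc31,
           "ICC(1,k)" = icc1k, "ICC(2,k)" = icc2k, "ICC(3,k)" = icc3k)

  ## F tests
  F1 <- MSR / MSW; df1 <- c(n - 1, n * (k - 1))
  F3 <- MSR / MSE; df3 <- c(n - 1, (n - 1) * (k - 1))
  p1 <- pf(F1, df1[1], df1[2], lower.tail = FALSE)
  p3 <- pf(F3, df3[1], df3[2], lower.tail = FALSE)

  sb <- function(x) k * x / (1 + (k - 1) * x)   # Spearman-Brown step-up

  ## one-way CI
  F1L <- F1 / qf(1 - alpha / 2, df1[1], df1[2])
  F1U <- F1 * qf(1 - alpha / 2, df1[2], df1[1])
  ci11 <- c((F1L - 1) / (F1L + k - 1), (F1U - 1) / (F1U + k - 1))
  ## two-way mixed (consistency) CI
  F3L <- F3 / qf(1 - alpha / 2, df3[1], df3[2])
  F3U <- F3 * qf(1 - alpha / 2, df3[2], df3[1])
  ci31 <- c((F3L - 1) / (F3L + k - 1), (F3U - 1) / (F3U + k - 1))
  ## two-way random (agreement) CI: Satterthwaite df on the occasion term
  Fj <- MSC / MSE
  vn <- (k - 1) * (n - 1) *
    (k * icc21 * Fj + n * (1 + (k - 1) * icc21) - k * icc21)^2
  vd <- (n - 1) * k^2 * icc21^2 * Fj^2 +
    (n * (1 + (k - 1) * icc21) - k * icc21)^2
  v <- vn / vd
  FU <- qf(1 - alpha / 2, n - 1, v)
  FL <- qf(1 - alpha / 2, v, n - 1)
  lo21 <- n * (MSR - FU * MSE) /
    (FU * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  up21 <- n * (FL * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FL * MSR)
  ci <- rbind(ci11, c(lo21, up21), ci31,
              sb(ci11), c(sb(lo21), sb(up21)), sb(ci31))
  dimnames(ci) <- list(names(est), c("lower", "upper"))

  structure(list(icc = est, ms = ms,
                 fvalue = c(oneway = F1, twoway = F3),
                 df = list(oneway = df1, twoway = df3),
                 p_value = c(oneway = p1, twoway = p3),
                 ci = ci, n = n, k = k, conf_level = conf_level,
                 negative = any(est < 0)),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat("Intraclass correlations (n =", x$n, ", k =", x$k, ")\n")
  out <- cbind(estimate = round(x$icc, 4), round(x$ci, 4))
  print(out)
  cat(sprintf("F(%d, %d) = %.3f, p = %.3g\n",
              x$df$twoway[1], x$df$twoway[2],
              x$fvalue["twoway"], x$p_value["twoway"]))
  invisible(x)
}

#' Variance in predictor estimates explained by batch factors
#'
#' Fits a linear model of each estimate on the dummy-encoded batch factors
#' jointly; `r2_collective` is its coefficient of determination, per-factor
#' contributions are the marginal R-squared of each factor alone, and
#' residualized estimates are observed minus fitted.
#'
#' @param estimates numeric vector, or a `predictor_estimates` (then
#'   `predictor` selects the column).
#' @param sample_sheet data frame with the factor columns, aligned to the
#'   estimates (matched on `array_id` when present).
#' @param factors character vector of factor column names (default chip,
#'   position, plate, well).
#' @param predictor column name when `estimates` is a data frame.
#' @return a `variance_decomposition`: list with `r2_collective`,
#'   `r2_marginal`, `residualized`, `n`, `df_batch`.
#' @export
batch_variance_explained <- function(estimates, sample_sheet,
                                     factors = c("chip", "position",
                                                 "plate", "well"),
                                     predictor = NULL) {
  if (is.data.frame(estimates)) {
    stopifnot(!is.null(predictor))
    sheet <- sample_sheet[match(estimates$array_id, sample_sheet$array_id), ]
    y <- estimates[[predictor]]
  } else {
    sheet <- sample_sheet
    y <- as.numeric(estimates)
  }
  stopifnot(all(factors %in% names(sheet)), length(y) == nrow(sheet))
  fd <- as.data.frame(lapply(sheet[factors], factor))
  total_levels <- sum(vapply(fd, nlevels, 0L))
  if (length(y) <= total_levels + 1)
    stop("saturated design: ", total_levels, " factor levels for ",
         length(y), " arrays")
  fit <- lm(y ~ ., data = fd)
  r2 <- summary(fit)$r.squared
  r2m <- vapply(factors, function(f)
    summary(lm(y ~ fd[[f]]))$r.squared, numeric(1))
  structure(list(r2_collective = r2,
                 r2_marginal = setNames(r2m, factors),
                 residualized = y - fitted(fit),
                 n = length(y),
                 df_batch = fit$rank - 1L),
            class = "variance_decomposition")
}

#' Regress batch factors out of predictor estimates
#'
#' Replaces each predictor column by the residual of its batch-factor
#' regression plus the grand mean, so downstream replicate ICCs are
#' well-defined on the adjusted scale.
#'
#' @inheritParams batch_variance_explained
#' @return estimates of the same shape, batch-adjusted.
#' @export
regress_out_batch <- function(estimates, sample_sheet,
                              factors = c("chip", "position",
                                          "plate", "well")) {
  if (is.data.frame(estimates)) {
    out <- estimates
    for (col in setdiff(names(estimates), "array_id")) {
      vd <- batch_variance_explained(estimates, sample_sheet,
                                     factors = factors, predictor = col)
      out[[col]] <- vd$residualized + mean(estimates[[col]])
    }
    out
  } else {
    vd <- batch_variance_explained(estimates, sample_sheet, factors = factors)
    vd$residualized + mean(as.numeric(estimates))
  }
}

#' Concordance of subsampled ICC rankings with the full-sample ranking
#'
#' For each subsample size m, draws `n_draws` subsets of replicate pairs
#' without replacement (shared across cells), recomputes ICC(2,1) for every
#' predictor-by-pipeline cell on the subset, and reports the mean Spearman
#' correlation of the subsample ICC vector with the full-sample vector --
#' the design curve answering "how many replicate pairs are enough?".
#'
#' @param tables list of replicate tables (one per predictor x pipeline
#'   cell), all with the same pairs in the same order.
#' @param sizes integer vector of subsample sizes (each in [3, n_pairs]).
#' @param n_draws subsets per size (default 20).
#' @param seed integer seed.
#' @param type which ICC to track (default `"ICC(2,1)"`).
#' @return data frame with `size`, `concordance` (mean rho), `sd`.
#' @export
subsample_consistency <- function(tables, sizes, n_draws = 20, seed = 1L,
                                  type = "ICC(2,1)") {
  stopifnot(is.list(tables), length(tables) >= 2)
  n_pairs <- nrow(tables[[1]])
  if (any(sizes < 3) || any(sizes > n_pairs))
    stop("sizes must lie in [3, ", n_pairs, "]")
  cell_icc <- function(rows) {
    vapply(tables, function(tb) {
      tryCatch(icc(tb[rows, , drop = FALSE])$icc[[type]],
               error = function(e) NA_real_)
    }, numeric(1))
  }
  full <- cell_icc(seq_len(n_pairs))
  with_seed(stage_seed(seed, "subsample"), {
    res <- lapply(sizes, function(m) {
      rho <- vapply(seq_len(n_draws), function(d) {
        sub <- cell_icc(sample.int(n_pairs, m))
        ok <- complete.cases(sub, full)
        spearman_cor(sub[ok], full[ok])$rho
      }, numeric(1))
      data.frame(size = m, concordance = mean(rho, na.rm = TRUE),
                 sd = sd(rho))
    })
    do.call(rbind, res)
  })
}
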