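#' Distribution summary of predictor estimates
#'
#' Sample mean, SD (n-1 denominator), and coefficient of variation
#' (CV = sd/mean) per predictor column; CV is `NA` when the mean is zero.
#'
#' @param estimates a `predictor_estimates` or data frame with `array_id`
#'   plus numeric predictor columns.
#' @return data frame with `predictor`, `mean`, `sd`, `cv`.
#' @export
summarize_distribution <- function(estimates) {
  cols <- setdiff(names(estimates), "array_id")
  stopifnot(nrow(estimates) >= 2)
  res <- lapply(cols, function(col) {
    v <- estimates[[col]]
    m <- mean(v); s <- sd(v)
    data.frame(predictor = col, mean = m, sd = s,
               cv = if (m == 0) NA_real_ else s / m,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Age-acceleration residuals
#'
#' Regresses predicted (DNAm) age on chronological age by ordinary least
#' squares and returns the residuals -- the age-acceleration measure. By
#' construction the residuals are mean-zero and orthogonal to age.
#'
#' @param estimates numeric vector of predictor estimates (>= 3 values).
#' @param age chronological age in years, same length, non-constant.
#' @return numeric vector of residuals.
#' @export
age_acceleration <- function(estimates, age) {
  stopifnot(length(estimates) == length(age), length(age) >= 3)
  if (var(age) == 0) stop("age is constant; acceleration undefined")
  residuals(lm(estimates ~ age))
}

#' Cox proportional-hazards association with mortality
#'
#' Fits a Cox model of survival on the predictor, adjusted for covariates
#' (chronological age by default), with Efron handling of tied event times.
#' The hazard ratio is reported per unit of the raw predictor, or per SD
#' when `standardize = TRUE`.
#'
#' @param estimates numeric predictor vector.
#' @param survival_time follow-up times (> 0).
#' @param event 0/1 event indicator (>= 10 events required).
#' @param covariates optional data frame of adjustment covariates (e.g.
#'   `data.frame(age = ...)`).
#' @param standardize report the hazard ratio per SD of the predictor.
#' @return list of class `cox_association`: `coef`, `hr`, `hr_se` (SE of the
#'   log-HR), `z`, `cox_p`, `n`, `n_events`, `standardized`.
#' @export
cox_mortality <- function(estimates, survival_time, event,
                          covariates = NULL, standardize = FALSE) {
  stopifnot(length(estimates) == length(survival_time),
            length(event) == length(estimates))
  if (any(survival_time <= 0)) stop("survival times must be positive")
  if (sum(event) < 10)
    stop("Cox fit requires >= 10 events (found ", sum(event), ")")
  x <- if (standardize) as.numeric(scale(estimates)) else estimates
  df <- data.frame(time = survival_time, event = event, predictor = x)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  rhs <- paste(setdiff(names(df), c("time", "event")), collapse = " + ")
  fit <- tryCatch(
    survival::coxph(as.formula(paste("survival::Surv(time, event) ~", rhs)),
                    data = df, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w)))
        stop("Cox fit did not converge (possible separation): ",
             conditionMessage(w))
      suppressWarnings(
        survival::coxph(as.formula(paste("survival::Surv(time, event) ~", rhs)),
                        data = df, ties = "efron"))
    })
  s <- summary(fit)
  co <- s$coefficients["predictor", ]
  structure(list(coef = unname(co["coef"]),
                 hr = unname(co["exp(coef)"]),
                 hr_se = unname(co["se(coef)"]),
                 z = unname(co["z"]),
                 cox_p = unname(co["Pr(>|z|)"]),
                 n = s$n, n_events = s$nevent,
                 standardized = standardize),
            class = "cox_association")
}

# All permutations of 1..n (n <= 9), one per row.
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  p <- all_perms(n - 1)
  out <- matrix(0L, n * nrow(p), n)
  row <- 1L
  for (pos in seq_len(n)) {
    block <- cbind(p, n)[, append(seq_len(n - 1), n, after = pos - 1),
                         drop = FALSE]
    out[row:(row + nrow(p) - 1L), ] <- block
    row <- row + nrow(p)
  }
  out
}

#' Spearman rank correlation with exact small-sample p-values
#'
#' Rank correlation using average ranks on ties. The p-value uses the
#' t-approximation for n >= 10 and the exact permutation distribution
#' (all n! permutations, two-sided) for 4 <= n < 10.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @return list with `rho`, `p`, `n`, and `undefined` (TRUE when either
#'   vector has zero rank variance, in which case `rho` is `NA`).
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("spearman_cor needs >= 4 complete observations")
  rx <- rank(x); ry <- rank(y)
  if (var(rx) == 0 || var(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, undefined = TRUE))
  rho <- cor(rx, ry)
  if (n >= 10) {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  } else {
    perms <- all_perms(n)
    rho_perm <- apply(perms, 1, function(pm) cor(rx, ry[pm]))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  }
  list(rho = rho, p = min(p, 1), n = n, undefined = FALSE)
}

#' Correlate pipeline ICC with a downstream statistic
#'
#' The paper-style diagnostic: across pipelines, does higher replicate
#' consistency go with a stronger (or weaker) downstream statistic? Both
#' vectors must be ordered by the same pipelines.
#'
#' @param icc_by_pipeline numeric vector of ICCs over pipelines.
#' @param statistic_by_pipeline the statistic over the same pipelines.
#' @param statistic label recording which statistic was correlated.
#' @return list with `statistic`, `rho`, `p`, `n`, `undefined`.
#' @export
icc_statistic_correlation <- function(icc_by_pipeline, statistic_by_pipeline,
                                      statistic = "statistic") {
  stopifnot(length(icc_by_pipeline) == length(statistic_by_pipeline))
  sc <- spearman_cor(icc_by_pipeline, statistic_by_pipeline)
  c(list(statistic = statistic), sc)
}

#' Rank pipelines by predictor consistency
#'
#' Within each predictor, pipelines are ranked by descending ICC (rank 1 =
#' most consistent; average ranks on ties; degenerate `NA` cells rank
#' last). Reports the rank matrix, each pipeline's median rank across
#' predictors, and each predictor's best pipeline plus median/min/max ICC.
#'
#' @param icc_matrix numeric matrix predictors x pipelines (dimnames used
#'   in the report).
#' @return a `pipeline_ranking`: list with `ranks`, `median_rank` (per
#'   pipeline), `best` (per predictor: pipeline label, its ICC, and the
#'   predictor's median/min/max ICC).
#' @export
rank_pipelines <- function(icc_matrix) {
  stopifnot(is.matrix(icc_matrix), length(icc_matrix) > 0)
  P <- ncol(icc_matrix)
  ranks <- icc_matrix
  for (i in seq_len(nrow(icc_matrix))) {
    r <- rank(-icc_matrix[i, ], ties.method = "average", na.last = "keep")
    if (anyNA(r)) r[is.na(r)] <- max(r, 0, na.rm = TRUE) +
        (sum(is.na(r)) + 1) / 2    # degenerate cells share the last ranks
    ranks[i, ] <- r
  }
  best_idx <- apply(icc_matrix, 1, which.max)
  best <- data.frame(
    predictor = rownames(icc_matrix) %||% as.character(seq_len(nrow(icc_matrix))),
    best_pipeline = colnames(icc_matrix)[best_idx] %||% as.character(best_idx),
    best_icc = icc_matrix[cbind(seq_len(nrow(icc_matrix)), best_idx)],
    median_icc = apply(icc_matrix, 1, median, na.rm = TRUE),
    min_icc = apply(icc_matrix, 1, min, na.rm = TRUE),
    max_icc = apply(icc_matrix, 1, max, na.rm = TRUE),
    stringsAsFactors = FALSE
  )
  rownames(best) <- NULL
  structure(list(ranks = ranks,
                 median_rank = apply(ranks, 2, median),
                 best = best),
            class = "pipeline_ranking")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
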