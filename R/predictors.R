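#' Construct a weighted-CpG predictor model
#'
#' A DNAm predictor is a linear combination of CpG beta values: raw score
#' `s = intercept + sum_j w_j beta_j`, optionally passed through an output
#' transform. The `"horvath_age"` transform applies [horvath_inverse()] to
#' express clock output in years.
#'
#' @param name predictor name.
#' @param intercept intercept of the linear combination.
#' @param weights named numeric vector, names = probe IDs.
#' @param transform `"identity"` or `"horvath_age"`.
#' @param adult_age knot (years) of the piecewise age calibration; > 0.
#' @param missing_policy `"mean_impute"` (default; a model probe missing from
#'   the beta matrix is filled with the across-array mean of available
#'   arrays... see [apply_predictor()]) or `"error"`.
#' @return an object of class `predictor_model`.
#' @export
predictor_model <- function(name, intercept, weights,
                            transform = c("identity", "horvath_age"),
                            adult_age = 20,
                            missing_policy = c("mean_impute", "error")) {
  transform <- match.arg(transform)
  missing_policy <- match.arg(missing_policy)
  if (length(weights) < 1 || is.null(names(weights)))
    stop("weights must be a non-empty named vector")
  if (adult_age <= 0) stop("adult_age must be positive")
  structure(list(name = name, intercept = as.numeric(intercept),
                 weights = weights, transform = transform,
                 adult_age = adult_age, missing_policy = missing_policy),
            class = "predictor_model")
}

#' @export
print.predictor_model <- function(x, ...) {
  cat("<predictor_model> ", x$name, ": ", length(x$weights),
      " CpG weights, transform = ", x$transform, "\n", sep = "")
  invisible(x)
}

#' Forward age calibration of the epigenetic-clock convention
#'
#' Maps chronological age to the log-linear training scale used by classical
#' epigenetic clocks: logarithmic below the adult-age knot, linear above it;
#' `F(age) = log(age + 1) - log(adult_age + 1)` for `age <= adult_age`, and
#' `(age - adult_age) / (adult_age + 1)` otherwise.
#'
#' @param age age in years (vectorized).
#' @param adult_age knot in years (default 20).
#' @return calibrated value(s).
#' @seealso [horvath_inverse()], its exact inverse.
#' @export
horvath_forward <- function(age, adult_age = 20) {
  ifelse(age <= adult_age,
         log(age + 1) - log(adult_age + 1),
         (age - adult_age) / (adult_age + 1))
}

#' Inverse age calibration (clock output to years)
#'
#' Exact inverse of [horvath_forward()]: for scores `s <= 0` (ages at or
#' below the knot) `(1 + adult_age) * exp(s) - 1`; for `s > 0`
#' `(1 + adult_age) * s + adult_age`. Continuous and strictly increasing in
#' `s`; both branches give `adult_age` at `s = 0`.
#'
#' @param s calibrated clock score (vectorized).
#' @param adult_age knot in years (default 20).
#' @return age in years.
#' @export
horvath_inverse <- function(s, adult_age = 20) {
  ifelse(s <= 0,
         (1 + adult_age) * exp(s) - 1,
         (1 + adult_age) * s + adult_age)
}

#' Apply predictor models to a beta matrix
#'
#' Computes one estimate per array per predictor. Model probes missing from
#' the beta matrix are handled per the model's `missing_policy`:
#' `"mean_impute"` fills NA cells of a present probe with its across-array
#' mean over available arrays, and fills a fully absent probe with the grand
#' mean beta of the matrix (logged via `message()`); `"error"` lists the
#' absent probe IDs.
#'
#' @param beta a `beta_matrix` (see [compute_beta()]) or plain numeric
#'   matrix probes x arrays.
#' @param models a single `predictor_model` or (named) list of them.
#' @return a `predictor_estimates` object: data frame with `array_id` and
#'   one column per predictor; attribute `pipeline` carries provenance.
#' @export
apply_predictor <- function(beta, models) {
  values <- if (inherits(beta, "beta_matrix")) beta$values else beta
  stopifnot(is.matrix(values), !is.null(rownames(values)))
  if (inherits(models, "predictor_model")) models <- list(models)
  if (is.null(names(models)))
    names(models) <- vapply(models, `[[`, "", "name")
  grand_mean <- mean(values, na.rm = TRUE)
  est <- lapply(models, function(m) {
    ids <- names(m$weights)
    present <- ids %in% rownames(values)
    if (!all(present) && m$missing_policy == "error")
      stop("predictor '", m$name, "': missing probes: ",
           paste(ids[!present], collapse = ", "))
    B <- matrix(grand_mean, length(ids), ncol(values),
                dimnames = list(ids, colnames(values)))
    B[ids[present], ] <- values[ids[present], , drop = FALSE]
    n_imputed <- sum(!present)
    if (anyNA(B)) {
      na_cells <- is.na(B)
      if (m$missing_policy == "error")
        stop("predictor '", m$name, "': NA beta cells for probes: ",
             paste(unique(rownames(B)[which(na_cells, arr.ind = TRUE)[, 1]]),
                   collapse = ", "))
      rm_ <- rowMeans(B, na.rm = TRUE)
      rm_[is.nan(rm_)] <- grand_mean
      B[na_cells] <- rm_[which(na_cells, arr.ind = TRUE)[, 1]]
      n_imputed <- n_imputed + sum(na_cells)
    }
    if (n_imputed > 0)
      message("predictor '", m$name, "': mean-imputed ", n_imputed,
              " missing probe value(s)")
    s <- drop(m$intercept + crossprod(B, m$weights))
    out <- switch(m$transform,
                  identity = s,
                  horvath_age = horvath_inverse(s, m$adult_age))
    if (any(!is.finite(out)))
      stop("predictor '", m$name, "' produced non-finite estimates")
    out
  })
  out <- data.frame(array_id = colnames(values), est,
                    check.names = FALSE, stringsAsFactors = FALSE)
  attr(out, "pipeline") <- if (inherits(beta, "beta_matrix")) beta$pipeline
                           else NA_character_
  class(out) <- c("predictor_estimates", "data.frame")
  out
}

#' Write a predictor model to CSV
#'
#' Format: a comment header block (`# name=`, `# transform=`,
#' `# intercept=`, `# adult_age=`) followed by `probe_id,weight` rows.
#'
#' @param model a `predictor_model`.
#' @param path output file path.
#' @return `path` invisibly.
#' @export
write_predictor_model <- function(model, path) {
  stopifnot(inherits(model, "predictor_model"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# name=", model$name),
               paste0("# transform=", model$transform),
               paste0("# intercept=",
                      format(model$intercept, digits = 17)),
               paste0("# adult_age=", format(model$adult_age, digits = 17)),
               "probe_id,weight"), con)
  writeLines(paste(names(model$weights),
                   format(model$weights, digits = 17, trim = TRUE),
                   sep = ","), con)
  invisible(path)
}

#' Read a predictor model from CSV
#'
#' Strict parser for the format written by [write_predictor_model()];
#' malformed lines are reported with their line number.
#'
#' @param path file path.
#' @return a `predictor_model`.
#' @export
read_predictor_model <- function(path) {
  lines <- readLines(path)
  meta <- list(adult_age = 20, transform = "identity")
  i <- 1L
  while (i <= length(lines) && startsWith(lines[i], "#")) {
    kv <- sub("^#\\s*", "", lines[i])
    pos <- regexpr("=", kv, fixed = TRUE)
    if (pos < 0) stop("line ", i, ": malformed metadata line: ", lines[i])
    meta[[substr(kv, 1, pos - 1)]] <- substr(kv, pos + 1, nchar(kv))
    i <- i + 1L
  }
  if (i > length(lines) || lines[i] != "probe_id,weight")
    stop("line ", i, ": expected header 'probe_id,weight'")
  body <- lines[-seq_len(i)]
  body <- body[nzchar(body)]
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0)
    stop("line ", i + bad[1], ": expected 'probe_id,weight', got: ",
         body[bad[1]])
  w <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(w))
    stop("line ", i + which(is.na(w))[1], ": non-numeric weight")
  if (is.null(meta$name)) stop("missing '# name=' metadata")
  if (is.null(meta$intercept)) stop("missing '# intercept=' metadata")
  predictor_model(name = meta$name,
                  intercept = as.numeric(meta$intercept),
                  weights = setNames(w, vapply(parts, `[[`, "", 1L)),
                  transform = meta$transform,
                  adult_age = as.numeric(meta$adult_age))
}
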