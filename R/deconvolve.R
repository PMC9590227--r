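#' Reference-based cell-fraction deconvolution
#'
#' Estimates the mixing fractions of reference cell types in each array by
#' constrained projection: per array, the observed betas over the reference
#' probes are regressed on the reference profiles under non-negativity
#' (NNLS). Fractions above 1 or summing above 1 are rescaled onto the
#' simplex boundary; with `renormalize = TRUE` fractions always sum to 1.
#'
#' @param beta a `beta_matrix` or probes x arrays matrix containing (at
#'   least) the reference probes.
#' @param reference probes x cell-types matrix of reference betas (>= 2
#'   cell types, rownames = probe IDs).
#' @param renormalize force fractions to sum to 1 (default FALSE).
#' @param condition_threshold warn when the reference condition number
#'   exceeds this (default 1e8).
#' @return list with `fractions` (arrays x cell types) and `residual_norm`
#'   per array.
#' @export
deconvolve_cell_fractions <- function(beta, reference, renormalize = FALSE,
                                      condition_threshold = 1e8) {
  values <- if (inherits(beta, "beta_matrix")) beta$values else beta
  stopifnot(is.matrix(reference), ncol(reference) >= 2,
            !is.null(rownames(reference)))
  missing <- setdiff(rownames(reference), rownames(values))
  if (length(missing) > 0)
    stop("reference probes absent from beta matrix: ",
         paste(head(missing, 5), collapse = ", "))
  kap <- kappa(reference, exact = TRUE)
  if (kap > condition_threshold)
    warning("reference profiles are near-collinear (condition number ",
            format(kap, digits = 3), ")")
  Y <- values[rownames(reference), , drop = FALSE]
  frac <- matrix(NA_real_, ncol(Y), ncol(reference),
                 dimnames = list(colnames(Y), colnames(reference)))
  rn <- numeric(ncol(Y))
  for (a in seq_len(ncol(Y))) {
    fit <- pracma::lsqnonneg(reference, Y[, a])
    f <- fit$x
    f <- pmin(f, 1)
    if (!renormalize && sum(f) > 1) f <- f / sum(f)
    if (renormalize && sum(f) > 0) f <- f / sum(f)
    frac[a, ] <- f
    rn[a] <- sqrt(sum((Y[, a] - reference %*% fit$x)^2))
  }
  list(fractions = frac, residual_norm = setNames(rn, colnames(Y)))
}
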