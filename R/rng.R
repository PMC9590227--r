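#' Derive a deterministic sub-stream seed for a named stage
#'
#' Every stochastic stage of the framework draws from its own sub-stream so
#' that changing, say, the number of predictors does not perturb the
#' intensities. Sub-stream seeds are derived from the dataset seed and a
#' stage label by a small multiplicative hash kept inside 32-bit integer
#' range.
#'
#' @param seed integer master seed.
#' @param stage character stage label.
#' @return an integer seed.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 131 + code) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 7919 + h) %% 2147483647)
}

# Evaluate `expr` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Truncated-normal draws on [0, Inf) via inverse-CDF; exact, not rejection,
# so the stream advances by exactly n uniforms.
rtnorm_pos <- function(n, mean, sd) {
  if (sd <= 0) return(pmax(rep(mean, length.out = n), 0) + 0 * runif(n))
  lo <- pnorm(0, mean = mean, sd = sd)
  qnorm(runif(n, min = lo, max = 1), mean = mean, sd = sd)
}

logit <- function(p, eps = 1e-6) {
  p <- pmin(pmax(p, eps), 1 - eps)
  log(p / (1 - p))
}

inv_logit <- function(x) 1 / (1 + exp(-x))
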