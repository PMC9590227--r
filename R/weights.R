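#' Build synthetic predictor coefficient tables from ground truth
#'
#' Constructs named linear predictors (intercept + CpG weights) against the
#' simulated truth, mimicking published weighted-CpG predictors without
#' redistributing any. For `target = "age"` or `"latent_score"` the weights
#' are the minimum-norm least-squares fit of the (possibly transform-scaled)
#' target on the true betas of a random probe subset, so the predictor is
#' exact on noise-free data. For `target = "random"` weights are drawn
#' i.i.d. normal. When `transform = "horvath_age"` the fit is done on the
#' forward-calibrated age scale (see [horvath_forward()]), so applying the
#' model and back-transforming recovers age.
#'
#' @param manifest an `array_manifest`.
#' @param truth a `ground_truth` built from it.
#' @param configs list of configs, each a list with `name`, `n_probes`,
#'   `target` (one of `"age"`, `"latent_score"`, `"random"`) and optional
#'   `transform` (`"identity"` default, or `"horvath_age"`).
#' @param seed integer seed.
#' @return a named list of [predictor_model()] objects.
#' @export
make_weight_tables <- function(manifest, truth, configs, seed = 1L) {
  stopifnot(inherits(manifest, "array_manifest"),
            inherits(truth, "ground_truth"))
  probes <- cpg_ids(manifest)
  B <- truth$true_beta
  with_seed(stage_seed(seed, "weights"), {
    models <- lapply(configs, function(cf) {
      stopifnot(!is.null(cf$name), !is.null(cf$n_probes), !is.null(cf$target))
      transform <- if (is.null(cf$transform)) "identity" else cf$transform
      if (cf$n_probes > length(probes))
        stop("config '", cf$name, "' requests ", cf$n_probes,
             " probes but the manifest has only ", length(probes))
      sel <- sort(sample.int(length(probes), cf$n_probes))
      ids <- probes[sel]
      if (cf$target == "random") {
        w <- rnorm(cf$n_probes)
        icpt <- rnorm(1)
      } else {
        y <- switch(cf$target,
                    age = truth$age,
                    latent_score = truth$latent_aging_score,
                    stop("unknown target '", cf$target, "'"))
        if (transform == "horvath_age") {
          adult_age <- if (is.null(cf$adult_age)) 20 else cf$adult_age
          y <- horvath_forward(y, adult_age = adult_age)
        }
        X <- cbind(1, B[, ids, drop = FALSE])
        ## min-norm LS: exact interpolation whenever n_probes >= n_subjects
        co <- drop(MASS::ginv(X) %*% y)
        icpt <- co[1]
        w <- co[-1]
      }
      predictor_model(name = cf$name, intercept = icpt,
                      weights = setNames(w, ids),
                      transform = transform,
                      adult_age = if (is.null(cf$adult_age)) 20 else cf$adult_age)
    })
    names(models) <- vapply(configs, `[[`, "", "name")
    models
  })
}
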