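#' Define one preprocessing pipeline
#'
#' A pipeline is an ordered choice of background correction, dye-bias
#' correction, quantile normalization, and probe-type calibration. The label
#' uniquely encodes the four choices; the all-`"none"` spec is the raw
#' pipeline.
#'
#' @param bg `"none"`, `"oob"`, or `"neg"`.
#' @param dye `"none"`, `"mean"`, or `"relic"`.
#' @param norm `"none"`, `"q1"`, `"q2"`, or `"q3"`.
#' @param probe `"none"` or `"rcp"`.
#' @return an object of class `pipeline_spec` with a `label` field like
#'   `"bg=oob,dye=relic,norm=q1,probe=rcp"`.
#' @export
pipeline_spec <- function(bg = c("none", "oob", "neg"),
                          dye = c("none", "mean", "relic"),
                          norm = c("none", "q1", "q2", "q3"),
                          probe = c("none", "rcp")) {
  bg <- match.arg(bg); dye <- match.arg(dye)
  norm <- match.arg(norm); probe <- match.arg(probe)
  structure(list(bg = bg, dye = dye, norm = norm, probe = probe,
                 label = sprintf("bg=%s,dye=%s,norm=%s,probe=%s",
                                 bg, dye, norm, probe)),
            class = "pipeline_spec")
}

#' @export
print.pipeline_spec <- function(x, ...) {
  cat("<pipeline_spec>", x$label, "\n")
  invisible(x)
}

#' Run one preprocessing pipeline end to end
#'
#' Applies, in order: background correction, dye-bias correction, quantile
#' normalization (all on intensities), beta computation, then probe-type
#' calibration on betas. `"none"` stages are skipped; the all-none spec
#' returns raw betas.
#'
#' @param ds an `intensity_dataset`.
#' @param spec a `pipeline_spec`.
#' @param manifest the matching `array_manifest`.
#' @param offset beta-value offset (default 100).
#' @return a `beta_matrix` whose `pipeline` field is the spec label.
#' @export
run_pipeline <- function(ds, spec, manifest, offset = 100) {
  stopifnot(inherits(spec, "pipeline_spec"))
  if (spec$bg != "none") ds <- background_correct(ds, spec$bg, manifest)
  if (spec$dye != "none") ds <- dye_correct(ds, spec$dye, manifest)
  if (spec$norm != "none") ds <- quantile_normalize(ds, spec$norm, manifest)
  beta <- compute_beta(ds, offset = offset, manifest = manifest,
                       pipeline = spec$label)
  if (spec$probe == "rcp") beta <- rcp_correct(beta, manifest)
  beta
}

#' Enumerate a pipeline grid
#'
#' Cartesian product of the per-stage choice lists, plus the raw
#' (all-`"none"`) spec, deduplicated by label, in deterministic order.
#'
#' @param bg,dye,norm,probe character vectors of stage choices.
#' @return a named list of `pipeline_spec`s (names = labels).
#' @export
enumerate_grid <- function(bg = c("none", "oob", "neg"),
                           dye = c("none", "mean", "relic"),
                           norm = c("none", "q1", "q2", "q3"),
                           probe = c("none", "rcp")) {
  if (any(lengths(list(bg, dye, norm, probe)) == 0))
    stop("every axis needs at least one level")
  g <- expand.grid(probe = probe, norm = norm, dye = dye, bg = bg,
                   stringsAsFactors = FALSE)
  g <- g[, c("bg", "dye", "norm", "probe")]
  specs <- c(list(pipeline_spec()),
             lapply(seq_len(nrow(g)), function(i)
               pipeline_spec(g$bg[i], g$dye[i], g$norm[i], g$probe[i])))
  labels <- vapply(specs, `[[`, "", "label")
  specs <- specs[!duplicated(labels)]
  names(specs) <- vapply(specs, `[[`, "", "label")
  specs
}
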