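#' Background correction from out-of-band or negative-control signal
#'
#' Estimates the per-array, per-channel additive background mean from the
#' designated source and subtracts it from every in-band intensity, flooring
#' at 1 intensity unit. `"oob"` uses out-of-band reads of type-I probes
#' (a red-channel type-I probe's unused read samples the green background and
#' vice versa); `"neg"` uses negative-control probes (green read in `meth`,
#' red read in `unmeth`).
#'
#' @param ds an `intensity_dataset`.
#' @param method `"oob"` or `"neg"`.
#' @param manifest the matching `array_manifest`.
#' @param floor minimum intensity after subtraction (default 1).
#' @return the corrected `intensity_dataset`.
#' @export
background_correct <- function(ds, method = c("oob", "neg"), manifest,
                               floor = 1) {
  method <- match.arg(method)
  stopifnot(inherits(ds, "intensity_dataset"),
            inherits(manifest, "array_manifest"))
  if (method == "oob") {
    if (is.null(ds$oob)) stop("oob correction requires out-of-band draws")
    t1 <- which(manifest$design_type == "I")
    ch <- manifest$channel[t1]
    if (!any(ch == "red") || !any(ch == "green"))
      stop("oob correction requires type-I probes in both channels")
    ## oob of a red probe samples green background and vice versa
    bg_green <- colMeans(ds$oob[ch == "red", , drop = FALSE])
    bg_red <- colMeans(ds$oob[ch == "green", , drop = FALSE])
  } else {
    neg <- which(manifest$is_negative_control)
    if (length(neg) == 0) stop("neg correction requires negative controls")
    bg_green <- colMeans(ds$meth[neg, , drop = FALSE])
    bg_red <- colMeans(ds$unmeth[neg, , drop = FALSE])
  }
  sub_ch <- function(x, bg) pmax(sweep(x, 2, bg, "-"), floor)

  t2 <- which(manifest$design_type == "II")
  if (length(t2) > 0) {
    ds$meth[t2, ] <- sub_ch(ds$meth[t2, , drop = FALSE], bg_green)
    ds$unmeth[t2, ] <- sub_ch(ds$unmeth[t2, , drop = FALSE], bg_red)
  }
  for (ch in c("red", "green")) {
    bg <- if (ch == "red") bg_red else bg_green
    t1c <- which(manifest$design_type == "I" & manifest$channel == ch)
    if (length(t1c) > 0) {
      ds$meth[t1c, ] <- sub_ch(ds$meth[t1c, , drop = FALSE], bg)
      ds$unmeth[t1c, ] <- sub_ch(ds$unmeth[t1c, , drop = FALSE], bg)
    }
    ctl <- which(!is.na(manifest$control_pair_id) & manifest$channel == ch)
    if (length(ctl) > 0)
      ds$meth[ctl, ] <- sub_ch(ds$meth[ctl, , drop = FALSE], bg)
  }
  neg <- which(manifest$is_negative_control)
  if (length(neg) > 0) {
    ds$meth[neg, ] <- sub_ch(ds$meth[neg, , drop = FALSE], bg_green)
    ds$unmeth[neg, ] <- sub_ch(ds$unmeth[neg, , drop = FALSE], bg_red)
  }
  ds
}

# Row/column bookkeeping of red-channel measurements: list of (matrix-name,
# row-index) pairs the dye kernels must transform.
red_measurements <- function(manifest) {
  t2 <- which(manifest$design_type == "II")
  t1r <- which(manifest$design_type == "I" & manifest$channel == "red")
  ctl_r <- which(!is.na(manifest$control_pair_id) & manifest$channel == "red")
  neg <- which(manifest$is_negative_control)
  list(meth = c(t1r, ctl_r),
       unmeth = c(t2, t1r, neg))
}

#' Dye-bias correction from same-target control pairs
#'
#' Each control pair measures one target in both color channels, so the
#' red/green imbalance of an array is identifiable. `"mean"` rescales all
#' red-channel measurements so the per-array mean red control intensity
#' equals the mean green control intensity. `"relic"` fits a per-array
#' linear regression of log green-control on log red-control intensity
#' across pairs and maps every red-channel measurement through the fitted
#' line (handles intensity-dependent imbalance).
#'
#' @param ds an `intensity_dataset`.
#' @param method `"mean"` or `"relic"`.
#' @param manifest the matching `array_manifest`; `"relic"` requires >= 10
#'   control pairs.
#' @return the corrected `intensity_dataset`.
#' @export
dye_correct <- function(ds, method = c("mean", "relic"), manifest) {
  method <- match.arg(method)
  stopifnot(inherits(ds, "intensity_dataset"),
            inherits(manifest, "array_manifest"))
  ctl <- which(!is.na(manifest$control_pair_id))
  if (length(ctl) == 0) stop("dye correction requires control pairs")
  ids <- manifest$control_pair_id[ctl]
  red_rows <- ctl[manifest$channel[ctl] == "red"]
  grn_rows <- ctl[manifest$channel[ctl] == "green"]
  ## align pairs
  ord <- match(manifest$control_pair_id[red_rows],
               manifest$control_pair_id[grn_rows])
  grn_rows <- grn_rows[ord]
  n_pairs <- length(red_rows)
  if (method == "relic" && n_pairs < 10)
    stop("relic requires >= 10 control pairs (found ", n_pairs, ")")

  R <- ds$meth[red_rows, , drop = FALSE]
  G <- ds$meth[grn_rows, , drop = FALSE]
  if (any(apply(R, 2, sd) == 0) || any(apply(G, 2, sd) == 0))
    stop("degenerate control intensities: zero variance within an array")

  tgt <- red_measurements(manifest)
  if (method == "mean") {
    f <- colMeans(G) / colMeans(R)
    ds$meth[tgt$meth, ] <- sweep(ds$meth[tgt$meth, , drop = FALSE], 2, f, "*")
    ds$unmeth[tgt$unmeth, ] <- sweep(ds$unmeth[tgt$unmeth, , drop = FALSE],
                                     2, f, "*")
  } else {
    eps <- 1e-8
    for (a in seq_len(ncol(R))) {
      x <- log(pmax(R[, a], eps))
      y <- log(pmax(G[, a], eps))
      fit <- lm(y ~ x)
      map <- function(v) exp(coef(fit)[1] + coef(fit)[2] * log(pmax(v, eps)))
      ds$meth[tgt$meth, a] <- map(ds$meth[tgt$meth, a])
      ds$unmeth[tgt$unmeth, a] <- map(ds$unmeth[tgt$unmeth, a])
    }
  }
  ds
}

#' Stratified quantile normalization of intensities
#'
#' Forces identical intensity distributions across arrays within each
#' stratum (reference distribution = mean of sorted columns; ties get
#' average values). Strata: `"q1"` = the four cells {meth, unmeth} x
#' {type I, type II}; `"q2"` = {meth, unmeth} pooling probe types;
#' `"q3"` = one pooled normalization of all CpG intensities.
#'
#' @param ds an `intensity_dataset`.
#' @param method `"q1"`, `"q2"`, or `"q3"`.
#' @param manifest the matching `array_manifest`.
#' @return the normalized `intensity_dataset` (control and negative-control
#'   rows untouched).
#' @export
quantile_normalize <- function(ds, method = c("q1", "q2", "q3"), manifest) {
  method <- match.arg(method)
  stopifnot(inherits(ds, "intensity_dataset"),
            inherits(manifest, "array_manifest"))
  if (ncol(ds$meth) < 2) {
    warning("quantile normalization needs >= 2 arrays; returning input")
    return(ds)
  }
  qn <- function(x) limma::normalizeQuantiles(x, ties = TRUE)
  t1 <- which(manifest$design_type == "I")
  t2 <- which(manifest$design_type == "II")
  cpg <- c(t1, t2)
  if (method == "q1") {
    for (rows in list(t1, t2)) {
      if (length(rows) < 2) next
      ds$meth[rows, ] <- qn(ds$meth[rows, , drop = FALSE])
      ds$unmeth[rows, ] <- qn(ds$unmeth[rows, , drop = FALSE])
    }
  } else if (method == "q2") {
    ds$meth[cpg, ] <- qn(ds$meth[cpg, , drop = FALSE])
    ds$unmeth[cpg, ] <- qn(ds$unmeth[cpg, , drop = FALSE])
  } else {
    stacked <- rbind(ds$meth[cpg, , drop = FALSE],
                     ds$unmeth[cpg, , drop = FALSE])
    stacked <- qn(stacked)
    n <- length(cpg)
    ds$meth[cpg, ] <- stacked[seq_len(n), , drop = FALSE]
    ds$unmeth[cpg, ] <- stacked[n + seq_len(n), , drop = FALSE]
  }
  ds
}

#' Compute beta values from intensities
#'
#' The platform-standard ratio `beta = meth / (meth + unmeth + offset)` over
#' CpG probes, bounded in `[0, 1)` for non-negative intensities; the offset
#' (default 100) stabilizes low-intensity probes.
#'
#' @param ds an `intensity_dataset`.
#' @param offset non-negative stabilizing constant (default 100).
#' @param manifest optional `array_manifest` restricting rows to CpG probes;
#'   without it all rows with non-missing `unmeth` are used.
#' @param pipeline provenance label stored on the result.
#' @return a `beta_matrix`: list with `values` (probes x arrays in [0,1]),
#'   `pipeline`, and `offset`.
#' @export
compute_beta <- function(ds, offset = 100, manifest = NULL,
                         pipeline = NA_character_) {
  stopifnot(inherits(ds, "intensity_dataset"), offset >= 0)
  rows <- if (is.null(manifest)) which(rowSums(is.na(ds$unmeth)) == 0)
          else cpg_index(manifest)
  m <- ds$meth[rows, , drop = FALSE]
  u <- ds$unmeth[rows, , drop = FALSE]
  if (any(m < 0, na.rm = TRUE) || any(u < 0, na.rm = TRUE))
    stop("negative intensities; background-correct or floor first")
  denom <- m + u + offset
  values <- m / denom
  values[denom == 0] <- 0    # empty-signal convention at offset 0
  structure(list(values = values, pipeline = pipeline, offset = offset),
            class = "beta_matrix")
}

#' Probe-type calibration via neighbor pairs
#'
#' Type-II probes show a compressed beta distribution relative to type-I
#' probes. Using genomically adjacent type-I/type-II pairs that share the
#' same true methylation level, a per-array robust linear regression of
#' type-I beta on type-II beta is fitted (iteratively reweighted least
#' squares with a bisquare weight, max 50 iterations) and applied to all
#' type-II betas, clipping results to [0, 1]. The beta scale is used
#' because type-II compression is linear there, making the calibration map
#' exactly invertible on noise-free pairs.
#'
#' @param beta a `beta_matrix`.
#' @param manifest the matching `array_manifest` with >= 10 neighbor pairs.
#' @return the corrected `beta_matrix`.
#' @export
rcp_correct <- function(beta, manifest) {
  stopifnot(inherits(beta, "beta_matrix"),
            inherits(manifest, "array_manifest"))
  pairs <- manifest[!is.na(manifest$neighbor_pair_id), ]
  ids <- unique(pairs$neighbor_pair_id)
  if (length(ids) < 10)
    stop("rcp correction requires >= 10 neighbor pairs (found ",
         length(ids), ")")
  p1 <- pairs$probe_id[pairs$design_type == "I"][
    match(ids, pairs$neighbor_pair_id[pairs$design_type == "I"])]
  p2 <- pairs$probe_id[pairs$design_type == "II"][
    match(ids, pairs$neighbor_pair_id[pairs$design_type == "II"])]
  t2_all <- manifest$probe_id[which(manifest$design_type == "II")]
  t2_all <- intersect(t2_all, rownames(beta$values))

  V <- beta$values
  clipped <- 0L
  for (a in seq_len(ncol(V))) {
    x <- V[p2, a]
    y <- V[p1, a]
    fit <- tryCatch(
      suppressWarnings(MASS::rlm(y ~ x, psi = MASS::psi.bisquare,
                                 maxit = 50, acc = 1e-8)),
      error = function(e) lm(y ~ x))
    z <- coef(fit)[1] + coef(fit)[2] * V[t2_all, a]
    clipped <- clipped + sum(z < 0 | z > 1)
    V[t2_all, a] <- pmin(pmax(z, 0), 1)
  }
  beta$values <- V
  attr(beta, "n_clipped") <- clipped
  beta
}
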