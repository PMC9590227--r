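#' Detection p-values against the negative-control background law
#'
#' For each CpG probe and array, the detection p-value is the one-sided
#' upper-tail probability of the observed total intensity (meth + unmeth)
#' under a normal approximation to the per-array, per-channel background law
#' estimated from negative controls. A type-II probe's total combines one
#' green and one red read (background mean `mu_g + mu_r`, variance
#' `sd_g^2 + sd_r^2`); a type-I probe's total combines two reads in its own
#' channel (mean `2 mu_c`, variance `2 sd_c^2`).
#'
#' @param ds an `intensity_dataset`.
#' @param manifest the matching `array_manifest` with >= 20 negative
#'   controls.
#' @return matrix CpG probes x arrays of p-values.
#' @export
detection_pvalues <- function(ds, manifest) {
  stopifnot(inherits(ds, "intensity_dataset"),
            inherits(manifest, "array_manifest"))
  neg <- which(manifest$is_negative_control)
  if (length(neg) < 20)
    stop("detection p-values require >= 20 negative controls (found ",
         length(neg), ")")
  ## negative controls: meth = green read, unmeth = red read
  mu_g <- colMeans(ds$meth[neg, , drop = FALSE])
  sd_g <- apply(ds$meth[neg, , drop = FALSE], 2, sd)
  mu_r <- colMeans(ds$unmeth[neg, , drop = FALSE])
  sd_r <- apply(ds$unmeth[neg, , drop = FALSE], 2, sd)

  cpg <- cpg_index(manifest)
  total <- ds$meth[cpg, , drop = FALSE] + ds$unmeth[cpg, , drop = FALSE]
  design <- manifest$design_type[cpg]
  channel <- manifest$channel[cpg]

  n_arrays <- ncol(total)
  mu <- matrix(NA_real_, length(cpg), n_arrays)
  sg <- matrix(NA_real_, length(cpg), n_arrays)
  is2 <- design == "II"
  mu[is2, ] <- rep(mu_g + mu_r, each = sum(is2))
  sg[is2, ] <- rep(sqrt(sd_g^2 + sd_r^2), each = sum(is2))
  for (ch in c("red", "green")) {
    i <- design == "I" & channel == ch
    if (!any(i)) next
    mu_c <- if (ch == "red") mu_r else mu_g
    sd_c <- if (ch == "red") sd_r else sd_g
    mu[i, ] <- rep(2 * mu_c, each = sum(i))
    sg[i, ] <- rep(sqrt(2) * sd_c, each = sum(i))
  }
  p <- pnorm(total, mean = mu, sd = sg, lower.tail = FALSE)
  dimnames(p) <- dimnames(total)
  p
}

#' Sample quality control
#'
#' Excludes an array when (a) more than `fail_frac` of its CpG probes have a
#' detection p-value above `fail_p`, or (b) its chipwide median (log2)
#' methylated or unmethylated intensity falls below
#' `median - k * MAD` of the array medians (low-intensity outliers).
#'
#' @param ds an `intensity_dataset`.
#' @param pvals detection p-value matrix from [detection_pvalues()].
#' @param fail_p per-probe detection threshold (default 0.05).
#' @param fail_frac maximum tolerated failing fraction (default 0.05).
#' @param median_outlier_rule list with elements `k` (MAD multiplier,
#'   default 3) and `log2` (apply log2 before the cutline, default TRUE).
#' @param manifest optional `array_manifest`; when given, medians are
#'   computed over CpG probes only.
#' @return a `qc_report`: data frame per array with `array_id`,
#'   `fail_fraction`, `median_meth`, `median_unmeth`, `excluded`, `reason`.
#' @export
sample_qc <- function(ds, pvals, fail_p = 0.05, fail_frac = 0.05,
                      median_outlier_rule = list(k = 3, log2 = TRUE),
                      manifest = NULL) {
  stopifnot(inherits(ds, "intensity_dataset"))
  if (ncol(pvals) != ncol(ds$meth))
    stop("pvals do not conform to the dataset (", ncol(pvals), " vs ",
         ncol(ds$meth), " arrays)")
  k <- if (is.null(median_outlier_rule$k)) 3 else median_outlier_rule$k
  use_log2 <- !isFALSE(median_outlier_rule$log2)

  rows <- if (is.null(manifest)) seq_len(nrow(ds$meth)) else cpg_index(manifest)
  frac <- colMeans(pvals > fail_p)
  med_m <- apply(ds$meth[rows, , drop = FALSE], 2, median, na.rm = TRUE)
  med_u <- apply(ds$unmeth[rows, , drop = FALSE], 2, median, na.rm = TRUE)
  tm <- if (use_log2) log2(pmax(med_m, 1)) else med_m
  tu <- if (use_log2) log2(pmax(med_u, 1)) else med_u
  cut_m <- median(tm) - k * mad(tm)
  cut_u <- median(tu) - k * mad(tu)
  low <- tm < cut_m | tu < cut_u
  det <- frac > fail_frac

  reason <- rep(NA_character_, ncol(ds$meth))
  reason[low] <- "intensity"
  reason[det] <- ifelse(low[det], "detection;intensity", "detection")
  report <- data.frame(
    array_id = colnames(ds$meth),
    fail_fraction = frac,
    median_meth = med_m,
    median_unmeth = med_u,
    excluded = det | low,
    reason = reason,
    stringsAsFactors = FALSE
  )
  rownames(report) <- NULL
  class(report) <- c("qc_report", "data.frame")
  attr(report, "cutlines") <- c(meth = cut_m, unmeth = cut_u)
  report
}

#' Drop excluded arrays from an intensity dataset
#'
#' @param ds an `intensity_dataset`.
#' @param report a `qc_report` from [sample_qc()].
#' @return the dataset restricted to retained arrays.
#' @export
apply_qc <- function(ds, report) {
  keep <- !report$excluded[match(colnames(ds$meth), report$array_id)]
  ds$meth <- ds$meth[, keep, drop = FALSE]
  ds$unmeth <- ds$unmeth[, keep, drop = FALSE]
  if (!is.null(ds$oob)) ds$oob <- ds$oob[, keep, drop = FALSE]
  ds$sample_sheet <- ds$sample_sheet[keep, , drop = FALSE]
  ds
}
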