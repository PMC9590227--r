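#' Generate a scaled-down Infinium-style probe manifest
#'
#' Builds a probe catalog mimicking the structure of an Infinium methylation
#' array at configurable size: CpG probes of design type I (both alleles read
#' in a single color channel) or type II (methylated read in green,
#' unmethylated in red), genomically adjacent type-I/type-II neighbor pairs
#' assumed to share the same true methylation level (the anchor for
#' probe-type calibration), same-target control-probe pairs measured once in
#' each channel (the anchor for dye-bias correction), and negative-control
#' probes carrying no methylation signal (the anchor for background
#' estimation and detection p-values).
#'
#' @param n_probes number of CpG probes (>= 100).
#' @param type2_fraction fraction of CpG probes with type II design
#'   (default 0.84, the approximate type-II share on modern arrays).
#' @param n_neighbor_pairs number of type-I/type-II neighbor pairs.
#' @param n_control_pairs number of same-target control pairs (default 85).
#' @param n_negative_controls number of negative-control probes.
#' @param seed integer seed; the manifest is deterministic given the seed.
#'
#' @return An object of class `array_manifest`: a data frame with columns
#'   `probe_id`, `design_type` ("I", "II", or NA for non-CpG controls),
#'   `channel` ("red", "green", "both"), `neighbor_pair_id`,
#'   `control_pair_id`, `is_negative_control`.
#' @export
generate_manifest <- function(n_probes,
                              type2_fraction = 0.84,
                              n_neighbor_pairs = 0,
                              n_control_pairs = 85,
                              n_negative_controls = 100,
                              seed = 1L) {
  stopifnot(n_probes >= 100, type2_fraction >= 0, type2_fraction <= 1,
            n_neighbor_pairs >= 0, n_control_pairs >= 0,
            n_negative_controls >= 0)
  n2 <- round(n_probes * type2_fraction)
  n1 <- n_probes - n2
  if (n_neighbor_pairs > min(n1, n2)) {
    stop("n_neighbor_pairs (", n_neighbor_pairs,
         ") exceeds available probes of one design type (type I: ", n1,
         ", type II: ", n2, ")")
  }
  with_seed(stage_seed(seed, "manifest"), {
    design <- sample(rep(c("I", "II"), c(n1, n2)))
    channel <- ifelse(design == "II", "both",
                      sample(c("red", "green"), n_probes, replace = TRUE))
    cpg <- data.frame(
      probe_id = sprintf("cg%07d", seq_len(n_probes)),
      design_type = design,
      channel = channel,
      neighbor_pair_id = NA_character_,
      control_pair_id = NA_character_,
      is_negative_control = FALSE,
      stringsAsFactors = FALSE
    )
    if (n_neighbor_pairs > 0) {
      i1 <- sample(which(design == "I"), n_neighbor_pairs)
      i2 <- sample(which(design == "II"), n_neighbor_pairs)
      ids <- sprintf("np%05d", seq_len(n_neighbor_pairs))
      cpg$neighbor_pair_id[i1] <- ids
      cpg$neighbor_pair_id[i2] <- ids
    }
    ctl <- if (n_control_pairs > 0) {
      ids <- sprintf("ctl%04d", seq_len(n_control_pairs))
      data.frame(
        probe_id = c(paste0(ids, "_red"), paste0(ids, "_grn")),
        design_type = NA_character_,
        channel = rep(c("red", "green"), each = n_control_pairs),
        neighbor_pair_id = NA_character_,
        control_pair_id = rep(ids, 2L),
        is_negative_control = FALSE,
        stringsAsFactors = FALSE
      )
    }
    neg <- if (n_negative_controls > 0) {
      data.frame(
        probe_id = sprintf("neg%05d", seq_len(n_negative_controls)),
        design_type = NA_character_,
        channel = "both",
        neighbor_pair_id = NA_character_,
        control_pair_id = NA_character_,
        is_negative_control = TRUE,
        stringsAsFactors = FALSE
      )
    }
    manifest <- rbind(cpg, ctl, neg)
    rownames(manifest) <- manifest$probe_id
    class(manifest) <- c("array_manifest", "data.frame")
    attr(manifest, "seed") <- seed
    manifest
  })
}

# Row indices of CpG probes (the methylation-bearing subset).
cpg_index <- function(manifest) {
  which(!is.na(manifest$design_type))
}

cpg_ids <- function(manifest) {
  manifest$probe_id[cpg_index(manifest)]
}

#' Validate the structural invariants of an array manifest
#'
#' Checks that every neighbor pair links exactly one type-I and one type-II
#' probe, that every control pair has exactly one red and one green entry,
#' and that negative controls carry no design type.
#'
#' @param manifest an `array_manifest`.
#' @return `TRUE` invisibly; stops with a message on violation.
#' @export
validate_manifest <- function(manifest) {
  stopifnot(inherits(manifest, "array_manifest"))
  np <- split(manifest$design_type, manifest$neighbor_pair_id)
  ok <- vapply(np, function(d) length(d) == 2L && setequal(d, c("I", "II")),
               logical(1))
  if (!all(ok)) stop("neighbor pairs must link one type-I and one type-II probe")
  cp <- split(manifest$channel, manifest$control_pair_id)
  ok <- vapply(cp, function(ch) length(ch) == 2L &&
                 setequal(ch, c("red", "green")), logical(1))
  if (!all(ok)) stop("control pairs must have exactly one entry per channel")
  if (any(manifest$is_negative_control & !is.na(manifest$design_type)))
    stop("negative controls must not carry a design type")
  invisible(TRUE)
}
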