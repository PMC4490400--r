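# Allele-specific copy-number aberration and LOH classification with
# ploidy-relative thresholds; focal-event listing; arm-level recurrence.

ABERRATION_CATEGORIES <- c("neutral", "gain", "loss", "high_amplification",
                           "homozygous_deletion")

#' Classify one segment against the sample's ploidy
#'
#' Empirical ploidy-relative thresholds: homozygous deletion, total copy
#' number = 0; high-level amplification, CN > ploidy + 2; gain,
#' CN >= ploidy + 1; loss, CN <= ploidy - 1; otherwise neutral. The printed
#' rules overlap (CN = 0 also satisfies the loss rule; CN > ploidy + 2 also
#' satisfies gain), so classification applies the precedence
#' homozygous_deletion > high_amplification > gain/loss > neutral. LOH is
#' flagged independently whenever the minor-allele copy number is 0.
#' Copy numbers are compared as real values; no rounding.
#'
#' @param total_cn,minor_cn segment copy numbers (vectorised)
#' @param ploidy sample ploidy (scalar or vector)
#' @return data.frame with columns category, loh
#' @export
classify_cn <- function(total_cn, minor_cn, ploidy) {
  stopifnot(all(ploidy > 0), all(minor_cn <= total_cn))
  category <- rep("neutral", length(total_cn))
  category[total_cn <= ploidy - 1] <- "loss"
  category[total_cn >= ploidy + 1] <- "gain"
  category[total_cn > ploidy + 2] <- "high_amplification"
  category[total_cn == 0] <- "homozygous_deletion"
  data.frame(category = category, loh = minor_cn == 0)
}

#' Classify a single segment
#'
#' @param seg one-row segment data.frame or list with total_cn, minor_cn
#' @param ploidy the sample's ploidy
#' @return list with elements `category` and `loh`
#' @export
classify_segment <- function(seg, ploidy) {
  res <- classify_cn(seg$total_cn, seg$minor_cn, ploidy)
  list(category = res$category[1], loh = res$loh[1])
}

#' Classify a segment table for one sample
#'
#' @param segments data.frame of segments (see [read_seg()])
#' @param ploidy the sample's ploidy
#' @return the segment data.frame with appended `category` and `loh` columns
#' @export
classify_segments <- function(segments, ploidy) {
  cbind(segments, classify_cn(segments$total_cn, segments$minor_cn, ploidy))
}

#' Classify all segments of a cohort
#'
#' @param segments cohort segment data.frame
#' @param ploidy per-sample ploidy data.frame (sample_id, ploidy)
#' @return classified segment data.frame
#' @export
classify_cohort <- function(segments, ploidy) {
  pl <- ploidy$ploidy[match(segments$sample_id, ploidy$sample_id)]
  if (anyNA(pl)) {
    stop("ploidy missing for sample ",
         segments$sample_id[which(is.na(pl))[1]], call. = FALSE)
  }
  cbind(segments, classify_cn(segments$total_cn, segments$minor_cn, pl))
}

#' List focal events: homozygous deletions and high-level amplifications
#'
#' Retains only the two focal categories supported by at least `min_probes`
#' consecutive array probes (default 5), sorted by sample then coordinate.
#' This deterministic minimum-probe filter replaces any manual curation.
#'
#' @param calls classified segment data.frame ([classify_segments()])
#' @param min_probes minimum probe support, default 5
#' @return subset of `calls`
#' @export
list_focal_events <- function(calls, min_probes = 5) {
  keep <- calls$category %in% c("homozygous_deletion", "high_amplification") &
    calls$n_probes >= min_probes
  out <- calls[keep, , drop = FALSE]
  out <- out[order(out$sample_id, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Fraction of one arm covered by calls in the given categories for one sample.
arm_covered_fraction <- function(calls, arm_row, categories) {
  seg <- calls[calls$chrom == arm_row$chrom &
                 calls$category %in% categories, , drop = FALSE]
  if (nrow(seg) == 0) return(0)
  s <- pmax(seg$start, arm_row$start)
  e <- pmin(seg$end, arm_row$end)
  keep <- s <= e
  sum((e - s + 1)[keep]) / (arm_row$end - arm_row$start + 1)
}

#' Arm-level recurrence of losses and gains across a cohort
#'
#' A sample counts as having lost (gained) an arm when loss-classified
#' (gain/amplification-classified) segments cover at least
#' `arm_fraction` of the arm's length; lengths are 1-based inclusive
#' (end - start + 1).
#'
#' @param calls classified cohort segment data.frame ([classify_cohort()])
#' @param samples cohort sample roster (denominator of the fractions)
#' @param arm_table arm coordinate table ([read_arm_table()])
#' @param arms arm names to summarise (e.g. c("4p","9p")); default all arms
#'   in `arm_table`
#' @param arm_fraction coverage threshold, default 0.9
#' @return data.frame: arm, n_lost, n_gained, fraction_lost, fraction_gained
#' @export
arm_recurrence <- function(calls, samples, arm_table = read_arm_table(),
                           arms = NULL, arm_fraction = 0.9) {
  stopifnot(length(samples) >= 1)
  if (is.null(arms)) arms <- arm_table$arm_name
  missing <- setdiff(arms, arm_table$arm_name)
  if (length(missing) > 0) {
    stop("arm(s) absent from arm table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(arms, function(an) {
    row <- arm_table[arm_table$arm_name == an, ][1, ]
    lost <- gained <- 0
    for (s in samples) {
      mine <- calls[calls$sample_id == s, , drop = FALSE]
      if (arm_covered_fraction(mine, row,
                               c("loss", "homozygous_deletion")) >=
          arm_fraction) lost <- lost + 1
      if (arm_covered_fraction(mine, row,
                               c("gain", "high_amplification")) >=
          arm_fraction) gained <- gained + 1
    }
    data.frame(arm = an, n_lost = lost, n_gained = gained,
               fraction_lost = lost / length(samples),
               fraction_gained = gained / length(samples),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
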