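# Molecular subtype assignment: IDH hotspot status, 1p/19q co-deletion from
# allele-specific copy number, TERT promoter annotation.

TERT_C228T_POS <- 1295228
TERT_C250T_POS <- 1295250

#' Call IDH-mutant status for one sample
#'
#' A sample is IDH-mutant iff it carries an IDH1 mutation at codon R132 or an
#' IDH2 mutation at codon R172; any other IDH1/IDH2 variant (e.g. IDH2 P162S)
#' does not qualify. Records on IDH1/IDH2 without an annotated protein change
#' are treated as non-qualifying with a message.
#'
#' @param muts data.frame of mutation records for a single sample
#' @return logical flag
#' @export
call_idh_status <- function(muts) {
  if (nrow(muts) == 0) return(FALSE)
  idh <- muts[muts$gene %in% c("IDH1", "IDH2"), , drop = FALSE]
  if (nrow(idh) == 0) return(FALSE)
  pc <- idh$protein_change
  blank <- is.na(pc) | !nzchar(pc)
  if (any(blank)) {
    message(sum(blank), " IDH1/IDH2 record(s) without protein_change ",
            "treated as non-qualifying")
  }
  pc[blank] <- ""
  hot <- (idh$gene == "IDH1" & startsWith(pc, "R132")) |
         (idh$gene == "IDH2" & startsWith(pc, "R172"))
  any(hot)
}

# Fraction of an arm covered by segments classified as 'loss' at the sample's
# ploidy; returns NA when no segment touches the arm.
arm_loss_fraction <- function(segments, ploidy, arm_row) {
  seg <- segments[segments$chrom == arm_row$chrom, , drop = FALSE]
  if (nrow(seg) == 0) return(NA_real_)
  s <- pmax(seg$start, arm_row$start)
  e <- pmin(seg$end, arm_row$end)
  keep <- s <= e
  if (!any(keep)) return(NA_real_)
  seg <- seg[keep, , drop = FALSE]
  cat_ <- classify_segments(seg, ploidy)$category
  lost <- cat_ %in% c("loss", "homozygous_deletion")
  arm_len <- arm_row$end - arm_row$start + 1
  sum((e[keep] - s[keep] + 1)[lost]) / arm_len
}

#' Call 1p/19q co-deletion for one sample
#'
#' TRUE iff loss-classified segments (ploidy-relative rules, see
#' [classify_segment()]) cover at least `arm_fraction` of BOTH the 1p and the
#' 19q arm. Missing coverage of either arm yields a warning and a FALSE
#' (unknown propagated as non-codel).
#'
#' @param segments allele-specific copy-number segments for one sample
#' @param ploidy the sample's ploidy
#' @param arm_table arm coordinate table ([read_arm_table()])
#' @param arm_fraction minimum lost fraction of each arm, default 0.9
#' @return logical flag
#' @export
call_1p19q_codel <- function(segments, ploidy,
                             arm_table = read_arm_table(),
                             arm_fraction = 0.9) {
  fr <- vapply(c("1p", "19q"), function(an) {
    row <- arm_table[arm_table$arm_name == an, , drop = FALSE]
    if (nrow(row) != 1) stop("arm ", an, " absent from arm table",
                             call. = FALSE)
    arm_loss_fraction(segments, ploidy, row[1, ])
  }, numeric(1))
  if (anyNA(fr)) {
    warning("no copy-number coverage of ",
            paste(names(fr)[is.na(fr)], collapse = " and "),
            "; 1p/19q status unknown, reported non-codel", call. = FALSE)
    return(FALSE)
  }
  all(fr >= arm_fraction)
}

#' Call TERT promoter mutation status
#'
#' Classifies promoter assay variants at the two recurrent hg19 hotspot
#' positions on chromosome 5: 1,295,228 (C228T) and 1,295,250 (C250T), both
#' described as G>A on the assayed strand. A variant at a hotspot with other
#' alleles raises a warning and does not produce a call. An empty assay table
#' returns "unknown"; an assayed sample with no hotspot variant is "wildtype".
#'
#' @param variants data.frame with columns chrom, pos, ref, alt; may have zero
#'   rows (assay performed, nothing found) — pass NULL for "no assay"
#' @return one of "C228T", "C250T", "wildtype", "unknown"
#' @export
call_tert_promoter <- function(variants) {
  if (is.null(variants)) return("unknown")
  if (nrow(variants) == 0) return("wildtype")
  hit <- variants[variants$pos %in% c(TERT_C228T_POS, TERT_C250T_POS), ,
                  drop = FALSE]
  if (nrow(hit) == 0) return("wildtype")
  ok <- hit$ref == "G" & hit$alt == "A"
  if (any(!ok)) {
    warning("variant at TERT hotspot position with alleles ",
            hit$ref[!ok][1], ">", hit$alt[!ok][1],
            " (expected G>A); not called", call. = FALSE)
    hit <- hit[ok, , drop = FALSE]
    if (nrow(hit) == 0) return("wildtype")
  }
  if (any(hit$pos == TERT_C228T_POS)) "C228T" else "C250T"
}

#' Assign the three-way molecular subtype
#'
#' The conventional partition: IDH-mutant 1p/19q co-deleted (IDHmut_codel),
#' IDH-mutant non-co-deleted (IDHmut_noncodel), and IDH wild-type (IDHwt).
#' IDH status takes precedence: an IDH-wild-type sample is IDHwt regardless of
#' co-deletion.
#'
#' @param idh logical IDH-mutant flag
#' @param codel logical 1p/19q co-deletion flag
#' @return one of "IDHmut_codel", "IDHmut_noncodel", "IDHwt"
#' @export
assign_subtype <- function(idh, codel) {
  stopifnot(is.logical(idh), is.logical(codel),
            length(idh) == 1, length(codel) == 1, !is.na(idh), !is.na(codel))
  if (!idh) return("IDHwt")
  if (codel) "IDHmut_codel" else "IDHmut_noncodel"
}

#' Assign subtypes across a cohort
#'
#' Convenience wrapper running [call_idh_status()], [call_1p19q_codel()] and
#' [assign_subtype()] per sample, with optional TERT promoter annotation.
#'
#' @param table a `cohort_mutation_table`
#' @param segments cohort segment data.frame ([read_seg()])
#' @param ploidy per-sample ploidy data.frame
#' @param arm_table arm coordinate table
#' @param tert_variants optional named list: sample_id -> promoter variant
#'   data.frame (NULL entries mean no assay)
#' @param arm_fraction arm-loss fraction threshold, default 0.9
#' @return data.frame: sample_id, idh_mutant, codel_1p19q, subtype,
#'   tert_promoter
#' @export
assign_subtypes <- function(table, segments, ploidy,
                            arm_table = read_arm_table(),
                            tert_variants = NULL, arm_fraction = 0.9) {
  stopifnot(inherits(table, "cohort_mutation_table"))
  res <- lapply(table$samples, function(s) {
    idh <- call_idh_status(
      table$records[table$records$sample_id == s, , drop = FALSE])
    seg_s <- segments[segments$sample_id == s, , drop = FALSE]
    pl <- ploidy$ploidy[match(s, ploidy$sample_id)]
    codel <- if (nrow(seg_s) == 0 || is.na(pl)) {
      warning("no copy-number profile for sample ", s,
              "; reported non-codel", call. = FALSE)
      FALSE
    } else {
      call_1p19q_codel(seg_s, pl, arm_table, arm_fraction)
    }
    tert <- call_tert_promoter(
      if (is.null(tert_variants)) NULL else tert_variants[[s]])
    data.frame(sample_id = s, idh_mutant = idh, codel_1p19q = codel,
               subtype = assign_subtype(idh, codel), tert_promoter = tert,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
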