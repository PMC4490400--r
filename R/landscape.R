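# Per-sample mutation burden, collapsed substitution spectrum, and
# exclusivity-ordered (memo-sort) oncoprint layout.

#' Per-sample mutation burden and rate per megabase
#'
#' Rates count ALL somatic mutations by default (the cohort-level
#' mutations-per-Mb convention); set `nonsilent_only = TRUE` to rate only
#' non-silent classes. Samples exceeding 3x the cohort median rate are flagged
#' as hypermutators in a message (flag only, never excluded).
#'
#' @param table a `cohort_mutation_table`
#' @param target_mb sequenced target footprint in Mb: a single number applied
#'   to every sample, or a named vector keyed by sample_id
#' @param nonsilent_only rate non-silent mutations instead of all
#' @return data.frame: sample_id, n_total, n_nonsilent, target_mb,
#'   rate_per_mb, hypermutator
#' @export
compute_burden <- function(table, target_mb, nonsilent_only = FALSE) {
  stopifnot(inherits(table, "cohort_mutation_table"))
  if (any(target_mb <= 0)) stop("target_mb must be positive", call. = FALSE)
  rec <- table$records
  n_total <- vapply(table$samples,
                    function(s) sum(rec$sample_id == s), numeric(1))
  n_nonsil <- vapply(table$samples, function(s) {
    sum(rec$sample_id == s & rec$variant_class %in% NONSILENT_CLASSES)
  }, numeric(1))
  mb <- if (length(target_mb) == 1 && is.null(names(target_mb))) {
    rep(target_mb, length(table$samples))
  } else {
    out <- unname(target_mb[table$samples])
    if (anyNA(out)) stop("target_mb missing for some samples", call. = FALSE)
    out
  }
  rated <- if (nonsilent_only) n_nonsil else n_total
  rate <- rated / mb
  hyper <- rate > 3 * stats::median(rate)
  if (any(hyper)) {
    message("hypermutator flag (> 3x median rate): ",
            paste(table$samples[hyper], collapse = ", "))
  }
  message(sprintf("cohort mutation rate per Mb: mean %.3f, median %.3f",
                  mean(rate), stats::median(rate)))
  data.frame(sample_id = table$samples, n_total = n_total,
             n_nonsilent = n_nonsil, target_mb = mb, rate_per_mb = rate,
             hypermutator = hyper, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Collapse a substitution to one of the six pyrimidine-reference classes
#'
#' Single-base substitutions with a purine reference (A or G) are
#' reverse-complemented so the reference base is a pyrimidine, yielding the
#' six classes C>A, C>G, C>T, T>A, T>C, T>G. Non-ACGT or multi-base alleles
#' return NA (indel/other, excluded from the spectrum).
#'
#' @param ref,alt allele strings (vectorised)
#' @return character vector of classes, NA for non-SNVs
#' @export
collapse_substitution <- function(ref, alt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  snv <- ref %in% names(comp) & alt %in% names(comp) & ref != alt
  out <- rep(NA_character_, length(ref))
  if (any(snv)) {
    r <- ref[snv]; a <- alt[snv]
    pur <- r %in% c("A", "G")
    r[pur] <- comp[ref[snv][pur]]
    a[pur] <- comp[alt[snv][pur]]
    out[snv] <- paste0(r, ">", a)
  }
  out
}

#' Per-sample collapsed substitution spectrum
#'
#' @param table a `cohort_mutation_table`
#' @return data.frame: sample_id, one count column per collapsed class,
#'   indel_count (records not classifiable as single-base substitutions)
#' @export
mutation_spectrum <- function(table) {
  stopifnot(inherits(table, "cohort_mutation_table"))
  rec <- table$records
  cls <- collapse_substitution(rec$ref, rec$alt)
  rows <- lapply(table$samples, function(s) {
    mine <- cls[rec$sample_id == s]
    counts <- vapply(SUBSTITUTION_CLASSES,
                     function(k) sum(mine == k, na.rm = TRUE), numeric(1))
    cbind(data.frame(sample_id = s, stringsAsFactors = FALSE),
          as.data.frame(as.list(counts), check.names = FALSE),
          data.frame(indel_count = sum(is.na(mine))))
  })
  do.call(rbind, rows)
}

#' Order samples to emphasise mutual exclusivity (memo-sort)
#'
#' The standard oncoprint ordering: genes are ranked by descending mutation
#' frequency, and samples are sorted by the descending binary word their
#' mutation profile forms over the ranked genes, with a stable tie-break on
#' sample_id. The result is always a permutation of the input samples and is
#' invariant to the input column order.
#'
#' @param gene_by_sample binary (0/1 or logical) matrix, rows genes, columns
#'   samples, with dimnames
#' @return character vector of sample identifiers in display order
#' @export
order_for_oncoprint <- function(gene_by_sample) {
  m <- gene_by_sample
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  storage.mode(m) <- "integer"
  if (nrow(m) == 0 || ncol(m) == 0) return(colnames(m))
  gene_rank <- order(rowSums(m), rownames(m), decreasing = c(TRUE, FALSE),
                     method = "radix")
  m <- m[gene_rank, , drop = FALSE]
  keys <- c(lapply(seq_len(nrow(m)), function(i) m[i, ]),
            list(colnames(m)))
  ord <- do.call(order, c(keys, list(decreasing = c(rep(TRUE, nrow(m)), FALSE),
                                     method = "radix")))
  colnames(m)[ord]
}

#' Binary gene-by-sample mutation matrix for selected genes
#'
#' @param table a `cohort_mutation_table`
#' @param genes genes to include (rows); defaults to all mutated genes
#' @param nonsilent_only count only non-silent records (default TRUE, the
#'   oncoprint convention)
#' @return integer 0/1 matrix, rows genes, columns samples
#' @export
mutation_matrix <- function(table, genes = NULL, nonsilent_only = TRUE) {
  stopifnot(inherits(table, "cohort_mutation_table"))
  rec <- table$records
  if (nonsilent_only) {
    rec <- rec[rec$variant_class %in% NONSILENT_CLASSES, , drop = FALSE]
  }
  if (is.null(genes)) genes <- sort(unique(rec$gene))
  m <- matrix(0L, nrow = length(genes), ncol = length(table$samples),
              dimnames = list(genes, table$samples))
  rec <- rec[rec$gene %in% genes, , drop = FALSE]
  if (nrow(rec) > 0) {
    m[cbind(match(rec$gene, genes), match(rec$sample_id, table$samples))] <- 1L
  }
  m
}
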