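#' @keywords internal
"_PACKAGE"

VARIANT_CLASSES <- c("missense", "nonsense", "splice_site", "frameshift",
                     "inframe_indel", "silent", "noncoding")

NONSILENT_CLASSES <- c("missense", "nonsense", "splice_site", "frameshift",
                       "inframe_indel")

SUBSTITUTION_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Read a tab-delimited table, skipping '#'-prefixed comment lines
#'
#' All package file formats are UTF-8 TSV with a header row; lines starting
#' with '#' are ignored.
#' @param path file path
#' @param required character vector of column names that must be present
#' @return data.frame with character columns (callers coerce as needed)
#' @keywords internal
read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", quote = "")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("format error in ", path, ": missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

as_num <- function(x, what, path) {
  out <- suppressWarnings(as.numeric(x))
  if (anyNA(out) & !anyNA(x)) {
    stop("format error in ", path, ": non-numeric value in column '", what, "'",
         call. = FALSE)
  }
  out
}

#' Read a gene model table
#'
#' A gene model supplies the coding length L(g) of every sequenced gene, the
#' denominator universe of the burden test. Columns: gene, coding_length_bp,
#' chrom, arm.
#'
#' @param path TSV path
#' @return data.frame with columns gene, coding_length_bp, chrom, arm
#' @export
read_gene_model <- function(path) {
  df <- read_tsv_checked(path, c("gene", "coding_length_bp", "chrom", "arm"))
  df$coding_length_bp <- as_num(df$coding_length_bp, "coding_length_bp", path)
  validate_gene_model(df)
}

#' @keywords internal
validate_gene_model <- function(df) {
  if (anyDuplicated(df$gene)) {
    stop("validation error: duplicate gene symbols in gene model: ",
         paste(unique(df$gene[duplicated(df$gene)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(df$coding_length_bp <= 0)) {
    stop("validation error: coding_length_bp must be positive", call. = FALSE)
  }
  bad <- !df$arm %in% c("p", "q")
  if (any(bad)) {
    stop("validation error: arm must be 'p' or 'q' (gene ",
         df$gene[which(bad)[1]], ")", call. = FALSE)
  }
  df
}

#' Construct a cohort mutation table
#'
#' Bundles somatic mutation records with the sequenced-gene universe G and
#' the sample roster S. The total mutation count A(G,S) used by the burden
#' test is the number of records whose gene lies in the universe.
#'
#' @param records data.frame of mutation records (columns sample_id, gene,
#'   chrom, pos, ref, alt, variant_class, protein_change)
#' @param gene_model gene-model data.frame (see [read_gene_model()])
#' @param samples explicit sample roster; defaults to the distinct sample_ids
#'   observed in `records`
#' @param strict if TRUE (default), records in genes absent from the model are
#'   an error; if FALSE they are dropped with a message (prevents silent
#'   denominator errors in the burden test)
#' @return object of class `cohort_mutation_table` with elements `records`,
#'   `universe`, `samples`
#' @export
cohort_mutation_table <- function(records, gene_model,
                                  samples = NULL, strict = TRUE) {
  records <- validate_mutation_records(records)
  gene_model <- validate_gene_model(gene_model)
  outside <- !(records$gene %in% gene_model$gene)
  if (any(outside)) {
    if (strict) {
      stop("validation error: ", sum(outside),
           " mutation record(s) in genes absent from the gene model (e.g. ",
           records$gene[which(outside)[1]],
           "); use strict = FALSE to drop them", call. = FALSE)
    }
    message("dropping ", sum(outside),
            " mutation record(s) in genes absent from the gene model")
    records <- records[!outside, , drop = FALSE]
  }
  if (is.null(samples)) samples <- sort(unique(records$sample_id))
  if (!all(records$sample_id %in% samples)) {
    stop("validation error: record sample_id not in the sample roster: ",
         setdiff(records$sample_id, samples)[1], call. = FALSE)
  }
  structure(list(records = records, universe = gene_model,
                 samples = samples),
            class = "cohort_mutation_table")
}

#' @keywords internal
validate_mutation_records <- function(df) {
  req <- c("sample_id", "gene", "chrom", "pos", "ref", "alt", "variant_class")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0) {
    stop("format error: missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"protein_change" %in% names(df)) df$protein_change <- NA_character_
  df$pos <- as.numeric(df$pos)
  bad <- which(!df$variant_class %in% VARIANT_CLASSES)
  if (length(bad) > 0) {
    stop("validation error on line ", bad[1], ": variant_class '",
         df$variant_class[bad[1]], "' not one of {",
         paste(VARIANT_CLASSES, collapse = ", "), "}", call. = FALSE)
  }
  if (nrow(df) > 0) {
    if (any(df$pos < 1, na.rm = TRUE)) {
      stop("validation error: pos must be >= 1", call. = FALSE)
    }
    same <- which(df$ref == df$alt)
    if (length(same) > 0) {
      stop("validation error on line ", same[1], ": ref equals alt",
           call. = FALSE)
    }
  }
  df
}

#' Read a MAF-like somatic mutation table
#'
#' Tab-delimited with header columns sample_id, gene, chrom, pos, ref, alt,
#' variant_class, protein_change. Coordinates are 1-based. variant_class must
#' be one of missense, nonsense, splice_site, frameshift, inframe_indel,
#' silent, noncoding.
#'
#' @inheritParams cohort_mutation_table
#' @param path TSV path
#' @param gene_model gene-model data.frame or path to one
#' @return a `cohort_mutation_table`
#' @export
read_mutation_table <- function(path, gene_model, samples = NULL,
                                strict = TRUE) {
  df <- read_tsv_checked(path, c("sample_id", "gene", "chrom", "pos", "ref",
                                 "alt", "variant_class"))
  df$pos <- as_num(df$pos, "pos", path)
  if (is.character(gene_model) && length(gene_model) == 1) {
    gene_model <- read_gene_model(gene_model)
  }
  cohort_mutation_table(df, gene_model, samples = samples, strict = strict)
}

#' Total cohort mutation count A(G,S)
#'
#' Number of mutation records falling in genes of the sequenced universe,
#' summed over all samples — the numerator of the cohort per-base rate.
#' @param table a `cohort_mutation_table`
#' @return integer count
#' @export
total_mutation_count <- function(table) {
  stopifnot(inherits(table, "cohort_mutation_table"))
  sum(table$records$gene %in% table$universe$gene)
}

#' @export
print.cohort_mutation_table <- function(x, ...) {
  cat("Cohort mutation table:", length(x$samples), "samples,",
      nrow(x$records), "mutation records,",
      nrow(x$universe), "genes in universe",
      sprintf("(%.1f Mb)", sum(x$universe$coding_length_bp) / 1e6), "\n")
  invisible(x)
}

#' Write a cohort mutation table back to TSV
#' @param table a `cohort_mutation_table`
#' @param path output TSV path
#' @return the path, invisibly
#' @export
write_mutation_table <- function(table, path) {
  write_tsv(table$records, path)
}

#' Read gene sets in GMT format
#'
#' Standard GMT dialect: one set per line, `name TAB description TAB member...`.
#' Descriptions are discarded; duplicate members within a line are collapsed
#' with a warning.
#'
#' @param path GMT path
#' @return named list of character vectors (gene symbols)
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("format error in ", path, " line ", i,
           ": GMT lines need name, description and >=1 member", call. = FALSE)
    }
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning("duplicate members collapsed in gene set '", fields[1], "'",
              call. = FALSE)
      members <- unique(members)
    }
    if (length(members) == 0) {
      stop("format error in ", path, " line ", i, ": empty gene set",
           call. = FALSE)
    }
    sets[[fields[1]]] <- members
  }
  sets
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors
#' @param path output path
#' @return the path, invisibly
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read segmented allele-specific copy-number profiles
#'
#' SEG-like TSV extended with a minor-allele column: sample_id, chrom, start,
#' end, n_probes, total_cn, minor_cn. Coordinates 1-based inclusive. Segments
#' are validated per sample and chromosome for non-overlap, and minor_cn may
#' not exceed total_cn.
#'
#' @param path TSV path
#' @return data.frame of segments
#' @export
read_seg <- function(path) {
  df <- read_tsv_checked(path, c("sample_id", "chrom", "start", "end",
                                 "n_probes", "total_cn", "minor_cn"))
  for (col in c("start", "end", "n_probes", "total_cn", "minor_cn")) {
    df[[col]] <- as_num(df[[col]], col, path)
  }
  validate_segments(df)
}

#' @keywords internal
validate_segments <- function(df) {
  if (nrow(df) == 0) return(df)
  if (any(df$start > df$end)) {
    stop("validation error: segment start > end", call. = FALSE)
  }
  if (any(df$n_probes < 0) || any(df$total_cn < 0) || any(df$minor_cn < 0)) {
    stop("validation error: negative probe count or copy number",
         call. = FALSE)
  }
  bad <- which(df$minor_cn > df$total_cn)
  if (length(bad) > 0) {
    stop("validation error: minor_cn > total_cn for sample ",
         df$sample_id[bad[1]], " segment ", df$chrom[bad[1]], ":",
         df$start[bad[1]], "-", df$end[bad[1]], call. = FALSE)
  }
  for (key in split(seq_len(nrow(df)),
                    paste(df$sample_id, df$chrom, sep = "\r"))) {
    if (length(key) < 2) next
    idx <- key[order(df$start[key])]
    overl <- which(df$start[idx][-1] <= df$end[idx][-length(idx)])
    if (length(overl) > 0) {
      i <- idx[overl[1]]; j <- idx[overl[1] + 1]
      stop("validation error: overlapping segments for sample ",
           df$sample_id[i], " on ", df$chrom[i], ": ",
           df$start[i], "-", df$end[i], " and ", df$start[j], "-", df$end[j],
           call. = FALSE)
    }
  }
  df
}

#' Read a per-sample ploidy table
#' @param path TSV with columns sample_id, ploidy
#' @return data.frame
#' @export
read_ploidy <- function(path) {
  df <- read_tsv_checked(path, c("sample_id", "ploidy"))
  df$ploidy <- as_num(df$ploidy, "ploidy", path)
  if (any(df$ploidy <= 0)) {
    stop("validation error: ploidy must be positive", call. = FALSE)
  }
  df
}

#' Read a log2 expression matrix (genes x samples TSV)
#'
#' First column `gene`, remaining columns one per sample; values are gene-level
#' log2 intensities. Gene and sample identifiers must be unique and all values
#' finite.
#'
#' @param path TSV path
#' @return numeric matrix, rownames genes, colnames samples
#' @export
read_expression_matrix <- function(path) {
  df <- read_tsv_checked(path, "gene")
  if (ncol(df) < 2) {
    stop("format error in ", path, ": no sample columns", call. = FALSE)
  }
  genes <- df$gene
  if (anyDuplicated(genes)) {
    stop("validation error: duplicate gene symbols in expression matrix",
         call. = FALSE)
  }
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "numeric"
  if (anyDuplicated(colnames(mat))) {
    stop("validation error: duplicate sample identifiers", call. = FALSE)
  }
  if (any(!is.finite(mat))) {
    stop("validation error: non-finite expression values", call. = FALSE)
  }
  rownames(mat) <- genes
  mat
}

#' Write a log2 expression matrix to TSV
#' @param mat numeric matrix with gene rownames and sample colnames
#' @param path output path
#' @return the path, invisibly
#' @export
write_expression_matrix <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a fusion-candidate table
#' @param path TSV with columns sample_id, gene5, gene3, spanning_reads,
#'   total_supporting_reads
#' @return data.frame
#' @export
read_fusion_table <- function(path) {
  df <- read_tsv_checked(path, c("sample_id", "gene5", "gene3",
                                 "spanning_reads", "total_supporting_reads"))
  df$spanning_reads <- as_num(df$spanning_reads, "spanning_reads", path)
  df$total_supporting_reads <-
    as_num(df$total_supporting_reads, "total_supporting_reads", path)
  bad <- which(df$spanning_reads > df$total_supporting_reads)
  if (length(bad) > 0) {
    stop("validation error: spanning_reads > total_supporting_reads for ",
         df$gene5[bad[1]], "-", df$gene3[bad[1]], call. = FALSE)
  }
  df
}

#' Read the chromosome-arm coordinate table
#'
#' TSV with columns chrom, arm, start, end (1-based inclusive). The packaged
#' default is an hg19 table with arm boundaries at centromere gap midpoints.
#'
#' @param path TSV path; default the packaged hg19 table
#' @return data.frame with an added `arm_name` column (e.g. "1p", "19q")
#' @export
read_arm_table <- function(path = system.file("extdata", "hg19_arms.tsv",
                                              package = "oligoscape")) {
  df <- read_tsv_checked(path, c("chrom", "arm", "start", "end"))
  df$start <- as_num(df$start, "start", path)
  df$end <- as_num(df$end, "end", path)
  if (any(df$start > df$end)) {
    stop("validation error: arm start > end", call. = FALSE)
  }
  df$arm_name <- paste0(sub("^chr", "", df$chrom), df$arm)
  df
}
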