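# Expression contrast between mutant and wild-type groups, hypergeometric
# gene-set over-representation, and gene-set mean-activity sample ranking.

#' Contrast configuration
#'
#' @param p_threshold raw p-value threshold, default 0.05
#' @param abs_logfc_threshold absolute log2 fold-change threshold, default 0.6
#' @param test "welch" (default, unequal variances) or "pooled"
#' @return list of class `contrast_config`
#' @export
contrast_config <- function(p_threshold = 0.05, abs_logfc_threshold = 0.6,
                            test = c("welch", "pooled")) {
  stopifnot(p_threshold > 0, abs_logfc_threshold > 0)
  structure(list(p_threshold = p_threshold,
                 abs_logfc_threshold = abs_logfc_threshold,
                 test = match.arg(test)),
            class = "contrast_config")
}

# Vectorised two-sample t-test across matrix rows.
row_t_test <- function(xa, xb, test) {
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- apply(xa, 1, stats::var); vb <- apply(xb, 1, stats::var)
  if (test == "welch") {
    se2 <- va / na + vb / nb
    stat <- (ma - mb) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    stat <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(ma))
  }
  p <- 2 * stats::pt(abs(stat), df, lower.tail = FALSE)
  list(logfc = ma - mb, stat = stat, df = df, p = p)
}

#' Differential expression between two sample groups
#'
#' Per-gene two-sample t-test on log2 intensities (Welch by default).
#' logFC = mean(group_a) - mean(group_b), so with the mutant group first a
#' negative logFC is downregulation in mutants. A gene is significant iff
#' p < `p_threshold` AND |logFC| > `abs_logfc_threshold` (both raw; BH
#' q-values are reported as an extra column, clearly not used by the rule).
#' Genes with zero variance across all samples are dropped from the tested
#' universe with a message.
#'
#' @param expr log2 expression matrix (genes x samples)
#' @param group_a,group_b disjoint sample-identifier vectors, each >= 2
#' @param cfg a [contrast_config()]
#' @return list of class `expression_contrast`: `table` (per-gene data.frame
#'   gene, logFC, statistic, df, p_value, q_value, significant), `significant`
#'   (gene vector), `universe` (tested genes), `config`
#' @export
differential_genes <- function(expr, group_a, group_b,
                               cfg = contrast_config()) {
  stopifnot(inherits(cfg, "contrast_config"))
  if (length(intersect(group_a, group_b)) > 0) {
    stop("groups must be disjoint", call. = FALSE)
  }
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  absent <- setdiff(c(group_a, group_b), colnames(expr))
  if (length(absent) > 0) {
    stop("sample(s) not in the matrix: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  sub <- expr[, c(group_a, group_b), drop = FALSE]
  zerovar <- apply(sub, 1, stats::var) == 0
  if (any(zerovar)) {
    message("dropping ", sum(zerovar), " zero-variance gene(s)")
    sub <- sub[!zerovar, , drop = FALSE]
  }
  tt <- row_t_test(sub[, group_a, drop = FALSE],
                   sub[, group_b, drop = FALSE], cfg$test)
  sig <- tt$p < cfg$p_threshold & abs(tt$logfc) > cfg$abs_logfc_threshold
  tab <- data.frame(gene = rownames(sub), logFC = tt$logfc,
                    statistic = tt$stat, df = tt$df, p_value = tt$p,
                    q_value = stats::p.adjust(tt$p, method = "BH"),
                    significant = sig, row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, significant = tab$gene[sig],
                 universe = tab$gene, config = cfg),
            class = "expression_contrast")
}

#' @export
print.expression_contrast <- function(x, ...) {
  cat(sprintf(
    "Expression contrast (%s t): %d genes tested, %d significant (p < %g & |logFC| > %g)\n",
    x$config$test, length(x$universe), length(x$significant),
    x$config$p_threshold, x$config$abs_logfc_threshold))
  invisible(x)
}

#' Hypergeometric gene-set over-representation
#'
#' Upper-tail probability of observing at least the seen overlap between the
#' differentially-expressed list and each gene set, drawing |DE| genes from
#' the universe without replacement. Sets with no members in the universe get
#' p = 1. Results sorted ascending by p-value.
#'
#' @param de_genes differentially-expressed gene vector (subset of universe)
#' @param sets named list of gene-symbol vectors
#' @param universe tested-gene universe
#' @return data.frame: set_name, n_universe, n_de, n_set_in_universe,
#'   n_overlap, p_value
#' @export
hypergeom_enrichment <- function(de_genes, sets, universe) {
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  universe <- unique(universe)
  de_genes <- unique(de_genes)
  if (!all(de_genes %in% universe)) {
    stop("de_genes must be a subset of the universe", call. = FALSE)
  }
  N <- length(universe); nde <- length(de_genes)
  rows <- lapply(names(sets), function(nm) {
    inU <- intersect(unique(sets[[nm]]), universe)
    ov <- length(intersect(inU, de_genes))
    p <- if (length(inU) == 0 || ov == 0) 1 else {
      stats::phyper(ov - 1, m = length(inU), n = N - length(inU), k = nde,
                    lower.tail = FALSE)
    }
    data.frame(set_name = nm, n_universe = N, n_de = nde,
               n_set_in_universe = length(inU), n_overlap = ov, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene-set mean activity per sample, with ranking
#'
#' For each sample, the mean log2 expression over the set members present in
#' the matrix (absent members are ignored); samples are then ranked by
#' descending activity with a stable tie-break on sample identifier order as
#' given in the matrix.
#'
#' @param expr log2 expression matrix (genes x samples)
#' @param gene_set character vector of gene symbols
#' @return data.frame in ranked order: sample_id, activity, rank
#' @export
gene_set_activity <- function(expr, gene_set) {
  members <- intersect(unique(gene_set), rownames(expr))
  if (length(members) == 0) {
    stop("no gene-set member present in the matrix", call. = FALSE)
  }
  act <- colMeans(expr[members, , drop = FALSE])
  ord <- order(-act, seq_along(act), method = "radix")
  data.frame(sample_id = colnames(expr)[ord], activity = unname(act[ord]),
             rank = seq_along(ord), stringsAsFactors = FALSE)
}
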