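# Fusion-candidate filtering: read-support thresholds plus a normal-tissue
# blacklist. A candidate survives iff spanning_reads > 2 (strict) AND
# total_supporting_reads >= 10 (inclusive) AND the gene pair is not
# blacklisted; every rejected candidate carries its first failing rule.

#' Fusion-filter configuration
#'
#' @param min_spanning_exclusive candidate passes if spanning_reads is
#'   strictly greater than this (default 2)
#' @param min_total_inclusive candidate passes if total_supporting_reads is
#'   at least this (default 10)
#' @param blacklist gene-pair blacklist from [load_blacklist()], or NULL
#' @return list of class `fusion_filter_config`
#' @export
fusion_filter_config <- function(min_spanning_exclusive = 2,
                                 min_total_inclusive = 10,
                                 blacklist = NULL) {
  stopifnot(min_spanning_exclusive >= 0, min_total_inclusive >= 0)
  structure(list(min_spanning_exclusive = min_spanning_exclusive,
                 min_total_inclusive = min_total_inclusive,
                 blacklist = blacklist),
            class = "fusion_filter_config")
}

#' Load a normal-tissue fusion blacklist
#'
#' TSV of gene pairs (columns gene5, gene3, or two unnamed columns). With
#' `orientation = "unordered"` (the conservative default) a pair blacklists
#' both orientations; with `"ordered"` only the listed 5'-3' orientation.
#'
#' @param path TSV path
#' @param orientation "unordered" or "ordered"
#' @return object of class `fusion_blacklist`
#' @export
load_blacklist <- function(path, orientation = c("unordered", "ordered")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) > 0 && identical(strsplit(lines[1], "\t")[[1]][1:2],
                                     c("gene5", "gene3"))) {
    lines <- lines[-1]
  }
  pairs <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 2 || !nzchar(f[1]) || !nzchar(f[2])) {
      stop("format error in blacklist line ", i, ": need two gene symbols",
           call. = FALSE)
    }
    f[1:2]
  })
  structure(list(pairs = pairs, orientation = orientation),
            class = "fusion_blacklist")
}

#' @keywords internal
blacklist_keys <- function(blacklist) {
  if (is.null(blacklist) || length(blacklist$pairs) == 0) return(character(0))
  keys <- vapply(blacklist$pairs, function(p) {
    if (blacklist$orientation == "unordered") {
      paste(sort(p), collapse = "\r")
    } else {
      paste(p, collapse = "\r")
    }
  }, character(1))
  unique(keys)
}

#' Is a gene pair blacklisted?
#' @param gene5,gene3 gene symbols (vectorised)
#' @param blacklist a `fusion_blacklist` or NULL
#' @return logical vector
#' @export
is_blacklisted <- function(gene5, gene3, blacklist) {
  if (is.null(blacklist)) return(rep(FALSE, length(gene5)))
  keys <- blacklist_keys(blacklist)
  q <- if (blacklist$orientation == "unordered") {
    mapply(function(a, b) paste(sort(c(a, b)), collapse = "\r"),
           gene5, gene3, USE.NAMES = FALSE)
  } else {
    paste(gene5, gene3, sep = "\r")
  }
  q %in% keys
}

#' Filter fusion candidates to high-confidence calls
#'
#' @param candidates fusion-candidate data.frame ([read_fusion_table()])
#' @param cfg a [fusion_filter_config()]
#' @return list with `retained` (surviving candidate rows) and `reasons`
#'   (all candidates with columns retained, reason; reason is the FIRST
#'   failing rule among "spanning_reads", "total_supporting_reads",
#'   "blacklist", or "pass")
#' @export
filter_fusions <- function(candidates, cfg = fusion_filter_config()) {
  stopifnot(inherits(cfg, "fusion_filter_config"))
  n <- nrow(candidates)
  reason <- rep("pass", n)
  fail_span <- candidates$spanning_reads <= cfg$min_spanning_exclusive
  fail_total <- candidates$total_supporting_reads < cfg$min_total_inclusive
  fail_black <- is_blacklisted(candidates$gene5, candidates$gene3,
                               cfg$blacklist)
  reason[fail_black] <- "blacklist"
  reason[fail_total] <- "total_supporting_reads"
  reason[fail_span] <- "spanning_reads"
  retained <- candidates[reason == "pass", , drop = FALSE]
  rownames(retained) <- NULL
  reasons <- cbind(candidates,
                   data.frame(retained = reason == "pass", reason = reason,
                              stringsAsFactors = FALSE))
  rownames(reasons) <- NULL
  list(retained = retained, reasons = reasons)
}
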