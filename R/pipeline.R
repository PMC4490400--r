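# End-to-end orchestration from a single config: subtype assignment ->
# mutation landscape -> burden scan -> copy-number calls -> fusion filter ->
# expression contrast -> cohort statistics. Stages whose inputs are absent
# are skipped (the study's own sub-analyses cover different sample subsets),
# and the run emits a manifest of outputs with content checksums so identical
# config + inputs yield identical checksums.

#' Validate a pipeline run configuration
#'
#' A config is a named list (or YAML file, see [run_pipeline()]) with elements:
#' `inputs` (paths: mutations, gene_model, gene_sets, segments, ploidy,
#' expression, fusions, blacklist, arm_table, mutant_samples), `output_dir`,
#' `seed`, and optional `thresholds` (arm_fraction, min_probes, p_threshold,
#' abs_logfc_threshold, target_mb, min_spanning_exclusive,
#' min_total_inclusive). Referenced input paths must exist.
#'
#' @param cfg named list
#' @return the validated config with threshold defaults filled in
#' @export
validate_config <- function(cfg) {
  if (is.null(cfg$output_dir)) stop("config error: output_dir is required",
                                    call. = FALSE)
  if (is.null(cfg$inputs) || !is.list(cfg$inputs)) {
    stop("config error: inputs list is required", call. = FALSE)
  }
  for (nm in names(cfg$inputs)) {
    p <- cfg$inputs[[nm]]
    if (!is.null(p) && !nm %in% "mutant_samples" && !file.exists(p)) {
      stop("config error: input '", nm, "' does not exist: ", p,
           call. = FALSE)
    }
  }
  th <- cfg$thresholds %||% list()
  defaults <- list(arm_fraction = 0.9, min_probes = 5, target_mb = NULL,
                   p_threshold = 0.05, abs_logfc_threshold = 0.6,
                   min_spanning_exclusive = 2, min_total_inclusive = 10)
  for (nm in names(defaults)) th[[nm]] <- th[[nm]] %||% defaults[[nm]]
  if (th$arm_fraction <= 0 || th$arm_fraction > 1) {
    stop("config error: arm_fraction must lie in (0, 1]", call. = FALSE)
  }
  cfg$thresholds <- th
  cfg$seed <- cfg$seed %||% 1L
  cfg
}

#' Run the full analysis pipeline
#'
#' @param cfg a config list (see [validate_config()]) or the path to a YAML
#'   file encoding one
#' @return data.frame manifest: stage, file, md5 — one row per written output
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg) && length(cfg) == 1) cfg <- yaml::read_yaml(cfg)
  cfg <- validate_config(cfg)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- cfg$inputs
  th <- cfg$thresholds
  outputs <- character(0); stages <- character(0)
  emit <- function(stage, name, df) {
    path <- file.path(cfg$output_dir, name)
    write_tsv(df, path)
    outputs <<- c(outputs, path)
    stages <<- c(stages, stage)
  }
  skip <- function(stage) message("stage skipped (missing input): ", stage)

  arm_table <- if (!is.null(inputs$arm_table)) read_arm_table(inputs$arm_table)
               else read_arm_table()

  table <- NULL
  if (!is.null(inputs$mutations) && !is.null(inputs$gene_model)) {
    table <- read_mutation_table(inputs$mutations, inputs$gene_model)
  }

  segments <- if (!is.null(inputs$segments)) read_seg(inputs$segments)
  ploidy <- if (!is.null(inputs$ploidy)) read_ploidy(inputs$ploidy)

  if (!is.null(table) && !is.null(segments) && !is.null(ploidy)) {
    sub <- suppressWarnings(
      assign_subtypes(table, segments, ploidy, arm_table,
                      arm_fraction = th$arm_fraction))
    emit("subtype", "subtypes.tsv", sub)
  } else skip("subtype")

  if (!is.null(table)) {
    target_mb <- th$target_mb %||%
      (sum(table$universe$coding_length_bp) / 1e6)
    burden <- suppressMessages(compute_burden(table, target_mb))
    emit("landscape", "sample_burden.tsv", burden)
    emit("landscape", "spectrum.tsv", mutation_spectrum(table))
    m <- mutation_matrix(table)
    freq <- rowSums(m)
    top <- names(sort(freq, decreasing = TRUE))[seq_len(min(20, nrow(m)))]
    ord <- order_for_oncoprint(m[top, , drop = FALSE])
    emit("landscape", "sample_order.tsv",
         data.frame(sample_id = ord, position = seq_along(ord)))
  } else skip("landscape")

  if (!is.null(table) && !is.null(inputs$gene_sets)) {
    sets <- read_gmt(inputs$gene_sets)
    scan <- suppressWarnings(burden_scan(table, sets))
    emit("burden", "burden_scan.tsv", as.data.frame(scan))
    emit("burden", "burden_member_tallies.tsv",
         attr(scan, "member_tallies"))
  } else skip("burden")

  if (!is.null(segments) && !is.null(ploidy)) {
    calls <- classify_cohort(segments, ploidy)
    emit("cn", "cn_calls.tsv", calls)
    emit("cn", "focal_events.tsv",
         list_focal_events(calls, min_probes = th$min_probes))
    emit("cn", "arm_recurrence.tsv",
         arm_recurrence(calls, unique(ploidy$sample_id), arm_table,
                        arm_fraction = th$arm_fraction))
  } else skip("cn")

  if (!is.null(inputs$fusions)) {
    blacklist <- if (!is.null(inputs$blacklist))
      load_blacklist(inputs$blacklist) else NULL
    fcfg <- fusion_filter_config(th$min_spanning_exclusive,
                                 th$min_total_inclusive, blacklist)
    res <- filter_fusions(read_fusion_table(inputs$fusions), fcfg)
    emit("fusion", "fusions_retained.tsv", res$retained)
    emit("fusion", "fusion_reasons.tsv", res$reasons)
  } else skip("fusion")

  if (!is.null(inputs$expression) && !is.null(inputs$mutant_samples)) {
    expr <- read_expression_matrix(inputs$expression)
    mutant <- inputs$mutant_samples
    if (is.character(mutant) && length(mutant) == 1 && file.exists(mutant)) {
      mutant <- readLines(mutant, warn = FALSE)
      mutant <- mutant[nzchar(mutant)]
    }
    wt <- setdiff(colnames(expr), mutant)
    ccfg <- contrast_config(th$p_threshold, th$abs_logfc_threshold)
    contrast <- suppressMessages(
      differential_genes(expr, mutant, wt, ccfg))
    emit("expression", "differential_genes.tsv", contrast$table)
    if (!is.null(inputs$gene_sets)) {
      sets <- read_gmt(inputs$gene_sets)
      enr <- hypergeom_enrichment(contrast$significant, sets,
                                  contrast$universe)
      emit("expression", "expression_enrichment.tsv", enr)
    }
  } else skip("expression")

  if (!is.null(table)) {
    # carrier frequency of the most frequently mutated gene, with exact CI
    m <- mutation_matrix(table)
    if (nrow(m) > 0) {
      top_gene <- names(which.max(rowSums(m)))
      est <- frequency_with_ci(sum(m[top_gene, ] > 0), ncol(m))
      emit("stats", "top_gene_frequency.tsv",
           data.frame(gene = top_gene, n_carriers = est$n_carriers,
                      n_total = est$n_total, point = est$point,
                      ci_low = est$ci_low, ci_high = est$ci_high))
    }
  } else skip("stats")

  manifest <- data.frame(stage = stages, file = outputs,
                         md5 = unname(tools::md5sum(outputs)),
                         stringsAsFactors = FALSE, row.names = NULL)
  write_tsv(manifest, file.path(cfg$output_dir, "manifest.tsv"))
  manifest
}
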