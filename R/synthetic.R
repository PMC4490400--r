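# Synthetic-cohort generators with exported ground truth.
#
# The mutation generator is the exact null of the burden test: every coding
# base mutates independently at a uniform per-sample rate, optionally
# multiplied per gene (spikes break the null for recovery tests). Defaults
# mirror a 51-sample anaplastic oligodendroglioma exome cohort over a ~50 Mb
# universe at ~1.6 mutations/Mb with a C>T-dominant spectrum.

SPECTRUM_WEIGHTS <- c("C>A" = 0.09, "C>G" = 0.09, "C>T" = 0.55,
                      "T>A" = 0.09, "T>C" = 0.09, "T>G" = 0.09)
# 37 non-silent of ~92.8 mutations per sample in the emulated cohort
NONSILENT_FRACTION_DEFAULT <- 0.4

#' Build a uniform synthetic gene model
#'
#' `n_genes` genes of equal coding length laid out across the arms of the
#' supplied arm table in proportion to arm length.
#'
#' @param n_genes number of genes
#' @param gene_length_bp coding length per gene (default 5000, giving a 50 Mb
#'   universe at 10,000 genes)
#' @param arm_table arm coordinate table
#' @return gene-model data.frame (gene, coding_length_bp, chrom, arm)
#' @export
synthetic_gene_model <- function(n_genes = 10000, gene_length_bp = 5000,
                                 arm_table = read_arm_table()) {
  lens <- arm_table$end - arm_table$start + 1
  per_arm <- pmax(1, round(n_genes * lens / sum(lens)))
  # trim/pad to exactly n_genes
  while (sum(per_arm) > n_genes) per_arm[which.max(per_arm)] <-
    per_arm[which.max(per_arm)] - 1
  while (sum(per_arm) < n_genes) per_arm[which.max(lens)] <-
    per_arm[which.max(lens)] + 1
  idx <- rep(seq_len(nrow(arm_table)), per_arm)
  data.frame(gene = sprintf("G%05d", seq_len(n_genes)),
             coding_length_bp = gene_length_bp,
             chrom = arm_table$chrom[idx],
             arm = arm_table$arm[idx],
             stringsAsFactors = FALSE)
}

# Draw ref/alt pairs from the collapsed-class mix, randomising the reported
# strand so purine-reference records exercise the collapse.
draw_substitutions <- function(n) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  cls <- sample(names(SPECTRUM_WEIGHTS), n, replace = TRUE,
                prob = SPECTRUM_WEIGHTS)
  ref <- substr(cls, 1, 1)
  alt <- substr(cls, 3, 3)
  flip <- stats::runif(n) < 0.5
  ref[flip] <- comp[substr(cls, 1, 1)][flip]
  alt[flip] <- comp[substr(cls, 3, 3)][flip]
  list(ref = ref, alt = alt)
}

draw_variant_classes <- function(n, nonsilent_fraction) {
  nonsil <- stats::runif(n) < nonsilent_fraction
  out <- character(n)
  out[nonsil] <- sample(NONSILENT_CLASSES, sum(nonsil), replace = TRUE,
                        prob = c(0.65, 0.08, 0.07, 0.15, 0.05))
  out[!nonsil] <- sample(c("silent", "noncoding"), sum(!nonsil),
                         replace = TRUE, prob = c(0.7, 0.3))
  out
}

#' Generate a synthetic somatic-mutation cohort
#'
#' Per gene g and sample s, the mutation count is Binomial(L(g),
#' base_rate * multiplier(g)) — independent per-base events, exactly the null
#' of the burden test. Substitutions follow a C>T-dominant collapsed-class mix
#' with random reporting strand; variant classes are non-silent with
#' probability `nonsilent_fraction`. Samples listed in `idh_mutant_samples`
#' additionally receive one IDH1 R132H (or IDH2 R172K) hotspot record.
#'
#' @param n_samples cohort size (default 51)
#' @param gene_model gene-model data.frame; default [synthetic_gene_model()]
#' @param base_rate per-base per-sample mutation probability (default 1.6e-6,
#'   i.e. 1.6 mutations/Mb)
#' @param spikes named numeric vector of per-gene rate multipliers
#' @param nonsilent_fraction fraction of non-silent records
#' @param idh_mutant_samples sample ids to receive an IDH hotspot mutation;
#'   requires IDH1/IDH2 in the model when non-empty
#' @param seed RNG seed (required; the generator is a pure function of its
#'   arguments and seed)
#' @return list: `table` (a `cohort_mutation_table`), `truth` (list with
#'   spiked_genes, idh_mutant_samples, seed)
#' @export
generate_mutation_cohort <- function(n_samples = 51,
                                     gene_model = synthetic_gene_model(),
                                     base_rate = 1.6e-6,
                                     spikes = NULL,
                                     nonsilent_fraction =
                                       NONSILENT_FRACTION_DEFAULT,
                                     idh_mutant_samples = NULL,
                                     seed) {
  stopifnot(base_rate > 0, nrow(gene_model) > 0)
  set.seed(seed)
  samples <- sprintf("S%03d", seq_len(n_samples))
  mult <- rep(1, nrow(gene_model))
  if (!is.null(spikes)) {
    miss <- setdiff(names(spikes), gene_model$gene)
    if (length(miss) > 0) {
      stop("spiked gene(s) absent from the model: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    mult[match(names(spikes), gene_model$gene)] <- spikes
  }
  ng <- nrow(gene_model)
  prob <- pmin(1, base_rate * mult)
  counts <- stats::rbinom(ng * n_samples,
                          size = rep(gene_model$coding_length_bp, n_samples),
                          prob = rep(prob, n_samples))
  nz <- which(counts > 0)
  gene_i <- ((nz - 1) %% ng) + 1
  samp_i <- ((nz - 1) %/% ng) + 1
  gene_idx <- rep(gene_i, counts[nz])
  samp_idx <- rep(samp_i, counts[nz])
  nrec <- length(gene_idx)
  subs <- draw_substitutions(nrec)
  rec <- data.frame(
    sample_id = samples[samp_idx],
    gene = gene_model$gene[gene_idx],
    chrom = gene_model$chrom[gene_idx],
    pos = 1 + floor(stats::runif(nrec) *
                      gene_model$coding_length_bp[gene_idx]),
    ref = subs$ref, alt = subs$alt,
    variant_class = draw_variant_classes(nrec, nonsilent_fraction),
    protein_change = NA_character_,
    stringsAsFactors = FALSE)
  if (length(idh_mutant_samples) > 0) {
    if (!all(c("IDH1", "IDH2") %in% gene_model$gene)) {
      stop("idh_mutant_samples requires IDH1 and IDH2 in the gene model",
           call. = FALSE)
    }
    use_idh2 <- stats::runif(length(idh_mutant_samples)) < 0.15
    hot <- data.frame(
      sample_id = idh_mutant_samples,
      gene = ifelse(use_idh2, "IDH2", "IDH1"),
      chrom = gene_model$chrom[match(ifelse(use_idh2, "IDH2", "IDH1"),
                                     gene_model$gene)],
      pos = ifelse(use_idh2, 515, 394),
      ref = "G", alt = "A",
      variant_class = "missense",
      protein_change = ifelse(use_idh2, "R172K", "R132H"),
      stringsAsFactors = FALSE)
    rec <- rbind(rec, hot)
  }
  table <- cohort_mutation_table(rec, gene_model, samples = samples)
  truth <- list(spiked_genes = as.list(spikes %||% stats::setNames(
    numeric(0), character(0))),
    idh_mutant_samples = idh_mutant_samples, seed = seed)
  list(table = table, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic allele-specific copy-number cohort
#'
#' Each sample draws each arm event independently at its stated frequency.
#' Entries of `arm_loss_freqs` may name a single arm ("9p") or a
#' comma-joined group lost jointly ("4p,4q" for whole chromosome 4;
#' "1p,19q" for co-deletion). Lost arms are emitted as whole-arm segments
#' with total_cn = ploidy - 1 and minor_cn = 0; other arms are neutral
#' (minor = floor(ploidy/2)). Focal homozygous deletions can be planted with
#' chosen probe counts; the surrounding arm segment is split around them.
#'
#' @param n_samples cohort size
#' @param arm_table arm coordinate table
#' @param arm_loss_freqs named numeric vector of loss frequencies in \[0,1\]
#' @param ploidy cohort ploidy (default 2)
#' @param probe_density array probes per Mb (default 300)
#' @param focal_homdels optional data.frame(sample_id, chrom, start, end,
#'   n_probes) of planted homozygous deletions
#' @param seed RNG seed
#' @return list: `segments`, `ploidy` (data.frames), `truth` (per-sample lost
#'   arm lists, planted focal events, seed)
#' @export
generate_ascn_cohort <- function(n_samples, arm_table = read_arm_table(),
                                 arm_loss_freqs = c("1p,19q" = 0.6,
                                                    "4p,4q" = 0.3,
                                                    "9p" = 0.28,
                                                    "14q" = 0.19),
                                 ploidy = 2, probe_density = 300,
                                 focal_homdels = NULL, seed) {
  stopifnot(all(arm_loss_freqs >= 0), all(arm_loss_freqs <= 1), ploidy > 0)
  groups <- strsplit(names(arm_loss_freqs), ",", fixed = TRUE)
  unknown <- setdiff(unlist(groups), arm_table$arm_name)
  if (length(unknown) > 0) {
    stop("unknown arm(s) in arm_loss_freqs: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  samples <- sprintf("S%03d", seq_len(n_samples))
  lost_arms <- stats::setNames(vector("list", n_samples), samples)
  for (i in seq_len(n_samples)) {
    hit <- stats::runif(length(groups)) < arm_loss_freqs
    lost_arms[i] <- list(as.character(unlist(groups[hit])))
  }
  seg_rows <- list()
  for (i in seq_len(n_samples)) {
    s <- samples[i]
    for (j in seq_len(nrow(arm_table))) {
      arm <- arm_table[j, ]
      lost <- arm$arm_name %in% lost_arms[[i]]
      tot <- if (lost) ploidy - 1 else ploidy
      mnr <- if (lost) 0 else floor(ploidy / 2)
      holes <- if (is.null(focal_homdels)) NULL else
        focal_homdels[focal_homdels$sample_id == s &
                        focal_homdels$chrom == arm$chrom &
                        focal_homdels$start >= arm$start &
                        focal_homdels$end <= arm$end, , drop = FALSE]
      cur <- arm$start
      if (!is.null(holes) && nrow(holes) > 0) {
        holes <- holes[order(holes$start), , drop = FALSE]
        for (h in seq_len(nrow(holes))) {
          if (holes$start[h] > cur) {
            seg_rows[[length(seg_rows) + 1]] <- data.frame(
              sample_id = s, chrom = arm$chrom, start = cur,
              end = holes$start[h] - 1,
              n_probes = round((holes$start[h] - cur) / 1e6 * probe_density),
              total_cn = tot, minor_cn = mnr, stringsAsFactors = FALSE)
          }
          seg_rows[[length(seg_rows) + 1]] <- data.frame(
            sample_id = s, chrom = arm$chrom, start = holes$start[h],
            end = holes$end[h], n_probes = holes$n_probes[h],
            total_cn = 0, minor_cn = 0, stringsAsFactors = FALSE)
          cur <- holes$end[h] + 1
        }
      }
      if (cur <= arm$end) {
        seg_rows[[length(seg_rows) + 1]] <- data.frame(
          sample_id = s, chrom = arm$chrom, start = cur, end = arm$end,
          n_probes = round((arm$end - cur + 1) / 1e6 * probe_density),
          total_cn = tot, minor_cn = mnr, stringsAsFactors = FALSE)
      }
    }
  }
  segments <- validate_segments(do.call(rbind, seg_rows))
  list(segments = segments,
       ploidy = data.frame(sample_id = samples, ploidy = ploidy,
                           stringsAsFactors = FALSE),
       truth = list(lost_arms = lost_arms,
                    arm_loss_freqs = as.list(arm_loss_freqs),
                    focal_homdels = focal_homdels, ploidy = ploidy,
                    seed = seed))
}

#' Generate a synthetic log2 expression matrix with planted gene-set shifts
#'
#' Baseline per gene ~ N(7, 1), plus per-sample Gaussian noise. Members of
#' each shifted set get the stated log2 shift added in the FIRST group
#' (the mutant group by convention).
#'
#' @param n_genes number of genes (named g00001...)
#' @param groups list of two disjoint sample-identifier vectors,
#'   mutant first
#' @param gene_sets named list of gene-symbol vectors over the synthetic genes
#' @param shifted_sets named numeric vector: set name -> log2 shift applied to
#'   the first group; every named set must exist in `gene_sets` and reference
#'   only present genes
#' @param noise_sd per-sample Gaussian noise sd in log2 units (default 0.5)
#' @param seed RNG seed
#' @return list: `expr` (matrix), `truth` (shifted_sets, groups, seed)
#' @export
generate_expression <- function(n_genes, groups, gene_sets = list(),
                                shifted_sets = NULL, noise_sd = 0.5, seed) {
  stopifnot(noise_sd > 0, length(groups) == 2,
            length(intersect(groups[[1]], groups[[2]])) == 0)
  set.seed(seed)
  genes <- sprintf("g%05d", seq_len(n_genes))
  samples <- c(groups[[1]], groups[[2]])
  base <- stats::rnorm(n_genes, mean = 7, sd = 1)
  expr <- matrix(base, nrow = n_genes, ncol = length(samples)) +
    matrix(stats::rnorm(n_genes * length(samples), 0, noise_sd),
           nrow = n_genes)
  dimnames(expr) <- list(genes, samples)
  if (!is.null(shifted_sets)) {
    for (nm in names(shifted_sets)) {
      if (!nm %in% names(gene_sets)) {
        stop("shifted set '", nm, "' not in gene_sets", call. = FALSE)
      }
      members <- gene_sets[[nm]]
      if (!all(members %in% genes)) {
        stop("shifted set '", nm, "' references absent genes", call. = FALSE)
      }
      expr[members, groups[[1]]] <- expr[members, groups[[1]]] +
        shifted_sets[[nm]]
    }
  }
  list(expr = expr,
       truth = list(shifted_sets = as.list(shifted_sets %||% list()),
                    groups = groups, seed = seed))
}

#' Generate a synthetic fusion-candidate table with decoys
#'
#' True candidates satisfy both read-support thresholds and avoid the
#' blacklist; each decoy class violates exactly its designated rule
#' (spanning <= 2 with adequate total; total < 10 with adequate spanning;
#' blacklisted pair with adequate support).
#'
#' @param n_true,n_decoys_below_spanning,n_decoys_below_total,n_blacklisted
#'   candidate counts per class
#' @param seed RNG seed
#' @return list: `candidates` (data.frame with truth labels dropped),
#'   `blacklist` (a `fusion_blacklist`), `truth` (per-row class labels, seed)
#' @export
generate_fusion_table <- function(n_true = 3, n_decoys_below_spanning = 4,
                                  n_decoys_below_total = 3,
                                  n_blacklisted = 2, seed) {
  stopifnot(n_true >= 0, n_decoys_below_spanning >= 0,
            n_decoys_below_total >= 0, n_blacklisted >= 0)
  set.seed(seed)
  mk <- function(n, prefix, spanning, total) {
    if (n == 0) return(NULL)
    data.frame(sample_id = sprintf("S%03d", sample.int(20, n, replace = TRUE)),
               gene5 = sprintf("%s5_%02d", prefix, seq_len(n)),
               gene3 = sprintf("%s3_%02d", prefix, seq_len(n)),
               spanning_reads = spanning,
               total_supporting_reads = total,
               stringsAsFactors = FALSE)
  }
  spa_t <- sample(3:20, n_true, replace = TRUE)
  true <- mk(n_true, "TRUE", spa_t, spa_t + sample(7:30, n_true, TRUE))
  ds_s <- sample(0:2, n_decoys_below_spanning, replace = TRUE)
  dspan <- mk(n_decoys_below_spanning, "DSPAN", ds_s,
              pmax(10, ds_s + sample(8:20, n_decoys_below_spanning, TRUE)))
  dt_s <- sample(3:8, n_decoys_below_total, replace = TRUE)
  dtot <- mk(n_decoys_below_total, "DTOT", dt_s,
             pmin(9, dt_s + sample(0:3, n_decoys_below_total, TRUE)))
  bl_s <- sample(3:20, n_blacklisted, replace = TRUE)
  blk <- mk(n_blacklisted, "BLACK", bl_s,
            bl_s + sample(7:30, n_blacklisted, TRUE))
  candidates <- rbind(true, dspan, dtot, blk)
  labels <- rep(c("true", "decoy_spanning", "decoy_total", "blacklisted"),
                c(n_true, n_decoys_below_spanning, n_decoys_below_total,
                  n_blacklisted))
  blacklist <- structure(
    list(pairs = if (is.null(blk)) list() else
      lapply(seq_len(nrow(blk)), function(i) c(blk$gene5[i], blk$gene3[i])),
      orientation = "unordered"),
    class = "fusion_blacklist")
  if (is.null(candidates)) {
    candidates <- data.frame(sample_id = character(0), gene5 = character(0),
                             gene3 = character(0),
                             spanning_reads = numeric(0),
                             total_supporting_reads = numeric(0),
                             stringsAsFactors = FALSE)
  }
  list(candidates = candidates, blacklist = blacklist,
       truth = list(labels = labels, seed = seed))
}

#' Write a complete synthetic cohort bundle to a directory
#'
#' Emits every input the pipeline consumes — mutation TSV, gene-model TSV,
#' gene-set GMT, segment and ploidy TSVs, expression TSV, fusion-candidate and
#' blacklist TSVs — plus `truth.json` with the generator ground truth. The
#' cohort has subtype-consistent structure: co-deleted samples carry IDH
#' hotspot mutations and joint whole-arm 1p/19q loss.
#'
#' @param dir output directory (created if needed)
#' @param n_samples cohort size (default 51)
#' @param seed RNG seed driving every generator
#' @return invisible list of written paths and the truth list
#' @export
write_synthetic_bundle <- function(dir, n_samples = 51, seed) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  arm_table <- read_arm_table()
  model <- synthetic_gene_model(n_genes = 2000, gene_length_bp = 5000,
                                arm_table = arm_table)
  model$gene[1:2] <- c("IDH1", "IDH2")
  samples <- sprintf("S%03d", seq_len(n_samples))
  set.seed(seed)
  subtype <- sample(c("IDHmut_codel", "IDHmut_noncodel", "IDHwt"),
                    n_samples, replace = TRUE, prob = c(0.75, 0.15, 0.10))
  idh_samples <- samples[subtype != "IDHwt"]
  spiked <- stats::setNames(rep(5, 50), model$gene[101:150])
  mut <- generate_mutation_cohort(n_samples = n_samples, gene_model = model,
                                  spikes = spiked,
                                  idh_mutant_samples = idh_samples,
                                  seed = seed + 1)
  codel <- samples[subtype == "IDHmut_codel"]
  ascn <- generate_ascn_cohort(n_samples, arm_table,
                               arm_loss_freqs = c("4p,4q" = 0.3, "9p" = 0.28,
                                                  "14q" = 0.19),
                               seed = seed + 2)
  # overwrite 1p/19q: joint loss exactly for the co-deleted subtype
  seg <- ascn$segments
  sel_1p19q <- (seg$chrom == "chr1" &
                  seg$end <= arm_table$end[arm_table$arm_name == "1p"]) |
    (seg$chrom == "chr19" &
       seg$start >= arm_table$start[arm_table$arm_name == "19q"])
  hit <- sel_1p19q & seg$sample_id %in% codel
  seg$total_cn[hit] <- 1
  seg$minor_cn[hit] <- 0
  gene_sets <- list()
  set_names <- sprintf("SET%03d", 1:20)
  pool <- model$gene[201:1200]
  for (i in seq_along(set_names)) {
    gene_sets[[set_names[i]]] <- pool[((i - 1) * 50 + 1):(i * 50)]
  }
  gene_sets[["SPIKED"]] <- names(spiked)
  fus <- generate_fusion_table(seed = seed + 3)
  paths <- list(
    mutations = file.path(dir, "mutations.tsv"),
    gene_model = file.path(dir, "gene_model.tsv"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    segments = file.path(dir, "segments.tsv"),
    ploidy = file.path(dir, "ploidy.tsv"),
    expression = file.path(dir, "expression.tsv"),
    fusions = file.path(dir, "fusions.tsv"),
    blacklist = file.path(dir, "blacklist.tsv"),
    truth = file.path(dir, "truth.json"))
  write_tsv(mut$table$records, paths$mutations)
  write_tsv(model, paths$gene_model)
  write_gmt(gene_sets, paths$gene_sets)
  write_tsv(seg, paths$segments)
  write_tsv(ascn$ploidy, paths$ploidy)
  tcf12_mut <- samples[seq_len(min(8, n_samples))]
  expr_sets <- list(SHIFTED = sprintf("g%05d", 1:40))
  exprg <- generate_expression(
    n_genes = 500,
    groups = list(tcf12_mut, setdiff(samples, tcf12_mut)),
    gene_sets = expr_sets, shifted_sets = c(SHIFTED = -1),
    noise_sd = 0.5, seed = seed + 4)
  write_expression_matrix(exprg$expr, paths$expression)
  write_tsv(fus$candidates, paths$fusions)
  bl <- do.call(rbind, lapply(fus$blacklist$pairs, function(p) {
    data.frame(gene5 = p[1], gene3 = p[2], stringsAsFactors = FALSE)
  }))
  if (is.null(bl)) bl <- data.frame(gene5 = character(0),
                                    gene3 = character(0))
  write_tsv(bl, paths$blacklist)
  truth <- list(subtype_labels = stats::setNames(as.list(subtype), samples),
                spiked_genes = as.list(spiked),
                spiked_set = "SPIKED",
                mutation = mut$truth, ascn = ascn$truth,
                expression = exprg$truth,
                tcf12_mutant_samples = tcf12_mut,
                fusion = fus$truth, seed = seed)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(paths, list(truth_data = truth)))
}
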