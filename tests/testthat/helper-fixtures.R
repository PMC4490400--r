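# Small in-code fixtures shared across tests.

tiny_gene_model <- function() {
  data.frame(
    gene = c("IDH1", "IDH2", "CIC", "FUBP1", "TCF12", "NOTCH1"),
    coding_length_bp = c(1200, 1300, 4800, 1900, 2100, 7700),
    chrom = c("chr2", "chr15", "chr19", "chr1", "chr15", "chr9"),
    arm = c("q", "q", "q", "p", "q", "q"),
    stringsAsFactors = FALSE)
}

tiny_records <- function() {
  data.frame(
    sample_id = c("s1", "s1", "s2", "s2", "s3"),
    gene = c("IDH1", "CIC", "IDH2", "FUBP1", "TCF12"),
    chrom = c("chr2", "chr19", "chr15", "chr1", "chr15"),
    pos = c(394, 100, 515, 50, 1804),
    ref = c("G", "C", "G", "A", "C"),
    alt = c("A", "T", "A", "G", "G"),
    variant_class = c("missense", "nonsense", "missense", "frameshift",
                      "missense"),
    protein_change = c("R132H", "R215*", "R172K", NA, "R602M"),
    stringsAsFactors = FALSE)
}

tiny_table <- function() {
  cohort_mutation_table(tiny_records(), tiny_gene_model())
}

# One whole-arm segment row.
arm_segment <- function(sample_id, arm_name, total_cn, minor_cn,
                        arm_table = read_arm_table(), n_probes = 1000,
                        frac = 1) {
  row <- arm_table[arm_table$arm_name == arm_name, ]
  len <- row$end - row$start + 1
  data.frame(sample_id = sample_id, chrom = row$chrom, start = row$start,
             end = row$start + floor(len * frac) - 1, n_probes = n_probes,
             total_cn = total_cn, minor_cn = minor_cn,
             stringsAsFactors = FALSE)
}

# Independent brute-force oracle: upper-tail binomial probability by direct
# PMF summation in log space (never calls the package's survival path).
brute_binom_upper_log <- function(m, k, p) {
  if (m <= 0) return(0)
  if (m > k) return(-Inf)
  lp <- dbinom(m:k, size = k, prob = p, log = TRUE)
  mx <- max(lp)
  mx + log(sum(exp(lp - mx)))
}

brute_binom_upper <- function(m, k, p) exp(brute_binom_upper_log(m, k, p))

# Hand-enumerated 12-candidate fusion fixture: rows 1-3 qualify; 4-6 fail the
# strict spanning rule (including spanning = 2 exactly); 7-9 fail the
# inclusive total rule (including total = 9); 10-11 are blacklisted pairs
# with good support; 12 fails spanning before total.
fusion_fixture <- function() {
  data.frame(
    sample_id = sprintf("s%02d", 1:12),
    gene5 = c("FGFR3", "AAA", "CCC", "DDD", "EEE", "FFF",
              "GGG", "HHH", "III", "BL1A", "BL2A", "JJJ"),
    gene3 = c("TACC3", "BBB", "CCC2", "DDD2", "EEE2", "FFF2",
              "GGG2", "HHH2", "III2", "BL1B", "BL2B", "JJJ2"),
    spanning_reads = c(8, 3, 5, 2, 1, 0, 5, 3, 9, 8, 4, 2),
    total_supporting_reads = c(20, 10, 15, 50, 12, 10, 9, 8, 9, 20, 11, 5),
    stringsAsFactors = FALSE)
}

fixture_blacklist <- function(orientation = "unordered") {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(c("gene5\tgene3", "BL1A\tBL1B", "BL2B\tBL2A"), path)
  load_blacklist(path, orientation)
}

# Independent rule oracle for copy-number classification, written as a
# literal transcription of the published threshold sentences.
oracle_classify <- function(total, minor, ploidy) {
  if (total == 0) cat_ <- "homozygous_deletion"
  else if (total > ploidy + 2) cat_ <- "high_amplification"
  else if (total >= ploidy + 1) cat_ <- "gain"
  else if (total <= ploidy - 1) cat_ <- "loss"
  else cat_ <- "neutral"
  list(category = cat_, loh = minor == 0)
}

# Exact rational hypergeometric upper tail by enumeration over all
# achievable overlaps (choose() arithmetic, independent of phyper).
brute_hyper_upper <- function(overlap, set_size, de_size, universe_size) {
  if (overlap <= 0) return(1)
  xs <- overlap:min(set_size, de_size)
  sum(choose(set_size, xs) * choose(universe_size - set_size, de_size - xs)) /
    choose(universe_size, de_size)
}
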