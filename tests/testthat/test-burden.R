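# The burden test compares the observed gene-set mutation count with
# Binomial(k = n*L(P), p = A/(n*L(G))) and reports the exact upper tail.

make_cohort <- function(counts_by_gene, model, n_samples = 2) {
  rec <- do.call(rbind, lapply(names(counts_by_gene), function(g) {
    k <- counts_by_gene[[g]]
    if (k == 0) return(NULL)
    data.frame(sample_id = rep(sprintf("s%d", seq_len(n_samples)),
                               length.out = k),
               gene = g, chrom = "chr1", pos = seq_len(k), ref = "C",
               alt = "T", variant_class = "missense", protein_change = NA,
               stringsAsFactors = FALSE)
  }))
  cohort_mutation_table(rec, model,
                        samples = sprintf("s%d", seq_len(n_samples)))
}

test_that("burden test reproduces the hand-checked binomial construction", {
  # n=2 samples, L_P=100 of L_G=1000, A=10 -> k=200, p=0.005
  model <- data.frame(gene = c("a", "b"), coding_length_bp = c(100, 900),
                      chrom = "chr1", arm = "p", stringsAsFactors = FALSE)
  tab <- make_cohort(list(a = 4, b = 6), model, n_samples = 2)
  res <- burden_test(tab, "a")
  expect_equal(res$k, 200)
  expect_equal(res$p, 0.005)
  expect_equal(res$m_obs, 4)
  # frozen from independent PMF summation of Binomial(200, 0.005) over x >= 4
  expect_equal(res$p_value, 0.0186813, tolerance = 1e-5)
  expect_equal(res$p_value, brute_binom_upper(4, 200, 0.005),
               tolerance = 1e-12)
})

test_that("degenerate tails behave: m=0 gives 1, closed forms match", {
  model <- data.frame(gene = c("a", "b"), coding_length_bp = c(3, 3),
                      chrom = "chr1", arm = "p", stringsAsFactors = FALSE)
  # m_obs = 0 for set {b}: p_value must be exactly 1
  tab <- make_cohort(list(a = 3), model, n_samples = 1)
  expect_equal(burden_test(tab, "b")$p_value, 1)
  # k=3, p=0.5, m=3: tail is p^k = 0.125
  expect_equal(exp(oligoscape:::binom_sf_log(3, 3, 0.5)), 0.125)
})

test_that("survival function matches brute-force PMF summation in log space", {
  set.seed(101)
  for (i in 1:200) {
    k <- sample(1:10000, 1)
    p <- runif(1, 1e-6, 0.2)
    m <- sample(0:min(k, 50), 1)
    mine <- oligoscape:::binom_sf_log(m, k, p)
    ref <- log(brute_binom_upper(m, k, p))
    expect_lt(abs(mine - ref), 1e-9)
  }
})

test_that("p-value is monotone in m_obs and in L_P", {
  ps <- vapply(1:20, function(m) oligoscape:::binom_sf_log(m, 1000, 0.01),
               numeric(1))
  expect_true(all(diff(ps) < 0))
  # larger set (larger k) at fixed m_obs -> larger tail probability
  pk <- vapply(c(100, 200, 400, 800), function(k) {
    oligoscape:::binom_sf_log(5, k, 0.01)
  }, numeric(1))
  expect_true(all(diff(pk) > 0))
})

test_that("the tail stays finite and exact for k up to 1e8", {
  lp <- oligoscape:::binom_sf_log(500, 1e8, 1e-6)
  expect_true(is.finite(lp))
  # Poisson limit sanity: k*p = 100, so log P(X >= 500) ~ -405
  expect_lt(lp, -400)
  expect_equal(oligoscape:::binom_sf_log(0, 1e8, 1e-6), 0)
})

test_that("members absent from the universe are excluded from L(P)", {
  model <- data.frame(gene = c("a", "b"), coding_length_bp = c(100, 900),
                      chrom = "chr1", arm = "p", stringsAsFactors = FALSE)
  tab <- make_cohort(list(a = 4, b = 6), model)
  expect_message(res <- burden_test(tab, c("a", "NOT_SEQUENCED")),
                 "excluded")
  expect_equal(res$L_P, 100)
  expect_equal(res$n_members_in_universe, 1)
  expect_error(burden_test(tab, "NOT_SEQUENCED"), "no members")
})

test_that("burden_scan matches burden_test, sorts by p and appends BH q-values", {
  model <- data.frame(gene = letters[1:10],
                      coding_length_bp = rep(1000, 10),
                      chrom = "chr1", arm = "p", stringsAsFactors = FALSE)
  counts <- as.list(setNames(c(9, 1, 2, 0, 3, 1, 2, 1, 0, 1), letters[1:10]))
  tab <- make_cohort(counts, model, n_samples = 4)
  sets <- list(hot = "a", cold = c("d", "i"), mid = c("c", "e"))
  scan <- burden_scan(tab, sets)
  expect_equal(scan$p_value[scan$set_name == "hot"],
               burden_test(tab, "a", "hot")$p_value)
  expect_false(is.unsorted(scan$p_value))
  expect_equal(scan$q_value,
               p.adjust(scan$p_value, method = "BH"))
  tallies <- attr(scan, "member_tallies")
  expect_equal(tallies$n_mutations[tallies$set_name == "hot" &
                                     tallies$gene == "a"], 9L)
})

test_that("a spiked gene set attains the smallest p in a scan", {
  model <- synthetic_gene_model(n_genes = 1000, gene_length_bp = 5000)
  spiked_genes <- model$gene[1:50]
  g <- generate_mutation_cohort(
    n_samples = 10, gene_model = model, base_rate = 1.6e-6,
    spikes = setNames(rep(5, 50), spiked_genes), seed = 77)
  sets <- c(list(SPIKED = spiked_genes),
            setNames(lapply(1:9, function(i) {
              model$gene[(50 + (i - 1) * 50 + 1):(50 + i * 50)]
            }), paste0("NULL", 1:9)))
  scan <- burden_scan(g$table, sets)
  expect_equal(scan$set_name[1], "SPIKED")
})
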