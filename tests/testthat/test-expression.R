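mk_expr <- function(n_genes, na, nb, seed = 1, noise = 0.5) {
  set.seed(seed)
  samples <- c(sprintf("a%02d", seq_len(na)), sprintf("b%02d", seq_len(nb)))
  m <- matrix(rnorm(n_genes * (na + nb), 7, noise), n_genes,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)), samples))
  m
}

test_that("planted shifts obey the joint p and logFC rule at its boundary", {
  m <- mk_expr(50, 10, 10, seed = 2, noise = 0.05)
  a <- grep("^a", colnames(m), value = TRUE)
  b <- grep("^b", colnames(m), value = TRUE)
  m["g0001", a] <- m["g0001", a] + 1.0   # clears both rules
  m["g0002", a] <- m["g0002", a] + 0.5   # tiny p but |logFC| <= 0.6
  res <- differential_genes(m, a, b)
  tab <- res$table
  expect_true("g0001" %in% res$significant)
  expect_equal(tab$logFC[tab$gene == "g0001"], 1.0, tolerance = 0.1)
  expect_false("g0002" %in% res$significant)
  expect_lt(tab$p_value[tab$gene == "g0002"], 0.05)
  # direction convention: mutant (group_a) minus wild-type
  m["g0003", a] <- m["g0003", a] - 1.0
  res2 <- differential_genes(m, a, b)
  expect_lt(res2$table$logFC[res2$table$gene == "g0003"], 0)
})

test_that("per-gene Welch and pooled tests match stats::t.test", {
  m <- mk_expr(20, 5, 7, seed = 3)
  a <- grep("^a", colnames(m), value = TRUE)
  b <- grep("^b", colnames(m), value = TRUE)
  for (testname in c("welch", "pooled")) {
    res <- differential_genes(m, a, b, contrast_config(test = testname))
    ref_p <- vapply(rownames(m), function(g) {
      t.test(m[g, a], m[g, b], var.equal = testname == "pooled")$p.value
    }, numeric(1))
    expect_equal(res$table$p_value, unname(ref_p[res$table$gene]),
                 tolerance = 1e-12)
  }
})

test_that("argument contract: disjoint groups of >=2 present samples", {
  m <- mk_expr(5, 3, 3)
  a <- grep("^a", colnames(m), value = TRUE)
  b <- grep("^b", colnames(m), value = TRUE)
  expect_error(differential_genes(m, a, c(a[1], b)), "disjoint")
  expect_error(differential_genes(m, a[1], b), "at least 2")
  expect_error(differential_genes(m, c(a, "nope"), b), "nope")
  m[1, ] <- 5  # constant gene is dropped from the universe
  expect_message(res <- differential_genes(m, a, b), "zero-variance")
  expect_equal(length(res$universe), 4)
})

test_that("null contrast has ~5% of genes below p 0.05 and almost none pass jointly", {
  m <- mk_expr(2000, 20, 20, seed = 4, noise = 0.5)
  a <- grep("^a", colnames(m), value = TRUE)
  b <- grep("^b", colnames(m), value = TRUE)
  res <- differential_genes(m, a, b)
  frac <- mean(res$table$p_value < 0.05)
  expect_gt(frac, 0.03); expect_lt(frac, 0.07)
  expect_lt(length(res$significant), 0.01 * 2000)
})

test_that("hypergeometric enrichment is exact against brute enumeration", {
  universe <- sprintf("u%02d", 1:10)
  sets <- list(S = universe[1:5])
  de <- universe[1:5]
  res <- hypergeom_enrichment(de, sets, universe)
  expect_equal(res$p_value, 1 / 252)
  # exhaustive small-universe agreement
  set.seed(6)
  for (i in 1:50) {
    N <- sample(5:20, 1)
    uni <- sprintf("x%02d", seq_len(N))
    st <- sample(uni, sample(1:N, 1))
    de2 <- sample(uni, sample(0:N, 1))
    p <- hypergeom_enrichment(de2, list(a = st), uni)$p_value
    ref <- brute_hyper_upper(length(intersect(st, de2)), length(st),
                             length(de2), N)
    expect_equal(p, ref, tolerance = 1e-13)
  }
  # degenerate cases
  expect_equal(hypergeom_enrichment(character(0), sets, universe)$p_value, 1)
  expect_equal(
    hypergeom_enrichment(de, list(off = c("no1", "no2")), universe)$p_value, 1)
  expect_error(hypergeom_enrichment(de, sets, character(0)), "empty")
  expect_error(hypergeom_enrichment("zzz", sets, universe), "subset")
})

test_that("gene-set activity averages present members and ranks stably", {
  m <- matrix(7, nrow = 3, ncol = 3,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2", "s3")))
  act <- gene_set_activity(m, c("g1", "g2"))
  expect_equal(act$sample_id, c("s1", "s2", "s3"))  # tie: input order
  expect_equal(act$activity, rep(7, 3))

  m2 <- m; m2[, "s3"] <- 8
  act2 <- gene_set_activity(m2, c("g1", "g2", "g3"))
  expect_equal(act2$sample_id[1], "s3")

  # members absent from the matrix are ignored in the mean
  m3 <- m; m3["g1", ] <- c(1, 2, 3); m3["g2", ] <- c(5, 4, 3)
  act3 <- gene_set_activity(m3, c("g1", "g2", "ABSENT"))
  expect_equal(sort(act3$activity, decreasing = TRUE),
               unname(sort(colMeans(m3[c("g1", "g2"), ]), decreasing = TRUE)))
  expect_error(gene_set_activity(m, "ABSENT"), "no gene-set member")
})

test_that("a downshifted set ranks shifted samples last by activity", {
  groups <- list(sprintf("m%02d", 1:6), sprintf("w%02d", 1:10))
  sets <- list(DOWN = sprintf("g%05d", 1:30))
  g <- generate_expression(200, groups, sets, c(DOWN = -1), noise_sd = 0.3,
                           seed = 8)
  act <- gene_set_activity(g$expr, sets$DOWN)
  # the 6 mutant samples occupy the bottom ranks on average
  mutant_ranks <- act$rank[act$sample_id %in% groups[[1]]]
  expect_gt(mean(mutant_ranks), 10)
})
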