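test_that("burden rates are mutations per Mb with the documented arithmetic", {
  model <- tiny_gene_model()
  rec <- do.call(rbind, c(
    replicate(10, tiny_records()[1, ], simplify = FALSE),
    replicate(30, tiny_records()[3, ], simplify = FALSE)))
  rec$sample_id <- rep(c("a", "b"), c(10, 30))
  tab <- cohort_mutation_table(rec, model)
  res <- suppressMessages(compute_burden(tab, target_mb = 20))
  expect_equal(res$rate_per_mb, c(0.5, 1.5))
  expect_equal(mean(res$rate_per_mb), 1.0)

  empty <- cohort_mutation_table(tiny_records()[0, ], model, samples = "a")
  res0 <- suppressMessages(compute_burden(empty, target_mb = 50))
  expect_equal(res0$rate_per_mb, 0)
  expect_error(compute_burden(tab, target_mb = 0), "positive")
})

test_that("non-silent counts follow the fixed class subset", {
  tab <- tiny_table()  # 5 records, all in non-silent classes
  res <- suppressMessages(compute_burden(tab, target_mb = 1))
  expect_equal(sum(res$n_nonsilent), 5)
  rec <- tiny_records()
  rec$variant_class[1] <- "silent"
  rec$variant_class[2] <- "noncoding"
  tab2 <- cohort_mutation_table(rec, tiny_gene_model())
  res2 <- suppressMessages(compute_burden(tab2, target_mb = 1))
  expect_equal(sum(res2$n_nonsilent), 3)
  expect_equal(sum(res2$n_total), 5)
})

test_that("substitution collapse maps all 12 ordered pairs onto 6 classes, 2 each", {
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  cls <- collapse_substitution(pairs$ref, pairs$alt)
  expect_equal(nrow(pairs), 12)
  expect_setequal(unique(cls), c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G"))
  expect_true(all(table(cls) == 2))
  expect_equal(collapse_substitution("G", "A"), "C>T")
  expect_equal(collapse_substitution("C", "T"), "C>T")
  expect_equal(collapse_substitution("A", "C"), "T>G")
  expect_true(is.na(collapse_substitution("AT", "A")))
  expect_true(is.na(collapse_substitution("N", "A")))
})

test_that("spectrum counts sum to the number of single-base substitutions", {
  g <- generate_mutation_cohort(n_samples = 5, seed = 3,
                                gene_model = synthetic_gene_model(500))
  sp <- mutation_spectrum(g$table)
  cls_cols <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  per_sample_records <- table(g$table$records$sample_id)
  for (i in seq_len(nrow(sp))) {
    expect_equal(sum(sp[i, cls_cols]) + sp$indel_count[i],
                 unname(per_sample_records[sp$sample_id[i]]))
  }
  # generator is C>T dominant, so the cohort-wide C>T share is largest
  totals <- colSums(sp[, cls_cols])
  expect_equal(names(which.max(totals)), "C>T")
})

test_that("memo-sort orders by descending binary words over ranked genes", {
  m <- matrix(c(1, 1, 0,
                0, 0, 1), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  expect_equal(order_for_oncoprint(m), c("s1", "s2", "s3"))

  z <- matrix(0L, 2, 3, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  expect_equal(order_for_oncoprint(z), c("s1", "s2", "s3"))

  one <- matrix(c(0, 1, 0, 1), nrow = 1,
                dimnames = list("g", paste0("s", 1:4)))
  ord <- order_for_oncoprint(one)
  expect_equal(ord, c("s2", "s4", "s1", "s3"))  # carriers first, stable
})

test_that("memo-sort output is a permutation invariant to input column order", {
  set.seed(42)
  for (rep in 1:10) {
    m <- matrix(rbinom(60, 1, 0.3), nrow = 5,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:12)))
    ord <- order_for_oncoprint(m)
    expect_setequal(ord, colnames(m))
    shuf <- m[, sample(ncol(m)), drop = FALSE]
    expect_equal(order_for_oncoprint(shuf), ord)
  }
})

test_that("hypermutators beyond 3x the median rate are flagged, not excluded", {
  rec <- do.call(rbind, replicate(40, tiny_records()[1, ], simplify = FALSE))
  rec$sample_id <- c(rep("hyper", 36), rep("a", 2), rep("b", 2))
  tab <- cohort_mutation_table(rec, tiny_gene_model())
  expect_message(res <- compute_burden(tab, target_mb = 1), "hypermutator")
  expect_equal(res$sample_id[res$hypermutator], "hyper")
  expect_equal(nrow(res), 3)
})
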