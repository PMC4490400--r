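test_that("segment classification matches the published threshold sentences", {
  expect_equal(classify_segment(list(total_cn = 0, minor_cn = 0), 2),
               list(category = "homozygous_deletion", loh = TRUE))
  expect_equal(classify_segment(list(total_cn = 3, minor_cn = 1), 2),
               list(category = "gain", loh = FALSE))
  expect_equal(classify_segment(list(total_cn = 2, minor_cn = 0), 2),
               list(category = "neutral", loh = TRUE))  # copy-neutral LOH
  expect_equal(classify_segment(list(total_cn = 5, minor_cn = 2), 2),
               list(category = "high_amplification", loh = FALSE))
  expect_equal(classify_segment(list(total_cn = 1, minor_cn = 0), 2),
               list(category = "loss", loh = TRUE))
  # boundary: CN = ploidy + 2 is gain, just above is amplification
  expect_equal(classify_segment(list(total_cn = 4, minor_cn = 1), 2)$category,
               "gain")
  expect_equal(classify_segment(list(total_cn = 4.01, minor_cn = 1),
                                2)$category, "high_amplification")
})

test_that("classification agrees with an independent rule oracle on random triples", {
  set.seed(9)
  n <- 2000
  ploidy <- sample(c(2, 3, 4, runif(5, 1.5, 4.5)), n, replace = TRUE)
  total <- round(pmax(0, ploidy + sample(-3:4, n, TRUE) +
                        rnorm(n, 0, 0.3) * rbinom(n, 1, 0.5)), 2)
  minor <- round(runif(n) * total, 2)
  # force the printed boundary cases into the draw
  total[1:5] <- c(0, ploidy[2] + 1, ploidy[3] - 1, ploidy[4] + 2 + 1e-9,
                  ploidy[5] + 2)
  minor[1] <- 0
  minor[2:5] <- pmin(minor[2:5], total[2:5])
  res <- classify_cn(total, minor, ploidy)
  for (i in seq_len(n)) {
    o <- oracle_classify(total[i], minor[i], ploidy[i])
    expect_identical(res$category[i], o$category)
    expect_identical(res$loh[i], o$loh)
  }
})

test_that("categories partition: every segment gets exactly one category", {
  set.seed(10)
  total <- round(runif(500, 0, 8), 1)
  minor <- round(runif(500) * total, 1)
  res <- classify_cn(total, minor, 2.4)
  expect_true(all(res$category %in% c("neutral", "gain", "loss",
                                      "high_amplification",
                                      "homozygous_deletion")))
  expect_equal(length(res$category), 500)
  expect_true(all(res$loh[res$category == "homozygous_deletion"]))
})

test_that("focal events require >=5 probes and the focal categories", {
  calls <- data.frame(
    sample_id = c("s1", "s1", "s1", "s2"),
    chrom = "chr9", start = c(100, 500, 900, 100), end = c(200, 600, 1000, 200),
    n_probes = c(4, 5, 100, 6),
    total_cn = c(0, 0, 6, 0), minor_cn = 0,
    category = c("homozygous_deletion", "homozygous_deletion", "gain",
                 "homozygous_deletion"),
    loh = TRUE, stringsAsFactors = FALSE)
  foc <- list_focal_events(calls)
  expect_equal(nrow(foc), 2)           # 4-probe homdel and the gain excluded
  expect_equal(foc$n_probes, c(5, 6))
  expect_equal(foc$sample_id, c("s1", "s2"))
  amp <- calls[3, ]; amp$category <- "high_amplification"
  expect_equal(nrow(list_focal_events(amp)), 1)
})

test_that("arm recurrence counts samples by length-weighted loss coverage", {
  at <- read_arm_table()
  samples <- sprintf("s%d", 1:10)
  seg <- do.call(rbind, c(
    lapply(samples[1:3], function(s) rbind(arm_segment(s, "4p", 1, 0, at),
                                           arm_segment(s, "4q", 1, 0, at))),
    list(arm_segment("s4", "9p", 1, 0, at, frac = 0.4))))
  pl <- data.frame(sample_id = unique(seg$sample_id), ploidy = 2)
  calls <- classify_cohort(seg, pl)
  rec <- arm_recurrence(calls, samples, at, arms = c("4p", "4q", "9p"))
  expect_equal(rec$fraction_lost[rec$arm == "4p"], 0.3)
  expect_equal(rec$fraction_lost[rec$arm == "4q"], 0.3)
  # 40% coverage of 9p is below the 0.9 threshold
  expect_equal(rec$fraction_lost[rec$arm == "9p"], 0)
  expect_error(arm_recurrence(calls, samples, at, arms = "99z"), "absent")
  none <- arm_recurrence(calls[0, ], samples, at, arms = "4p")
  expect_equal(none$fraction_lost, 0)
})

test_that("planted arm-loss frequencies are recovered within sampling error", {
  g <- generate_ascn_cohort(
    n_samples = 200, arm_loss_freqs = c("4p,4q" = 0.3, "9p" = 0.3,
                                        "14q" = 0.2), seed = 21)
  calls <- classify_cohort(g$segments, g$ploidy)
  rec <- arm_recurrence(calls, g$ploidy$sample_id,
                        arms = c("4p", "9p", "14q"))
  for (case in list(c("4p", 0.3), c("9p", 0.3), c("14q", 0.2))) {
    f <- as.numeric(case[2])
    se3 <- 3 * sqrt(f * (1 - f) / 200)
    expect_lt(abs(rec$fraction_lost[rec$arm == case[1]] - f), se3)
  }
})
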