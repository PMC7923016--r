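test_that("allele and genotype frequencies come from exact count arithmetic", {
  ct <- genotype_counts(mora_fixture("table1_mora"))
  f <- allele_frequencies(ct, "MC1R")
  expect_equal(unname(f[["e"]]), 564 / 714)
  expect_equal(sum(f), 1)
  fn <- allele_frequencies(ct, "NR6A1")
  expect_equal(unname(fn[["C"]]), 3 / 714)
  g <- genotype_frequencies(ct, "MC1R")
  expect_equal(unname(g[["e/e"]]), 225 / 357)
  expect_equal(unname(genotype_frequencies(ct, "NR6A1")[["T/T"]]), 355 / 357)
  expect_equal(sum(g), 1)

  single <- genotype_count_table(list(MC1R = c("e/e" = 1)))
  expect_equal(unname(allele_frequencies(single, "MC1R")[["e"]]), 1)
  expect_equal(unname(genotype_frequencies(single, "MC1R")[["e/e"]]), 1)
  empty <- genotype_count_table(list(MC1R = c("e/e" = 0)))
  expect_error(allele_frequencies(empty, "MC1R"), "undefined")
})

test_that("count-derived frequency tables sum to one exactly", {
  ft <- as_freq_table(list(`Mora Romagnola` = retained_mora_counts(),
                           `Italian Duroc` = duroc_counts()))
  for (b in freq_breeds(ft)) {
    for (ln in unique(ft$locus)) {
      rows <- ft$breed == b & ft$locus == ln
      if (any(rows)) expect_identical(sum(ft$freq[rows]), 1)
    }
  }
})

test_that("chi-square HWE test behaves at the reference points", {
  perfect <- genotype_count_table(list(MC1R = c("E+/E+" = 25, "E+/e" = 50, "e/e" = 25)))
  h <- hwe_test(perfect, "MC1R")
  expect_equal(h$statistic, 0)
  expect_equal(h$p_value, 1)
  expect_identical(h$df, 1L)

  mono <- genotype_count_table(list(NR6A1 = c("T/T" = 50)))
  hm <- hwe_test(mono, "NR6A1")
  expect_true(hm$degenerate)
  expect_equal(hm$p_value, 1)

  # four-allele table: df = k(k-1)/2
  ct4 <- genotype_counts(mora_fixture("table1_mora"))
  h4 <- hwe_test(ct4, "MC1R")
  expect_identical(h4$df, 6L)
  expect_true(h4$p_value >= 0 && h4$p_value <= 1)
})

test_that("the exact HWE test matches the brute-force pairing oracle", {
  # conditional distribution of heterozygote counts by exhaustive pairing
  for (case in list(c(n = 4, nA = 3), c(n = 4, nA = 4), c(n = 3, nA = 2))) {
    n <- case[["n"]]; nA <- case[["nA"]]
    dist <- oracle_het_distribution(n, nA)
    for (nab in as.integer(names(dist))) {
      naa <- (nA - nab) / 2
      nbb <- n - naa - nab
      counts <- c(naa, nab, nbb)
      names(counts) <- c("A/A", "A/B", "B/B")
      ct <- genotype_count_table(list(L = counts[counts > 0]),
                                 loci = list(L = locus("L", c("A", "B"))))
      p_pkg <- hwe_test(ct, "L", method = "exact")$p_value
      p_oracle <- sum(dist[dist <= dist[[as.character(nab)]] * (1 + 1e-12)])
      expect_equal(p_pkg, p_oracle, tolerance = 1e-12,
                   label = sprintf("exact HWE p (n=%d, nA=%d, nAB=%d)", n, nA, nab))
    }
  }
  expect_error(hwe_test(genotype_counts(mora_fixture("table1_mora")), "MC1R", "exact"),
               "biallelic")
})

test_that("Weir-Cockerham theta agrees with an independent scalar oracle", {
  set.seed(421)
  for (rep in 1:20) {
    n1 <- sample(10:40, 1); n2 <- sample(10:40, 1)
    p1 <- runif(1, 0.1, 0.9); p2 <- runif(1, 0.1, 0.9)
    a <- random_count_table(n1, p1)
    b <- random_count_table(n2, p2)
    res <- try(wc_fst_pair(a, b), silent = TRUE)
    if (inherits(res, "try-error")) next  # both loci monomorphic by chance
    oracle <- oracle_wc_theta(
      list(oracle_pop_summary(a), oracle_pop_summary(b)),
      split(res$components$allele, res$components$locus))
    expect_equal(res$theta, oracle, tolerance = 1e-10)
  }
})

test_that("jointly monomorphic loci contribute nothing and symmetry holds", {
  mr <- retained_mora_counts()
  duroc <- duroc_counts()
  res <- wc_fst_pair(mr, duroc)
  nr <- res$components[res$components$locus == "NR6A1", ]
  expect_true(all(nr[, c("a", "b", "c")] == 0))
  expect_false(res$informative[["NR6A1"]])
  expect_equal(res$theta, wc_fst_pair(duroc, mr)$theta)  # order-invariant
  expect_lte(res$theta, 1)
  both_mono <- genotype_count_table(list(NR6A1 = c("T/T" = 10)))
  expect_error(wc_fst_pair(both_mono, both_mono), "no informative locus|undefined")
})

test_that("same-frequency populations give near-zero mean theta", {
  set.seed(99)
  thetas <- replicate(200, {
    a <- random_count_table(200, 0.3, loci = "MC1R")
    b <- random_count_table(200, 0.3, loci = "MC1R")
    out <- try(wc_fst_pair(a, b)$theta, silent = TRUE)
    if (inherits(out, "try-error")) NA_real_ else out
  })
  expect_gt(mean(thetas, na.rm = TRUE), -0.02)
  expect_lt(mean(thetas, na.rm = TRUE), 0.02)
})
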