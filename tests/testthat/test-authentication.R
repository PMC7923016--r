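mr_mc1r <- c(`E+` = 0.192, e = 0.809)
mr_nr <- c(T = 1.000, C = 0.000)

test_that("delta differentials reproduce the reference comparisons", {
  apulo <- c(`E+` = 0.040, e = 0.035, ED2 = 0.856, EP = 0.069)
  d <- delta_differential(mr_mc1r, apulo, c("E+", "e"), "combined")
  expect_equal(round(d$value, 3), 0.925)
  expect_equal(delta_differential(mr_mc1r, mr_mc1r, c("E+", "e"), "combined")$value,
               abs(1 - 1.001), tolerance = 1e-12)  # self-comparison ~ 0
  wb <- c(`E+` = 0.925, e = 0.022, ED2 = 0.004, EP = 0.049)
  expect_equal(round(delta_differential(mr_mc1r, wb, c("E+", "e"), "combined")$value, 3),
               0.053)
  dr <- delta_differential(mr_mc1r, wb, c("E+", "e"), "per_allele_range")
  expect_equal(round(dr$range, 3), c(0.733, 0.787))
  expect_equal(round(dr$value, 3), 0.760)
  # culling premise: target must sum to ~1 over its breed-specific alleles
  expect_error(delta_differential(c(`E+` = 0.5, e = 0.3, EP = 0.2),
                                  apulo, c("E+", "e")), "culling premise")
})

test_that("error rates follow 1 - delta and the product rule", {
  expect_equal(error_rate(0.925), 0.075)
  expect_equal(error_rate(1), 0)
  expect_equal(error_rate(0.760), 0.240)
  expect_equal(round_err <- combined_error_rate(0.075, 0.856), 0.0642)
  expect_equal(combined_error_rate(0.5, 0), 0)
  expect_error(error_rate(1.2), "\\[0, 1\\]")
  # ERc never exceeds either component
  set.seed(2)
  for (i in 1:20) {
    e1 <- runif(1); e2 <- runif(1)
    expect_lte(combined_error_rate(e1, e2), min(e1, e2))
  }
})

test_that("assignment probabilities count allowed-genotype carriers", {
  allowed <- c("e/e", "E+/e", "E+/E+")
  expect_equal(assignment_probability(c("e/e" = 1), allowed), 0)       # Duroc
  expect_equal(assignment_probability(c("EP/EP" = 1), allowed), 1)     # Large White
  expect_equal(assignment_probability(c("C/C" = 0.9, "C/T" = 0.1), "T/T"), 1)
  mixed <- c("e/e" = 0.4, "E+/e" = 0.3, "EP/e" = 0.3)
  expect_equal(assignment_probability(mixed, allowed), 0.3)
  expect_error(assignment_probability(c("e/e" = 0.5), allowed), "sum to 1")
})

test_that("genotype-consistency verdicts follow the shipped standard", {
  expect_identical(authenticate_sample("E+/e", "T/T")$verdict, "consistent")
  expect_identical(authenticate_sample("e/E+", "T/T")$verdict, "consistent")
  expect_identical(authenticate_sample("EP/e", "T/T")$verdict, "inconsistent")
  expect_identical(authenticate_sample("e/e", "T/C")$verdict, "inconsistent")
  v <- authenticate_sample(NA, "T/T")
  expect_identical(v$verdict, "indeterminate")
  ok <- authenticate_sample("e/e", "T/T")
  expect_match(ok$caveat, "Duroc")
})

test_that("the published-parity summary regenerates the printed matrix", {
  st <- build_summary_table(mora_fixture("table2_panel"),
                            rounding = "published_parity")
  pick <- function(b) st[st$breed == b, ]
  # printed |delta| column (Duroc delta excluded: printed 0.191 is not
  # reproducible from the printed frequencies under either reading)
  printed_delta <- c(`Apulo Calabrese` = 0.925, Casertana = 0.857,
                     `Cinta Senese` = 0.955, `Nero Siciliano` = 0.875,
                     Sarda = 0.638, `Wild Boar` = 0.053,
                     `Italian Large White` = 1.000, `Italian Landrace` = 1.000,
                     Pietrain = 1.000, `Belgian Landrace` = 1.000,
                     Hampshire = 1.000)
  for (b in names(printed_delta)) {
    col <- if (b == "Wild Boar") "delta_mc1r_combined" else "delta_mc1r"
    expect_equal(pick(b)[[col]], printed_delta[[b]], label = paste("delta", b))
  }
  # printed ER / ERc columns, all 12 rows
  printed <- rbind(
    c(0.075, 0.856, 0.064), c(0.143, 0.938, 0.134), c(0.045, 1.000, 0.045),
    c(0.125, 0.718, 0.090), c(0.362, 0.991, 0.359), c(0.240, 0.018, 0.004),
    c(0.000, 1.000, 0.000), c(0.000, 1.000, 0.000), c(0.809, 1.000, 0.809),
    c(0.000, 1.000, 0.000), c(0.000, 1.000, 0.000), c(0.000, 1.000, 0.000))
  rownames(printed) <- c("Apulo Calabrese", "Casertana", "Cinta Senese",
                         "Nero Siciliano", "Sarda", "Wild Boar",
                         "Italian Large White", "Italian Landrace",
                         "Italian Duroc", "Pietrain", "Belgian Landrace",
                         "Hampshire")
  for (b in rownames(printed)) {
    row <- pick(b)
    expect_equal(c(row$er_mc1r, row$er_nr6a1, row$erc), unname(printed[b, ]),
                 label = paste("ER row", b))
  }
  # wild boar parenthesised combined-mode ERc
  expect_equal(pick("Wild Boar")$erc_combined, 0.017)
  # PMR derivable only for locus-fixed populations
  expect_equal(pick("Italian Duroc")$pmr_mc1r, 0)
  expect_equal(pick("Italian Large White")$pmr_mc1r, 1)
  expect_equal(pick("Cinta Senese")$pmr_nr6a1, 0)
  expect_true(is.na(pick("Apulo Calabrese")$pmr_mc1r))
})

test_that("full-precision mode keeps the product identity exact", {
  counts <- list(`Mora Romagnola` = retained_mora_counts(),
                 `Italian Duroc` = duroc_counts())
  ft <- as_freq_table(counts)
  st <- build_summary_table(ft, rounding = "full",
                            genotype_tables = counts["Italian Duroc"])
  row <- st[st$breed == "Italian Duroc", ]
  expect_identical(row$erc, row$er_mc1r * row$er_nr6a1)
  expect_equal(row$pmr_mc1r, 0)
  # self-comparison limit: delta 0 gives the (1, 1, 1) error-rate row
  d0 <- delta_differential(c(`E+` = 0.2, e = 0.8), c(`E+` = 0.2, e = 0.8),
                           c("E+", "e"), "combined")
  expect_equal(error_rate(d0), 1)
  expect_equal(combined_error_rate(error_rate(d0), 1), 1)
})
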