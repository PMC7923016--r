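test_that("genotype keys are unordered pairs and locus definitions validate", {
  expect_identical(geno("e", "E+"), geno("E+", "e"))
  expect_identical(geno("e", "E+"), "E+/e")
  expect_identical(geno_key("T/C"), "C/T")
  expect_true(is.na(geno(NA, "e")))
  expect_error(locus("MC1R", c("e", "e")), "unique")
  expect_error(locus("", "e"), "non-empty")
  loc <- locus_mc1r()
  expect_length(loc$alleles, 5)
})

test_that("genotype tables round-trip through the delimited format", {
  s <- mora_fixture("table1_mora")
  tmp <- tempfile(fileext = ".csv")
  write_genotype_table(s, tmp)
  s2 <- read_genotype_table(tmp)
  expect_equal(n_animals(s2), 357)
  ct1 <- genotype_counts(s)
  ct2 <- genotype_counts(s2)
  expect_identical(ct1$counts, ct2$counts)

  # small hand-written file: allele order within a genotype is irrelevant
  tmp2 <- tempfile(fileext = ".csv")
  writeLines(c("animal_id,breed,class,MC1R_a1,MC1R_a2,NR6A1_a1,NR6A1_a2",
               "a1,MR,sow,e,E+,T,T",
               "a2,MR,sow,E+,e,T,T",
               "a3,MR,boar,,,T,T"), tmp2)
  s3 <- read_genotype_table(tmp2)
  expect_equal(n_animals(s3), 3)
  g <- geno(s3$data$MC1R_a1, s3$data$MC1R_a2)
  expect_identical(g[1], g[2])
  expect_true(is.na(g[3]))  # missing token -> explicit missing genotype

  writeLines(c("animal_id,breed,class,MC1R_a1,MC1R_a2,NR6A1_a1,NR6A1_a2",
               "a1,MR,sow,e,Z,T,T"), tmp2)
  expect_error(read_genotype_table(tmp2), "allele 'Z'.*MC1R")
  writeLines(c("animal_id,breed,MC1R_a1", "a1,MR,e"), tmp2)
  expect_error(read_genotype_table(tmp2), "missing column")
})

test_that("reference genotype sample reproduces the published genotype counts", {
  ct <- genotype_counts(mora_fixture("table1_mora"))
  expect_identical(ct$counts$MC1R[["e/e"]], 225L)
  expect_identical(ct$counts$MC1R[["E+/e"]], 109L)
  expect_identical(ct$counts$MC1R[["E+/E+"]], 11L)
  expect_identical(ct$counts$MC1R[["E+/ED2"]], 5L)
  expect_identical(ct$counts$MC1R[["ED2/e"]], 5L)
  expect_identical(ct$counts$MC1R[["E+/ED1"]], 1L)
  expect_identical(ct$counts$MC1R[["ED1/ED2"]], 1L)
  expect_identical(ct$counts$NR6A1[["T/T"]], 355L)
  expect_identical(ct$counts$NR6A1[["C/T"]], 1L)
  expect_identical(ct$counts$NR6A1[["C/C"]], 1L)
  expect_identical(unname(ct$n), c(357L, 357L))
})

test_that("GENEPOP export is structurally valid and round-trips exactly", {
  one <- population_sample("MR", data.frame(
    animal_id = "x1", breed = "MR", class = "sow",
    MC1R_a1 = "e", MC1R_a2 = "e", NR6A1_a1 = "T", NR6A1_a2 = "T",
    stringsAsFactors = FALSE))
  tmp <- tempfile(fileext = ".gen")
  write_genepop(one, tmp)
  lines <- readLines(tmp)
  expect_length(lines, 1 + 2 + 1 + 1)  # title, 2 locus lines, Pop, 1 animal
  expect_identical(lines[2:3], c("MC1R", "NR6A1"))
  expect_match(lines[4], "^Pop$")
  # lexicographic codes: E+=01, ED1=02, ED2=03, EP=04, e=05; T: C=01, T=02
  expect_match(lines[5], "0505 0202")

  s <- mora_fixture("table1_mora")
  write_genepop(s, tmp)
  emitted <- readLines(tmp)
  expect_equal(sum(grepl("0505 ", emitted, fixed = TRUE)), 225)  # e/e pairs
  back <- read_genepop(tmp)
  expect_length(back, 1)
  expect_identical(genotype_counts(back[[1]])$counts, genotype_counts(s)$counts)

  wide <- locus("HYPER", sprintf("a%03d", 1:100))
  expect_error(write_genepop(
    population_sample("x", data.frame(animal_id = "i", breed = "x", class = "sow",
                                      HYPER_a1 = "a001", HYPER_a2 = "a002"),
                      list(HYPER = wide)), tmp),
    "at most 99")
})

test_that("frequency tables read, validate sums, and locate entries", {
  ft <- mora_fixture("table2_panel")
  expect_length(freq_breeds(ft), 13)
  wb <- freq_vector(ft, "Wild Boar", "MC1R")
  expect_identical(attr(wb, "n"), 113L)
  expect_equal(unname(wb[["E+"]]), 0.925)

  ok <- data.frame(breed = "b", n = 10, locus = "L",
                   allele = c("A", "B"), freq = c(0.5, 0.5))
  expect_s3_class(allele_freq_table(ok), "ba_freq_table")
  bad <- transform(ok, freq = c(0.7, 0.4))
  expect_error(allele_freq_table(bad, tol = 0.02), "sum")
  expect_warning(allele_freq_table(bad, tol = 0.02, on_violation = "warning"), "sum")
  expect_error(allele_freq_table(transform(ok, freq = c(1.2, -0.2))), "\\[0, 1\\]")
})
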