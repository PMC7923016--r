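test_that("the MC1R restriction decision tree is total over the five alleles", {
  # full published pattern of each allele calls that allele back
  expect_identical(call_mc1r_allele(hhai = "uncut", bstui = "uncut"), "e")
  expect_identical(call_mc1r_allele(hhai = "cut", bstui = "uncut"), "ED1")
  expect_identical(call_mc1r_allele(hhai = "cut", bstui = "cut", bsphi = "uncut"), "E+")
  expect_identical(call_mc1r_allele(hhai = "cut", bstui = "cut", bsphi = "cut",
                                    indel_bp = 168), "ED2")
  expect_identical(call_mc1r_allele(hhai = "cut", bstui = "cut", bsphi = "cut",
                                    indel_bp = 170), "EP")
  # HhaI alone is diagnostic for e
  expect_identical(call_mc1r_allele(hhai = "uncut"), "e")
})

test_that("ambiguous and contradictory restriction patterns are rejected", {
  expect_error(call_mc1r_allele(), "at least one assay")
  expect_error(call_mc1r_allele(hhai = "cut"), "BstUI")
  expect_error(call_mc1r_allele(hhai = "cut", bstui = "cut"), "BspHI")
  expect_error(call_mc1r_allele(hhai = "cut", bstui = "cut", bsphi = "cut"), "indel")
  expect_error(call_mc1r_allele(hhai = "uncut", bstui = "cut"), "inconsistent|contradicts")
  expect_error(call_mc1r_allele(hhai = "cut", bstui = "cut", bsphi = "cut",
                                indel_bp = 169), "outside the published")
})

test_that("NR6A1 calls follow the MspI cut state", {
  expect_identical(call_nr6a1_allele("cut"), "C")
  expect_identical(call_nr6a1_allele("uncut"), "T")
  expect_error(call_nr6a1_allele("unknown"), "MspI")
})

test_that("record checks apply phenotype and genotype rules with precedence", {
  std <- mora_romagnola_standard()
  rec <- function(class = "sow", coat = "black_and_tan", m1 = "e", m2 = "e",
                  n1 = "T", n2 = "T") {
    data.frame(animal_id = "x", breed = "MR", class = class, coat_colour = coat,
               ears = "bent_forward_parallel", linea_sparta = "present",
               MC1R_a1 = m1, MC1R_a2 = m2, NR6A1_a1 = n1, NR6A1_a2 = n2,
               stringsAsFactors = FALSE)
  }
  expect_identical(check_record(rec(), std)$status, "retained")
  red_adult <- check_record(rec(coat = "red"), std)
  expect_identical(red_adult$status, "excluded")
  expect_identical(red_adult$primary_reason, "phenotype_coat")
  expect_identical(check_record(rec(class = "young", coat = "red"), std)$status,
                   "retained")  # red tolerated in young pigs
  ed2 <- check_record(rec(m1 = "ED2"), std)
  expect_identical(ed2$primary_reason, "genotype_MC1R")
  cC <- check_record(rec(n2 = "C"), std)
  expect_identical(cC$primary_reason, "genotype_NR6A1")
  # phenotype takes precedence, all reasons recorded
  multi <- check_record(rec(coat = "red", m1 = "ED2", n2 = "C"), std)
  expect_identical(multi$primary_reason, "phenotype_coat")
  expect_setequal(multi$reasons, c("phenotype_coat", "genotype_MC1R", "genotype_NR6A1"))
  miss <- check_record(rec(m1 = NA, m2 = NA), std)
  expect_identical(miss$status, "indeterminate")
})

test_that("the Herd-Book filter reproduces the published exclusions", {
  s <- mora_fixture("table1_mora")
  rep <- apply_herdbook_filter(s)
  expect_length(rep$retained, 342)
  expect_equal(nrow(rep$excluded), 15)
  expect_identical(unname(rep$counts[["phenotype_coat"]]), 1L)
  geno_excl <- sum(rep$counts[c("genotype_MC1R", "genotype_NR6A1")])
  expect_identical(geno_excl, 14L)
  expect_identical(unname(rep$counts[["genotype_MC1R"]]), 12L)
  expect_identical(unname(rep$counts[["genotype_NR6A1"]]), 2L)
  # partition: every animal lands in exactly one bucket
  expect_equal(length(rep$retained) + nrow(rep$excluded) + length(rep$indeterminate),
               n_animals(s))
  # idempotence: the retained set passes its own filter untouched
  rep2 <- apply_herdbook_filter(rep$retained_sample)
  expect_equal(nrow(rep2$excluded), 0)
  expect_length(rep2$retained, 342)
})

test_that("breed standards serialise to and from the YAML config", {
  path <- system.file("extdata", "mora_romagnola_standard.yml", package = "breedauth")
  std <- read_breed_standard(path)
  ref <- mora_romagnola_standard()
  expect_identical(std$allowed_genotypes, ref$allowed_genotypes)
  tmp <- tempfile(fileext = ".yml")
  write_breed_standard(ref, tmp)
  expect_identical(read_breed_standard(tmp)$allowed_genotypes, ref$allowed_genotypes)
  expect_error(breed_standard(list(MC1R = character(0)),
                              ref$phenotype_rules), "empty")
})

test_that("compliance reports serialise to CSV and JSON", {
  rep <- apply_herdbook_filter(mora_fixture("table1_mora"))
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_compliance_report(rep, csv, js)
  out <- read.csv(csv, stringsAsFactors = FALSE)
  expect_equal(sum(out$status == "excluded"), 15)
  summ <- jsonlite::read_json(js)
  expect_equal(summ$n_retained, 342)
  expect_equal(summ$counts$genotype_MC1R, 12)
})
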