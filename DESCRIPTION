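Package: breedauth
Title: Breed Authentication and Herd-Book Genotype Standards from Coat-Colour
    and Vertebral-Number Markers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for redefining a pig-breed Herd Book standard from DNA
    markers in the MC1R (Extension locus) and NR6A1 genes and for quantifying
    how well those markers authenticate mono-breed meat products. Implements
    allele calling from PCR-RFLP restriction patterns, Herd-Book compliance
    filtering by phenotype and genotype, allele and genotype frequency
    estimation, Hardy-Weinberg testing (chi-square and exact), pairwise
    multi-allele Weir-Cockerham Fst, exact tests of genic differentiation
    (full enumeration and Markov-chain Monte Carlo), Fisher combination of
    per-locus p-values, classical multidimensional scaling of populations
    from allele frequencies, and allele-frequency differential, error-rate
    and assignment-probability statistics for meat authentication. Includes
    a Hardy-Weinberg genotype simulator and the printed-table reference
    panels needed to reproduce the published analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
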