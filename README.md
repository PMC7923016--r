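# breedauth

Population-genetics tooling for DNA-marker-based breed standards and
"mono-breed" meat authentication, built around the two-marker system used to
redefine the Mora Romagnola pig Herd Book: the *MC1R* (*Extension*)
coat-colour locus (alleles `E+`, `ED1`, `ED2`, `EP`, `e`) and the *NR6A1*
p.P192L vertebral-number variant (alleles `C`/`T`).

For a breed whose breed-specific alleles are `E+`/`e` at *MC1R* and `T` at
*NR6A1*, the package answers three questions:

1. **Which registered animals conform to the genetic standard?** Allele calls
   from PCR-RFLP cut/uncut patterns (`call_mc1r_allele()`,
   `call_nr6a1_allele()`) feed a Herd-Book filter
   (`apply_herdbook_filter()`) that partitions a herd into retained /
   excluded / indeterminate with machine-readable reasons.
2. **How differentiated is the breed from potential substitution sources?**
   Allele/genotype frequencies from exact count arithmetic, Hardy–Weinberg
   tests (chi-square and biallelic exact), pairwise Weir–Cockerham
   *F*st from variance components *a*, *b*, *c*
   (θ = Σa / Σ(a+b+c) over alleles and loci), the exact test of genic
   differentiation on 2×k allele tables (full enumeration or Metropolis
   Markov chain with batch-mean standard errors), Fisher combination across
   informative loci, and classical MDS of populations from allele
   frequencies.
3. **How reliable is a meat-sample verdict?** Per-locus allele-frequency
   differentials |δ| (combined or per-allele mode), mis-assignment error
   rates ER = 1 − |δ| and ERc = ER(MC1R) × ER(NR6A1), correct-assignment
   probabilities PMR = 1 − Σ f(allowed genotypes) from observed genotype
   frequencies, and a per-sample genotype-consistency verdict
   (`authenticate_sample()`).

The printed reference datasets of the study (whole-herd genotype sample,
13-population allele-frequency panel, earlier herd sample) are rebuilt in
code by `mora_fixture()`, and `simulate_population()` generates
Hardy–Weinberg genotype samples with class-specific phenotype rates for
testing every stage without external data.

## Worked example

```r
library(breedauth)

herd <- mora_fixture("table1_mora")          # 357 genotyped breeding pigs
report <- apply_herdbook_filter(herd)
report
#> <compliance report> standard: Mora Romagnola
#>   retained: 342  excluded: 15  indeterminate: 0
#>   exclusions by primary reason:
#>     phenotype_coat: 1
#>     genotype_MC1R: 12
#>     genotype_NR6A1: 2

counts <- genotype_counts(report$retained_sample)
allele_frequencies(counts, "MC1R")
#>         e        E+
#> 0.8084795 0.1915205

hwe_test(counts, "MC1R")
#> <HWE test> chi-square = 0.2910, df = 1, p = 0.5896

duroc <- genotype_count_table(list(MC1R = c("e/e" = 30), NR6A1 = c("T/T" = 30)))
wc_fst_pair(counts, duroc)
#> <pairwise Fst> multi-locus theta = 0.1069
#>   MC1R: theta = 0.1069
#>   NR6A1: uninformative

st <- build_summary_table(mora_fixture("table2_panel"), rounding = "published_parity")
st[st$breed == "Apulo Calabrese", c("delta_mc1r", "er_mc1r", "er_nr6a1", "erc")]
#>   delta_mc1r er_mc1r er_nr6a1   erc
#> 1      0.925   0.075    0.856 0.064

authenticate_sample("E+/e", "T/T")
#> <authentication verdict> consistent
#>   MC1R: allowed
#>   NR6A1: allowed
#>   note: a consistent genotype does not exclude Duroc origin (Duroc is fixed for e/e and T/T)
```

The 15 exclusions (1 phenotypic, 14 genotypic: 3.9% of the breeding stock)
and the retained-herd frequencies, the *F*st of 0.107 against the closest
breed (Italian Duroc) and 0.756 against Italian Large White, and the
error-rate rows above are the herd-management quantities the Herd-Book
redefinition was based on.

A thin command-line front end over the same functions ships in
`inst/exec/breedauth` (subcommands `run`, `filter`, `freqs`, `hwe`, `fst`,
`gtest`, `mds`, `auth-stats`, `authenticate`, `simulate`, `fixtures`), and
`run_pipeline()` wires all stages end to end with per-stage TSV/JSON outputs
and a seed-recording manifest.

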