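---
title: "Marker-based Herd-Book standards and mono-breed meat authentication"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-based Herd-Book standards and mono-breed meat authentication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breedauth)
```

## The problem

Mora Romagnola is a small autochthonous pig breed whose survival rests on the
premium price of "mono-breed" pork products, a price that attracts
mis-labelling fraud. Its Herd Book redefined the breed standard around two DNA
markers whose allele distributions are close to unique among the breeds a
fraudster could substitute: the *Extension* coat-colour locus (*MC1R*), where
the breed carries only the wild-type allele `E+` and the recessive red allele
`e`, and the *NR6A1* vertebral-number variant (g.299084751C>T, p.P192L), where
the breed is fixed for the domestic allele `T`. `breedauth` implements the
full computational chain behind such a redefinition: calling alleles from
restriction-assay patterns, filtering the herd against the standard,
estimating allele and genotype frequencies, testing Hardy-Weinberg
equilibrium, quantifying between-population differentiation, and computing
the authentication statistics that say how well the two markers separate the
breed from everything else.

## Allele calling from PCR-RFLP patterns

The five major *Extension* alleles are resolved by three restriction digests
and one fragment-length read, applied as an ordered decision tree
(`call_mc1r_allele()`): *HhaI* cuts every allele except `e`; *BstUI* cuts
every allele except `e` and `ED1`; *BspHI* cuts `ED2` and `EP` but not `E+`;
a CC indel separates `ED2` (168 bp) from `EP` (170 bp). The tree consults
each assay only on the branch where it is informative, demands the assay
state it needs (an unknown state raises an *ambiguous call* error naming the
missing assay), and cross-checks any supplied state against the called
allele's published pattern (a contradiction raises an *inconsistency* error).
The published truth table does not state how *BspHI* behaves on `e` or
`ED1`; rather than guess, the tree is ordered so those branches are never
reached for those alleles, and states outside the published table are
errors. Inputs are already-scored cut/uncut calls: interpreting mixed band
images of heterozygotes is out of scope, so diploid genotypes are built from
two per-allele patterns.

## The compliance filter

`apply_herdbook_filter()` encodes the redefined standard
(`mora_romagnola_standard()`): adults must be black and tan, with ears bent
forward and parallel to the muzzle and the dorsal bristle mane ("Linea
sparta"); young pigs may transiently violate all three. Allowed genotypes
are `e/e`, `E+/e`, `E+/E+` at *MC1R* and `T/T` at *NR6A1*. Rules are applied
in a fixed precedence — phenotype, then *MC1R*, then *NR6A1* — and an animal
failing several rules records all reasons but counts once, under the first.
This mirrors the two-stage field workflow (phenotyping first, genotyping
second) and keeps the per-reason tallies additive: on the packaged
whole-herd sample the filter excludes 1 animal on coat colour and 14 on
genotype (12 *MC1R*, 2 *NR6A1*), retaining 342 of 357. A missing genotype at
a standard locus yields an *indeterminate* status, deliberately distinct
from exclusion.

```{r}
report <- apply_herdbook_filter(mora_fixture("table1_mora"))
report
```

## Population-genetic machinery

**Frequencies.** Allele frequencies are exact count ratios
(`allele count / 2n`), so per-locus frequencies sum to 1 exactly; tables read
from text (`read_frequency_table()`) tolerate a 0.015 deviation per
breed-locus row because printed 3-decimal tables drift by rounding (the
panel's own target-breed row sums to 1.001).

**Hardy-Weinberg.** `hwe_test()` offers a Pearson chi-square goodness-of-fit
over all k(k+1)/2 genotypes with k(k-1)/2 degrees of freedom (no continuity
correction, no pooling of rare genotypes — with several hundred animals and
two common alleles neither is needed) and, for biallelic loci, the
conditional exact test by full enumeration of heterozygote counts, with the
probability-ordering criterion and a 1e-12 relative tie tolerance. On the
retained herd both give p > 0.10 (chi-square 0.59, exact 0.73); the two can
legitimately differ by more than 0.1 because the exact test's probability
ordering treats the discrete tails differently than the asymptotic
chi-square.

**Fst.** `wc_fst_pair()` implements the two-population Weir-Cockerham
moment estimator from per-allele variance components a, b, c, summed over
alleles and loci (theta = sum a / sum(a+b+c)). Components are returned for
audit; loci monomorphic in both samples contribute (0, 0, 0) and are flagged
uninformative. A population compared with itself gives a slightly *negative*
theta (the unbiased estimator's finite-sample behaviour, visible in
published tables as small negative values for near-identical populations),
not exactly zero — tests assert |theta| < 0.01 there, and the estimator is
cross-validated against an independently coded scalar oracle to 1e-10.

**Genic differentiation.** `exact_g_test()` performs the conditional exact
test on the 2 x k alleles-by-populations table with fixed margins. Tables
whose state space is at most 200,000 configurations are fully enumerated
(zero standard error); larger tables use a Metropolis chain with ±1 moves on
random 2x2 sub-tables, defaulting to 10,000 dememorisation steps and 100
batches of 5,000 iterations, with the standard error taken over batch
means. Two numerical details matter: the tie criterion is applied in log
space with a 1e-9 tolerance (distinct table log-probabilities differ by far
more, while exact ties from symmetric margins must be caught), and the
incrementally updated log-probability is recomputed exactly at every batch
boundary to shed accumulated rounding drift — without this the chain
silently drops states probability-tied with the observed table, which can
carry several percent of the mass. Loci monomorphic across both populations
are excluded from Fisher's combination (`combine_pvalues_fisher()`), whose
choice for across-locus combination is this package's own: with one
informative locus (the usual case here, since *NR6A1* is fixed in most
breeds) the combined value is simply that locus's p.

**MDS.** `classical_mds()` concatenates each population's per-locus
frequency vectors (absent allele = 0), computes Euclidean distances and
delegates the double-centering eigendecomposition to `stats::cmdscale()`.
Components are oriented so the largest-magnitude coordinate is positive,
making runs reproducible. On the shipped panel the four cosmopolitan breeds
fixed for `EP` collapse onto a single point, as they must.

## Authentication statistics

The per-locus mis-assignment differential |δ| (`delta_differential()`)
compares the target breed's summed frequency over its breed-specific alleles
(which is 1 by the post-culling premise; the premise is enforced with a
0.002 tolerance) with the same sum in a comparison population, so in
combined mode |δ| = 1 − Σ other. When the comparison population itself
carries the target alleles at high frequency the combined differential
degenerates towards 0, so above a 0.90 summed-frequency threshold the
per-allele mode takes over: |δ| per allele, averaged, with the range
reported. That switch reproduces the published treatment of the wild boar
comparison (range 0.733–0.787, average 0.760, combined 0.053) and is the
only sensible reading of the Duroc comparison, where combined |δ| is 0.
Error rates follow `ER = 1 − |δ|` per locus and `ERc = ER × ER` across loci;
the correct-assignment probability `PMR = 1 − Σ f(allowed genotypes)` uses
*observed* genotype frequencies — Hardy-Weinberg imputation from allele
frequencies is deliberately refused because observed genotype distributions
in these breeds are not in HWE, and with allele-frequency-only input PMR is
reported only for populations fixed at the locus (their genotype
distribution being degenerate).

Two rounding modes exist. `"full"` carries full precision from counts and is
the default for new data. `"published_parity"` rounds input frequencies to
3 decimals, carries ER/ERc at full precision, and rounds half-up to
3 decimals on report — the order under which the printed tables are
internally consistent (e.g. 0.075 × 0.856 → 0.064, and the Duroc error rate
1 − mean(0.192, 0.191) = 0.8085 → 0.809).

```{r}
st <- build_summary_table(mora_fixture("table2_panel"), rounding = "published_parity")
st[, c("breed", "delta_mc1r", "delta_mode", "er_mc1r", "er_nr6a1", "erc")]
```

The per-sample verdict (`authenticate_sample()`) is genotype consistency
with the standard, with an explicit caveat: Duroc is fixed for `e/e` and
`T/T`, so a consistent verdict can never exclude Duroc origin — consistency
is necessary, not sufficient.

## The simulator and what passing tests mean

`simulate_population()` draws, per animal and locus, two alleles
independently from the specified frequency vector — single-generation
random-mating (Hardy-Weinberg) draws with no pedigree, drift, linkage or
genotyping error. Phenotypes are drawn per age class; the default young-pig
rates (red coat 8.9%, non-standard ears 11%, absent mane 9%) are the rates
observed in the monitored herd, and adults are generated standard. Each call
seeds its own generator (derived from the spec seed and the breed's position)
and restores the global RNG state. Because the generator emulates exactly
the model the estimators assume, passing calibration tests (parameter
recovery within binomial error, chi-square type-I error near nominal)
validates the implementations, not the robustness of the methods to real
data features such as genotyping error, relatedness within farms, or
departure from HWE.

## Packaged reference data

`mora_fixture()` rebuilds the study's printed datasets in code: the
357-animal whole-herd genotype sample, the 13-population allele-frequency
panel, and the earlier 74-pig sample (allele counts 26 `E+` / 122 `e`). Two
documented reconstructions are baked into the whole-herd sample: the two
*NR6A1* C-carrier sows are assigned `e/e` at *MC1R* (the only assignment
consistent with the retained-sample allele counts of 131 `E+` / 553 `e`), and
the red-coated sow is an adult with `e/e`, `T/T` as the published table's
footnote records. The panel ships the printed 3-decimal values as-is,
including their rounding drift; the retained herd's exact `e` frequency is
553/684 = 0.80848, which the panel prints as 0.809 (a double-rounding slip),
so parity checks on that row use a 1e-3 tolerance.

## Problem sizes and known limitations

The test suite runs the Markov chain at its full default settings (510,000
steps) on the 2x2 herd-comparison table and on small enumerable tables;
calibration properties use 200–2,000 replicates at n = 200–342 animals,
which the estimators' desk-scale inputs make quick. Known limitations: the
exact genic test covers two populations (2 x k tables), not R x k; the
exact HWE test is biallelic; Fst is the two-population estimator; PMR cannot
be computed from allele frequencies alone for non-fixed populations; and the
two-marker panel itself cannot distinguish the target breed from Duroc, a
limitation of the marker system the package reports rather than hides.
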