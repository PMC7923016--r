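#' Hardy-Weinberg equilibrium test
#'
#' Tests observed genotype counts at one locus against Hardy-Weinberg
#' proportions. Two methods:
#'
#' * `"chi_square"` — Pearson goodness-of-fit of observed vs HWE-expected
#'   genotype counts over all k(k+1)/2 genotypes of the k observed alleles,
#'   with k(k-1)/2 degrees of freedom (allele frequencies estimated from
#'   the data). No continuity correction and no pooling of rare genotypes.
#' * `"exact"` — the biallelic conditional exact test: full enumeration of
#'   heterozygote counts compatible with the observed allele counts, with
#'   p the sum of probabilities of outcomes as probable or less probable
#'   than the observed one (probability ties resolved with a 1e-12
#'   relative tolerance).
#'
#' A locus monomorphic in the sample gives a degenerate result with p = 1.
#'
#' @param counts a [genotype_count_table()].
#' @param locus locus name.
#' @param method `"chi_square"` (default) or `"exact"`.
#' @return an object of class `"ba_hwe"`: list with `method`, `statistic`
#'   (chi-square only), `df`, `p_value`, `degenerate`.
#' @examples
#' ct <- genotype_count_table(
#'   list(MC1R = c("e/e" = 222, "E+/e" = 109, "E+/E+" = 11)))
#' hwe_test(ct, "MC1R")$p_value  # > 0.10
#' @export
hwe_test <- function(counts, locus, method = c("chi_square", "exact")) {
  method <- match.arg(method)
  v <- counts$counts[[locus]]
  if (is.null(v)) stop_validation("no counts for locus '%s'", locus)
  n <- counts$n[[locus]]
  p <- allele_frequencies(counts, locus)
  alleles <- names(p)
  k <- length(alleles)
  if (k < 2) {
    return(structure(list(method = method, statistic = NA_real_, df = 0L,
                          p_value = 1, degenerate = TRUE), class = "ba_hwe"))
  }
  if (method == "chi_square") {
    gts <- all_genotypes(alleles)
    obs <- stats::setNames(numeric(length(gts)), gts)
    obs[names(v)] <- v
    al <- geno_split(gts)
    expd <- ifelse(al[, 1] == al[, 2],
                   n * p[al[, 1]]^2,
                   2 * n * p[al[, 1]] * p[al[, 2]])
    stat <- sum((obs - expd)^2 / expd)
    df <- as.integer(k * (k - 1) / 2)
    pv <- stats::pchisq(stat, df, lower.tail = FALSE)
    structure(list(method = method, statistic = stat, df = df, p_value = pv,
                   degenerate = FALSE), class = "ba_hwe")
  } else {
    if (k != 2) stop_validation("the exact HWE test is implemented for biallelic loci (got %d alleles)", k)
    ac <- allele_count_vector(counts, locus)
    nA <- min(ac)  # rarer allele
    rare <- names(ac)[which.min(ac)]
    gts <- names(v)
    al <- geno_split(gts)
    n_het_obs <- sum(v[(al[, 1] == rare) != (al[, 2] == rare)])
    # conditional log-probability of nAB heterozygotes given n and nA
    lp <- function(nab) {
      naa <- (nA - nab) / 2
      nbb <- n - naa - nab
      lfactorial(n) - lfactorial(naa) - lfactorial(nab) - lfactorial(nbb) +
        nab * log(2) + lfactorial(nA) + lfactorial(2 * n - nA) - lfactorial(2 * n)
    }
    nab_all <- seq(nA %% 2, nA, by = 2)
    probs <- exp(vapply(nab_all, lp, numeric(1)))
    p_obs <- probs[match(n_het_obs, nab_all)]
    pv <- sum(probs[probs <= p_obs * (1 + 1e-12)])
    structure(list(method = method, statistic = NA_real_, df = NA_integer_,
                   p_value = min(pv, 1), degenerate = FALSE), class = "ba_hwe")
  }
}

#' @export
print.ba_hwe <- function(x, ...) {
  if (x$degenerate) {
    cat("<HWE test> monomorphic locus (degenerate), p = 1\n")
  } else if (x$method == "chi_square") {
    cat(sprintf("<HWE test> chi-square = %.4f, df = %d, p = %.4g\n",
                x$statistic, x$df, x$p_value))
  } else {
    cat(sprintf("<HWE test> exact (biallelic), p = %.4g\n", x$p_value))
  }
  invisible(x)
}
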