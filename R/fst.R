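#' Pairwise Weir-Cockerham Fst from genotype counts
#'
#' Moment estimator of Fst (theta) for two populations from genotype count
#' tables, following the classic analysis-of-variance decomposition into
#' per-allele variance components: `a` (among populations), `b` (among
#' individuals within populations) and `c` (within individuals). For each
#' locus and allele, with r = 2 populations of sizes n_i, allele frequencies
#' p_i and observed heterozygote frequencies h_i:
#'
#' \deqn{a = \frac{\bar n}{n_c}\left[s^2 - \frac{1}{\bar n - 1}\left(\bar p(1-\bar p) - \frac{r-1}{r}s^2 - \frac{\bar h}{4}\right)\right]}
#' \deqn{b = \frac{\bar n}{\bar n - 1}\left[\bar p(1-\bar p) - \frac{r-1}{r}s^2 - \frac{2\bar n - 1}{4\bar n}\bar h\right]}
#' \deqn{c = \bar h / 2}
#'
#' where the bars are sample-size-weighted means and s^2 is the weighted
#' among-population variance of p. The multi-locus estimate is
#' `sum(a) / sum(a + b + c)` over all alleles and loci; loci monomorphic in
#' both samples contribute (0, 0, 0) and are flagged uninformative.
#'
#' @param counts_a,counts_b [genotype_count_table()] objects for the two
#'   populations.
#' @param loci character vector of loci to include; default all loci shared
#'   by the two tables.
#' @return an object of class `"ba_fst"`: list with `components` (data
#'   frame: locus, allele, a, b, c), `per_locus` (named vector of per-locus
#'   theta, `NA` where uninformative), `theta` (multi-locus estimate) and
#'   `informative` (logical per locus).
#' @examples
#' mr <- genotype_count_table(list(MC1R = c("e/e" = 222, "E+/e" = 109, "E+/E+" = 11),
#'                                 NR6A1 = c("T/T" = 342)))
#' duroc <- genotype_count_table(list(MC1R = c("e/e" = 30), NR6A1 = c("T/T" = 30)))
#' wc_fst_pair(mr, duroc)$theta  # ~ 0.107
#' @export
wc_fst_pair <- function(counts_a, counts_b, loci = NULL) {
  if (is.null(loci)) loci <- intersect(names(counts_a$counts), names(counts_b$counts))
  if (!length(loci)) stop_validation("no shared loci between the two samples")
  r <- 2
  comp <- list()
  informative <- stats::setNames(logical(length(loci)), loci)
  for (ln in loci) {
    pa <- allele_frequencies(counts_a, ln)
    pb <- allele_frequencies(counts_b, ln)
    alleles <- sort_c(union(names(pa), names(pb)))
    if (length(alleles) < 2) {  # monomorphic in both samples
      comp[[ln]] <- data.frame(locus = ln, allele = alleles,
                               a = 0, b = 0, c = 0, stringsAsFactors = FALSE)
      informative[ln] <- FALSE
      next
    }
    informative[ln] <- TRUE
    n <- c(counts_a$n[[ln]], counts_b$n[[ln]])
    ha <- het_frequencies(counts_a, ln, alleles)
    hb <- het_frequencies(counts_b, ln, alleles)
    nbar <- mean(n)
    nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
    rows <- lapply(alleles, function(a) {
      p <- c(pa[a] %||% 0, pb[a] %||% 0); p[is.na(p)] <- 0
      h <- c(ha[[a]], hb[[a]])
      pbar <- sum(n * p) / (r * nbar)
      s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(n * h) / (r * nbar)
      A <- (nbar / nc) *
        (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
      B <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
      C <- hbar / 2
      data.frame(locus = ln, allele = a, a = A, b = B, c = C, stringsAsFactors = FALSE)
    })
    comp[[ln]] <- do.call(rbind, rows)
  }
  components <- do.call(rbind, comp)
  rownames(components) <- NULL
  per_locus <- vapply(loci, function(ln) {
    cc <- components[components$locus == ln, ]
    den <- sum(cc$a + cc$b + cc$c)
    if (!informative[ln] || den == 0) NA_real_ else sum(cc$a) / den
  }, numeric(1))
  den <- sum(components$a + components$b + components$c)
  if (den == 0) stop_validation("undefined theta: no informative locus")
  structure(list(components = components, per_locus = per_locus,
                 theta = sum(components$a) / den, informative = informative),
            class = "ba_fst")
}

#' @export
print.ba_fst <- function(x, ...) {
  cat(sprintf("<pairwise Fst> multi-locus theta = %.4f\n", x$theta))
  for (ln in names(x$per_locus)) {
    cat(sprintf("  %s: %s\n", ln,
                if (is.na(x$per_locus[[ln]])) "uninformative"
                else sprintf("theta = %.4f", x$per_locus[[ln]])))
  }
  invisible(x)
}
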