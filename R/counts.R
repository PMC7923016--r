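#' Genotype count tables
#'
#' A genotype count table holds, per locus, the observed counts of each
#' diploid genotype (canonical `"a/b"` keys) together with the number of
#' animals typed at that locus. It is the input of the frequency,
#' Hardy-Weinberg and Fst machinery.
#'
#' @param counts named list: locus -> named integer vector of genotype
#'   counts (names are genotypes in any allele order).
#' @param loci named list of [locus()] definitions covering the counted loci.
#' @return an object of class `"ba_counts"`.
#' @examples
#' duroc <- genotype_count_table(list(MC1R = c("e/e" = 30), NR6A1 = c("T/T" = 30)))
#' @export
genotype_count_table <- function(counts, loci = default_loci()) {
  out <- list()
  for (ln in names(counts)) {
    v <- counts[[ln]]
    if (any(v < 0) || any(v != round(v))) {
      stop_validation("genotype counts at %s must be non-negative integers", ln)
    }
    keys <- geno_key(names(v))
    loc <- loci[[ln]]
    if (is.null(loc)) stop_validation("no locus definition for '%s'", ln)
    check_allele(unique(as.vector(geno_split(keys))), loc, where = "genotype counts")
    agg <- tapply(as.integer(v), keys, sum)
    out[[ln]] <- stats::setNames(as.integer(agg), names(agg))
  }
  structure(list(counts = out,
                 n = vapply(out, function(v) sum(v), integer(1)),
                 loci = loci[names(out)]),
            class = "ba_counts")
}

#' Tally genotype counts from a population sample
#'
#' Animals with a missing genotype at a locus are excluded from that locus's
#' counts only (never from the sample).
#'
#' @param sample a [population_sample()].
#' @return a `"ba_counts"` object.
#' @export
genotype_counts <- function(sample) {
  counts <- list()
  for (ln in names(sample$loci)) {
    g <- sample_genotypes(sample, ln)
    g <- g[!is.na(g)]
    tab <- table(g)
    counts[[ln]] <- stats::setNames(as.integer(tab), names(tab))
  }
  genotype_count_table(counts, sample$loci)
}

#' @export
print.ba_counts <- function(x, ...) {
  for (ln in names(x$counts)) {
    cat(sprintf("<genotype counts> %s (n = %d animals)\n", ln, x$n[[ln]]))
    v <- x$counts[[ln]]
    for (g in names(v)) cat(sprintf("  %-10s %d\n", g, v[[g]]))
  }
  invisible(x)
}

#' Allele counts at a locus
#'
#' Tallies allele copies from genotype counts: 2 per homozygote, 1 each per
#' heterozygote. Alleles are returned in lexicographic (C byte) order.
#'
#' @param counts a [genotype_count_table()].
#' @param locus locus name.
#' @return named integer vector of allele counts.
#' @export
allele_counts <- function(counts, locus) {
  v <- counts$counts[[locus]]
  if (is.null(v)) stop_validation("no counts for locus '%s'", locus)
  al <- geno_split(names(v))
  acc <- tapply(c(v, v), c(al[, 1], al[, 2]), sum)
  out <- stats::setNames(as.integer(acc), names(acc))
  out[sort_c(names(out))]
}

# back-compat internal alias
allele_count_vector <- function(counts, locus) allele_counts(counts, locus)

#' Allele frequencies from genotype counts
#'
#' `frequency(allele) = allele count / (2 * n_animals)`; the frequencies sum
#' to 1 exactly (integer arithmetic on counts).
#'
#' @param counts a `"ba_counts"` table.
#' @param locus locus name.
#' @return named numeric vector of allele frequencies with attribute `n`.
#' @export
allele_frequencies <- function(counts, locus) {
  n <- counts$n[[locus]]
  if (is.null(n) || n < 1) stop_validation("undefined frequency: no animals typed at '%s'", locus)
  ac <- allele_count_vector(counts, locus)
  out <- ac / (2 * n)
  attr(out, "n") <- n
  out
}

#' Genotype frequencies from genotype counts
#'
#' @inheritParams allele_frequencies
#' @return named numeric vector of genotype frequencies (canonical keys)
#'   with attribute `n`.
#' @export
genotype_frequencies <- function(counts, locus) {
  n <- counts$n[[locus]]
  if (is.null(n) || n < 1) stop_validation("undefined frequency: no animals typed at '%s'", locus)
  out <- counts$counts[[locus]] / n
  attr(out, "n") <- n
  out
}

#' Build an allele-frequency table from samples or count tables
#'
#' @param x a named list of `"ba_counts"` objects (names are breeds), or a
#'   list of [population_sample()] objects.
#' @return a `"ba_freq_table"` in long form; frequencies are exact from
#'   counts and sum to 1 per breed-locus.
#' @export
as_freq_table <- function(x) {
  rows <- list()
  for (breed in names(x)) {
    ct <- x[[breed]]
    if (inherits(ct, "ba_population")) ct <- genotype_counts(ct)
    for (ln in names(ct$counts)) {
      f <- allele_frequencies(ct, ln)
      rows[[length(rows) + 1]] <- data.frame(
        breed = breed, n = attr(f, "n"), locus = ln,
        allele = names(f), freq = as.numeric(f), stringsAsFactors = FALSE)
    }
  }
  allele_freq_table(do.call(rbind, rows), tol = 1e-9)
}

# Observed heterozygote frequency of each allele (proportion of animals
# heterozygous FOR that allele), needed by the Weir-Cockerham components.
het_frequencies <- function(counts, locus, alleles) {
  v <- counts$counts[[locus]]
  n <- counts$n[[locus]]
  al <- geno_split(names(v))
  out <- stats::setNames(numeric(length(alleles)), alleles)
  for (a in alleles) {
    het <- (al[, 1] == a) != (al[, 2] == a)
    out[a] <- sum(v[het]) / n
  }
  out
}
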