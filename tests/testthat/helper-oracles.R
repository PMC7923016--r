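# Independent oracles used to cross-check the package's estimators.
# These deliberately re-derive each quantity along a different code path
# (scalar loops, brute-force enumeration) than the implementation.

# Two-population Weir-Cockerham theta, scalar per-allele loop.
# pops: list of two lists, each with n (animals), p (named allele freqs)
# and h (named observed heterozygote frequency per allele).
oracle_wc_theta <- function(pops, alleles_by_locus) {
  num <- 0; den <- 0
  r <- 2
  for (ln in names(alleles_by_locus)) {
    for (al in alleles_by_locus[[ln]]) {
      n <- c(pops[[1]][[ln]]$n, pops[[2]][[ln]]$n)
      p <- c(pops[[1]][[ln]]$p[al], pops[[2]][[ln]]$p[al])
      p[is.na(p)] <- 0
      h <- c(pops[[1]][[ln]]$h[al], pops[[2]][[ln]]$h[al])
      h[is.na(h)] <- 0
      nbar <- mean(n)
      nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
      pbar <- sum(n * p) / (r * nbar)
      s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(n * h) / (r * nbar)
      a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
      b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      num <- num + a; den <- den + a + b + cc
    }
  }
  num / den
}

# Summaries (n, p, h) of a genotype count table for the oracle above.
oracle_pop_summary <- function(ct) {
  out <- list()
  for (ln in names(ct$counts)) {
    v <- ct$counts[[ln]]
    n <- sum(v)
    al <- do.call(rbind, strsplit(names(v), "/", fixed = TRUE))
    alleles <- sort(unique(as.vector(al)))
    cnt <- sapply(alleles, function(a) sum(v * ((al[, 1] == a) + (al[, 2] == a))))
    het <- sapply(alleles, function(a) sum(v[(al[, 1] == a) != (al[, 2] == a)]) / n)
    out[[ln]] <- list(n = n, p = cnt / (2 * n), h = het)
  }
  out
}

# Random two-allele genotype count table for property tests.
random_count_table <- function(n, p, loci = c("MC1R", "NR6A1")) {
  counts <- list()
  alleles <- list(MC1R = c("E+", "e"), NR6A1 = c("C", "T"))
  for (ln in loci) {
    a <- alleles[[ln]]
    g <- replicate(n, paste(sort(sample(a, 2, replace = TRUE, prob = c(p, 1 - p))),
                            collapse = "/"))
    tab <- table(g)
    counts[[ln]] <- stats::setNames(as.integer(tab), names(tab))
  }
  genotype_count_table(counts)
}

# Conditional distribution of the heterozygote count given allele counts,
# by brute-force enumeration of all equally likely pairings of 2n labelled
# allele tokens. Independent of the analytic exact-HWE formula. Tiny n only.
oracle_het_distribution <- function(n, nA) {
  tokens <- c(rep("A", nA), rep("B", 2 * n - nA))
  idx <- seq_len(2 * n)
  res <- new.env()
  pair_up <- function(remaining, nhet) {
    if (!length(remaining)) {
      key <- as.character(nhet)
      res[[key]] <- (res[[key]] %||% 0) + 1
      return(invisible())
    }
    first <- remaining[1]
    for (j in remaining[-1]) {
      het <- tokens[first] != tokens[j]
      pair_up(setdiff(remaining, c(first, j)), nhet + het)
    }
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  pair_up(idx, 0)
  counts <- unlist(as.list(res))
  counts / sum(counts)
}

# Embed points of the unit square as two biallelic loci: the frequency
# vectors ((x,1-x),(y,1-y)) place populations on a plane scaled by sqrt(2).
planar_freq_table <- function(xy) {
  rows <- do.call(rbind, lapply(seq_len(nrow(xy)), function(i) {
    data.frame(breed = sprintf("p%02d", i), n = 10,
               locus = c("L1", "L1", "L2", "L2"),
               allele = c("A", "B", "A", "B"),
               freq = c(xy[i, 1], 1 - xy[i, 1], xy[i, 2], 1 - xy[i, 2]),
               stringsAsFactors = FALSE)
  }))
  allele_freq_table(rows)
}

# Duroc / Italian Large White published genotype layouts, used repeatedly.
duroc_counts <- function() {
  genotype_count_table(list(MC1R = c("e/e" = 30), NR6A1 = c("T/T" = 30)))
}
ilw_counts <- function() {
  genotype_count_table(list(MC1R = c("EP/EP" = 49), NR6A1 = c("T/T" = 49)))
}
retained_mora_counts <- function() {
  genotype_count_table(list(MC1R = c("e/e" = 222, "E+/e" = 109, "E+/E+" = 11),
                            NR6A1 = c("T/T" = 342)))
}
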