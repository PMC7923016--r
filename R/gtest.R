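#' Markov chain configuration for the exact genic test
#'
#' Default chain settings follow common population-genetics practice for
#' exact differentiation tests: 10,000 dememorisation steps, 100 batches of
#' 5,000 iterations. The seed is mandatory so every run is reproducible.
#'
#' @param dememorisation burn-in steps before sampling.
#' @param batches number of batches (also used for the batch-mean standard
#'   error).
#' @param iterations_per_batch sampled steps per batch.
#' @param seed integer RNG seed (required).
#' @return an object of class `"ba_mc_config"`.
#' @export
mc_chain_config <- function(dememorisation = 10000, batches = 100,
                            iterations_per_batch = 5000, seed) {
  if (missing(seed)) stop_validation("a seed is required for the Markov chain")
  vals <- c(dememorisation, batches, iterations_per_batch)
  if (any(vals < 1) || any(vals != round(vals))) {
    stop_validation("chain settings must be positive integers")
  }
  structure(list(dememorisation = as.integer(dememorisation),
                 batches = as.integer(batches),
                 iterations_per_batch = as.integer(iterations_per_batch),
                 seed = as.integer(seed)),
            class = "ba_mc_config")
}

# log conditional probability of a 2xk table given fixed margins
# (multivariate Fisher/hypergeometric distribution)
log_table_prob <- function(tab) {
  sum(lfactorial(rowSums(tab))) + sum(lfactorial(colSums(tab))) -
    lfactorial(sum(tab)) - sum(lfactorial(tab))
}

# number of 2xk tables with the given margins (first-row compositions)
count_tables_2xk <- function(row1_total, col_margins) {
  # DP over columns: ways to split row1_total across columns with caps
  ways <- numeric(row1_total + 1); ways[1] <- 1
  for (cm in col_margins) {
    new <- numeric(row1_total + 1)
    for (s in 0:row1_total) {
      if (ways[s + 1] == 0) next
      upto <- min(cm, row1_total - s)
      idx <- s + 0:upto
      new[idx + 1] <- new[idx + 1] + ways[s + 1]
    }
    ways <- new
  }
  ways[row1_total + 1]
}

enumerate_exact_p <- function(tab, tol = 1e-12) {
  k <- ncol(tab)
  rm <- rowSums(tab); cm <- colSums(tab)
  obs_lp <- log_table_prob(tab)
  num <- 0; den <- 0
  rec <- function(j, rem, row1) {
    if (j == k) {
      x <- rem
      if (x < 0 || x > cm[k]) return()
      t2 <- rbind(c(row1, x), cm - c(row1, x))
      if (any(t2 < 0)) return()
      lp <- log_table_prob(t2)
      pr <- exp(lp)
      den <<- den + pr
      if (lp <= obs_lp + tol) num <<- num + pr
      return()
    }
    for (x in 0:min(rem, cm[j])) rec(j + 1, rem - x, c(row1, x))
  }
  rec(1, rm[1], integer(0))
  num / den
}

mc_exact_p <- function(tab, config, tol = 1e-9) {
  # tol is a log-space tie tolerance: distinct hypergeometric log
  # probabilities of these tables differ by far more than 1e-9, while the
  # incrementally updated log probability can drift by ~1e-12 per batch
  # (it is recomputed exactly at every batch boundary).
  k <- ncol(tab)
  cur <- tab
  lp_obs <- log_table_prob(cur)
  lp_cur <- lp_obs
  # Metropolis: +-1 move on a random 2x2 sub-table preserving margins; the
  # log-probability ratio only involves the four changed cells.
  with_local_seed(config$seed, {
    run_steps <- function(nsteps, count_hits) {
      hits <- 0L
      for (i in seq_len(nsteps)) {
        jj <- sample.int(k, 2L)
        j1 <- jj[1L]; j2 <- jj[2L]
        dir <- if (stats::runif(1) < 0.5) 1L else -1L
        o11 <- cur[1L, j1]; o21 <- cur[2L, j1]
        o12 <- cur[1L, j2]; o22 <- cur[2L, j2]
        n11 <- o11 + dir; n21 <- o21 - dir
        n12 <- o12 - dir; n22 <- o22 + dir
        if (n11 >= 0 && n21 >= 0 && n12 >= 0 && n22 >= 0) {
          dlp <- lfactorial(o11) + lfactorial(o21) + lfactorial(o12) + lfactorial(o22) -
                 lfactorial(n11) - lfactorial(n21) - lfactorial(n12) - lfactorial(n22)
          if (dlp >= 0 || stats::runif(1) < exp(dlp)) {
            cur[1L, j1] <<- n11; cur[2L, j1] <<- n21
            cur[1L, j2] <<- n12; cur[2L, j2] <<- n22
            lp_cur <<- lp_cur + dlp
          }
        }
        if (count_hits && lp_cur <= lp_obs + tol) hits <- hits + 1L
      }
      hits
    }
    run_steps(config$dememorisation, FALSE)
    batch_means <- vapply(seq_len(config$batches), function(b) {
      lp_cur <<- log_table_prob(cur)  # shed accumulated rounding drift
      run_steps(config$iterations_per_batch, TRUE) / config$iterations_per_batch
    }, numeric(1))
    list(p = mean(batch_means),
         se = stats::sd(batch_means) / sqrt(config$batches))
  })
}

#' Exact test of genic differentiation between two populations
#'
#' Conditional exact test on the 2 x k alleles-by-populations contingency
#' table with fixed margins, the multi-allele generalisation of Fisher's
#' exact probability test. The p-value is the total conditional probability
#' of tables as probable or less probable than the observed one
#' (probability-ordering criterion, ties resolved with a 1e-12 tolerance).
#' Small tables are fully enumerated (zero standard error); larger ones are
#' evaluated by a Metropolis Markov chain over tables with fixed margins
#' (+-1 moves on random 2x2 sub-tables) whose standard error is estimated
#' from batch means.
#'
#' @param allele_counts_a,allele_counts_b named integer vectors of allele
#'   counts in the two populations (names are allele codes; the union of
#'   names is used, absent alleles counting 0).
#' @param config a [mc_chain_config()]; required when the Markov chain is
#'   used.
#' @param method `"auto"` (enumerate when the state space is at most
#'   `max_tables`, else Markov chain), `"enumeration"` or `"mc"`.
#' @param max_tables enumeration cutoff for `method = "auto"`.
#' @return list with `p`, `se` (0 for enumeration), `method` used, and
#'   `informative` (`FALSE`, with `p = NA`, when the pooled locus is
#'   monomorphic).
#' @examples
#' exact_g_test(c(`E+` = 131, e = 553), c(`E+` = 26, e = 122))
#' @export
exact_g_test <- function(allele_counts_a, allele_counts_b, config = NULL,
                         method = c("auto", "enumeration", "mc"),
                         max_tables = 2e5) {
  method <- match.arg(method)
  alleles <- sort_c(union(names(allele_counts_a), names(allele_counts_b)))
  get0v <- function(v, a) if (a %in% names(v)) v[[a]] else 0L
  tab <- rbind(vapply(alleles, get0v, numeric(1), v = allele_counts_a),
               vapply(alleles, get0v, numeric(1), v = allele_counts_b))
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) < 2) {
    return(list(p = NA_real_, se = NA_real_, method = "none", informative = FALSE))
  }
  if (method == "auto") {
    nt <- count_tables_2xk(sum(tab[1, ]), colSums(tab))
    method <- if (nt <= max_tables) "enumeration" else "mc"
  }
  if (method == "enumeration") {
    list(p = enumerate_exact_p(tab), se = 0, method = "enumeration", informative = TRUE)
  } else {
    if (is.null(config)) stop_validation("a Markov chain config (with seed) is required for method 'mc'")
    res <- mc_exact_p(tab, config)
    list(p = res$p, se = res$se, method = "mc", informative = TRUE)
  }
}

#' Combine independent p-values with Fisher's method
#'
#' `-2 * sum(log(p))` referred to a chi-square distribution with `2k`
#' degrees of freedom. A length-1 list returns its element unchanged.
#'
#' @param p_list numeric vector of p-values in (0, 1].
#' @return combined p-value.
#' @export
combine_pvalues_fisher <- function(p_list) {
  p_list <- as.numeric(p_list)
  if (!length(p_list)) stop_validation("cannot combine an empty list of p-values")
  if (any(is.na(p_list)) || any(p_list <= 0 | p_list > 1)) {
    stop_validation("p-values must lie in (0, 1]")
  }
  if (length(p_list) == 1) return(p_list)
  stats::pchisq(-2 * sum(log(p_list)), df = 2 * length(p_list), lower.tail = FALSE)
}

#' Genic differentiation between two samples over multiple loci
#'
#' Runs [exact_g_test()] per locus on the allele counts of two genotype
#' count tables and combines the informative loci with
#' [combine_pvalues_fisher()]. Loci monomorphic across both populations are
#' flagged uninformative and excluded from the combination.
#'
#' @param counts_a,counts_b [genotype_count_table()] objects.
#' @param config a [mc_chain_config()].
#' @param loci loci to test; default all shared.
#' @param ... passed to [exact_g_test()].
#' @return an object of class `"ba_gtest"`: list with `per_locus` (list of
#'   per-locus results), `combined_p`, `config`.
#' @export
genic_differentiation <- function(counts_a, counts_b, config = NULL,
                                  loci = NULL, ...) {
  if (is.null(loci)) loci <- intersect(names(counts_a$counts), names(counts_b$counts))
  per_locus <- lapply(stats::setNames(loci, loci), function(ln) {
    exact_g_test(allele_count_vector(counts_a, ln),
                 allele_count_vector(counts_b, ln), config = config, ...)
  })
  ps <- vapply(per_locus, function(r) if (isTRUE(r$informative)) r$p else NA_real_,
               numeric(1))
  informative <- !is.na(ps)
  combined <- if (any(informative)) combine_pvalues_fisher(ps[informative]) else NA_real_
  structure(list(per_locus = per_locus, combined_p = combined, config = config),
            class = "ba_gtest")
}

#' @export
print.ba_gtest <- function(x, ...) {
  cat("<genic differentiation (exact test)>\n")
  for (ln in names(x$per_locus)) {
    r <- x$per_locus[[ln]]
    if (!isTRUE(r$informative)) {
      cat(sprintf("  %s: uninformative (monomorphic)\n", ln))
    } else if (r$method == "enumeration") {
      cat(sprintf("  %s: p = %.4g (full enumeration)\n", ln, r$p))
    } else {
      cat(sprintf("  %s: p = %.4g (MC, se = %.2g)\n", ln, r$p, r$se))
    }
  }
  cat(sprintf("  combined (Fisher): p = %.4g\n", x$combined_p))
  invisible(x)
}
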