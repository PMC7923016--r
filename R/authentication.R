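#' Allele-frequency differential between the target breed and a comparison
#' population
#'
#' The basis of the per-locus mis-assignment error rates. The target breed's
#' breed-specific alleles (for Mora Romagnola: `E+` and `e` at MC1R, `T` at
#' NR6A1) must carry essentially all of the target's frequency mass — the
#' post-culling premise sum(target over target_alleles) = 1.
#'
#' Modes:
#' * `"combined"` — the differential of the summed frequencies. Since the
#'   target sum is 1 by premise, it equals `|1 - sum(other over
#'   target_alleles)|`.
#' * `"per_allele_average"` / `"per_allele_range"` — per-allele
#'   differentials `|target(a) - other(a)|`, summarised as their mean
#'   (`value`), with the individual values and their range always attached.
#'   Used when the comparison population itself carries the target alleles
#'   at high frequency (wild boar, Duroc), where the combined differential
#'   degenerates towards 0.
#'
#' @param target,other named numeric allele-frequency vectors.
#' @param target_alleles character vector of the target breed's
#'   breed-specific alleles.
#' @param mode one of `"combined"`, `"per_allele_average"`,
#'   `"per_allele_range"`.
#' @param premise_tol allowed deviation of the target's summed frequency
#'   from 1 (default 0.002, accommodating printed-table rounding drift).
#' @return an object of class `"ba_delta"`: list with `mode`, `value` (in
#'   \[0, 1\]), `per_allele_values`, `range`.
#' @examples
#' mr <- c(`E+` = 0.192, e = 0.809)
#' wb <- c(`E+` = 0.925, e = 0.022, ED2 = 0.004, EP = 0.049)
#' delta_differential(mr, wb, c("E+", "e"), "combined")$value           # 0.053
#' delta_differential(mr, wb, c("E+", "e"), "per_allele_average")$value # 0.760
#' @export
delta_differential <- function(target, other, target_alleles,
                               mode = c("combined", "per_allele_average",
                                        "per_allele_range"),
                               premise_tol = 0.002) {
  mode <- match.arg(mode)
  miss <- setdiff(target_alleles, names(target))
  if (length(miss)) stop_validation("target frequencies missing allele '%s'", miss[1])
  s_target <- sum(target[target_alleles])
  if (abs(s_target - 1) > premise_tol) {
    stop_validation(
      "target frequencies over the target alleles sum to %.4f, not 1 (tolerance %.3f): the culling premise does not hold",
      s_target, premise_tol)
  }
  getf <- function(v, a) if (a %in% names(v)) v[[a]] else 0
  o <- vapply(target_alleles, getf, numeric(1), v = other)
  if (mode == "combined") {
    value <- abs(1 - sum(o))
    per <- NULL; rng <- NULL
  } else {
    t <- vapply(target_alleles, getf, numeric(1), v = target)
    per <- abs(t - o)
    rng <- range(per)
    value <- mean(per)
  }
  structure(list(mode = mode, value = value, per_allele_values = per, range = rng),
            class = "ba_delta")
}

#' Per-locus mis-assignment error rate
#'
#' The probability of incorrectly accepting a sample from the comparison
#' population at one locus: `ER = 1 - |delta|`.
#'
#' @param delta a `"ba_delta"` or a plain differential value in \[0, 1\].
#' @return error rate in \[0, 1\].
#' @export
error_rate <- function(delta) {
  v <- if (inherits(delta, "ba_delta")) delta$value else as.numeric(delta)
  if (is.na(v) || v < 0 || v > 1) stop_validation("delta must lie in [0, 1]")
  1 - v
}

#' Combined two-locus error rate
#'
#' Product rule over the two marker loci: `ERc = ER(MC1R) * ER(NR6A1)`.
#'
#' @param er_a,er_b per-locus error rates in \[0, 1\].
#' @return combined error rate.
#' @export
combined_error_rate <- function(er_a, er_b) {
  if (any(c(er_a, er_b) < 0 | c(er_a, er_b) > 1)) {
    stop_validation("error rates must lie in [0, 1]")
  }
  er_a * er_b
}

#' Probability of correctly assigning a target-breed sample
#'
#' One minus the frequency of occurrence, in the comparison population, of
#' animals whose genotype belongs to the target breed's allowed set. Uses
#' observed genotype frequencies (never Hardy-Weinberg imputation).
#'
#' @param other_genotype_freqs named numeric vector of observed genotype
#'   frequencies (canonical `"a/b"` keys) in the comparison population.
#' @param target_genotypes character vector of the target breed's allowed
#'   genotypes at the locus.
#' @return probability in \[0, 1\].
#' @examples
#' assignment_probability(c("e/e" = 1), c("e/e", "E+/e", "E+/E+"))  # 0
#' @export
assignment_probability <- function(other_genotype_freqs, target_genotypes) {
  s <- sum(other_genotype_freqs)
  if (abs(s - 1) > 0.002) {
    stop_validation("genotype frequencies must sum to 1 (got %.4f)", s)
  }
  keys <- geno_key(names(other_genotype_freqs))
  allowed <- geno_key(target_genotypes)
  1 - sum(other_genotype_freqs[keys %in% allowed])
}

#' Authenticate a meat sample's genotype against a breed standard
#'
#' A sample is consistent with the target breed iff its genotype at every
#' standard locus belongs to the allowed set (for the shipped Mora
#' Romagnola standard: MC1R in \{e/e, E+/e, E+/E+\} and NR6A1 = T/T). A
#' consistent verdict is necessary, not sufficient: Duroc meat carries
#' e/e + T/T and is indistinguishable by this two-marker panel, which the
#' verdict notes.
#'
#' @param mc1r,nr6a1 genotype strings (any allele order), or `NA` if not
#'   called.
#' @param standard a `"ba_standard"`; default [mora_romagnola_standard()].
#' @return an object of class `"ba_verdict"`: list with `verdict`
#'   (`"consistent"`, `"inconsistent"` or `"indeterminate"`), per-locus
#'   results and `caveat`.
#' @examples
#' authenticate_sample("E+/e", "T/T")$verdict  # "consistent"
#' authenticate_sample("EP/e", "T/T")$verdict  # "inconsistent"
#' @export
authenticate_sample <- function(mc1r, nr6a1, standard = mora_romagnola_standard()) {
  observed <- list(MC1R = mc1r, NR6A1 = nr6a1)
  per_locus <- list()
  verdict <- "consistent"
  for (ln in names(standard$allowed_genotypes)) {
    g <- observed[[ln]]
    if (is.null(g) || is.na(g)) {
      per_locus[[ln]] <- "missing"
      verdict <- "indeterminate"
      next
    }
    key <- geno_key(g)
    alleles <- as.vector(geno_split(key))
    check_allele(alleles, standard$loci[[ln]], where = "sample genotype")
    ok <- key %in% standard$allowed_genotypes[[ln]]
    per_locus[[ln]] <- if (ok) "allowed" else "not allowed"
    if (!ok && verdict != "indeterminate") verdict <- "inconsistent"
  }
  if (any(vapply(per_locus, identical, logical(1), "not allowed"))) verdict <- "inconsistent"
  caveat <- if (verdict == "consistent")
    "a consistent genotype does not exclude Duroc origin (Duroc is fixed for e/e and T/T)"
  else NA_character_
  structure(list(verdict = verdict, per_locus = per_locus, caveat = caveat),
            class = "ba_verdict")
}

#' @export
print.ba_verdict <- function(x, ...) {
  cat(sprintf("<authentication verdict> %s\n", x$verdict))
  for (ln in names(x$per_locus)) cat(sprintf("  %s: %s\n", ln, x$per_locus[[ln]]))
  if (!is.na(x$caveat)) cat("  note:", x$caveat, "\n")
  invisible(x)
}

#' Authentication summary table (|delta|, ER, ERc, PMR) against a panel
#'
#' Builds, for every population in the frequency table other than the
#' target breed, the full row of authentication statistics:
#' per-locus |delta| differentials, per-locus error rates, the combined
#' error rate, and (where genotype data allow) the correct-assignment
#' probabilities.
#'
#' Mode selection for the MC1R differential: combined mode by default;
#' per-allele average when the comparison population's summed frequency
#' over the target alleles exceeds `switch_threshold` (wild boar, Duroc),
#' where the combined differential degenerates towards 0. Both variants are
#' always reported.
#'
#' PMR uses observed genotype frequencies: supplied per-breed
#' [genotype_count_table()]s if given, otherwise derivable only for
#' populations fixed at the locus (single allele at frequency 1, whose
#' genotype distribution is degenerate); otherwise `NA`.
#'
#' In `"published_parity"` mode all arithmetic is carried out on
#' frequencies rounded to 3 decimals and reported values are rounded
#' half-up to 3 decimals, matching how printed tables are internally
#' consistent; `"full"` keeps full precision and is the default for data
#' derived from counts.
#'
#' @param freq_table a `"ba_freq_table"` containing the target breed.
#' @param target target breed name.
#' @param genotype_tables optional named list of `"ba_counts"` per
#'   comparison breed for PMR.
#' @param rounding `"full"` or `"published_parity"`.
#' @param standard the breed standard supplying allowed genotypes (PMR) and
#'   loci.
#' @param target_alleles named list: locus -> target breed-specific alleles.
#' @param switch_threshold combined-to-per-allele switch point.
#' @return data frame of class `"ba_auth_summary"`, one row per comparison
#'   population with columns `breed`, `n`, `delta_mc1r` (mode actually
#'   used), `delta_mode`, `delta_mc1r_combined`, `delta_mc1r_avg`,
#'   `delta_nr6a1`, `er_mc1r`, `er_nr6a1`, `erc`, `erc_combined`,
#'   `pmr_mc1r`, `pmr_nr6a1`.
#' @export
build_summary_table <- function(freq_table, target = "Mora Romagnola",
                                genotype_tables = NULL,
                                rounding = c("full", "published_parity"),
                                standard = mora_romagnola_standard(),
                                target_alleles = list(MC1R = c("E+", "e"),
                                                      NR6A1 = "T"),
                                switch_threshold = 0.90) {
  rounding <- match.arg(rounding)
  breeds <- freq_breeds(freq_table)
  if (!target %in% breeds) stop_validation("target breed '%s' not in frequency table", target)
  rnd_in <- function(x) if (rounding == "published_parity") round_half_up(x, 3) else x
  rnd_out <- function(x) if (rounding == "published_parity") round_half_up(x, 3) else x
  t_mc1r <- rnd_in(freq_vector(freq_table, target, "MC1R"))
  t_nr <- rnd_in(freq_vector(freq_table, target, "NR6A1"))
  rows <- list()
  for (breed in setdiff(breeds, target)) {
    o_mc1r <- freq_vector(freq_table, breed, "MC1R")
    n_breed <- attr(o_mc1r, "n")
    o_mc1r <- rnd_in(o_mc1r)
    o_nr <- rnd_in(freq_vector(freq_table, breed, "NR6A1"))
    d_comb <- delta_differential(t_mc1r, o_mc1r, target_alleles$MC1R, "combined")
    d_avg <- delta_differential(t_mc1r, o_mc1r, target_alleles$MC1R, "per_allele_average")
    sum_other <- sum(o_mc1r[intersect(target_alleles$MC1R, names(o_mc1r))])
    mode <- if (sum_other > switch_threshold) "per_allele_average" else "combined"
    d_used <- if (mode == "combined") d_comb else d_avg
    d_nr <- delta_differential(t_nr, o_nr, target_alleles$NR6A1, "combined")
    # error rates and products are carried at full precision and rounded
    # only on report, so ER = 1 - delta and ERc = ER * ER agree with the
    # printed tables' internal consistency (e.g. 1 - 0.1915 -> 0.809)
    er_m <- error_rate(d_used)
    er_n <- error_rate(d_nr)
    erc <- combined_error_rate(er_m, er_n)
    erc_comb <- combined_error_rate(error_rate(d_comb), er_n)
    pmr <- vapply(c("MC1R", "NR6A1"), function(ln) {
      ofreq <- NULL
      if (!is.null(genotype_tables) && breed %in% names(genotype_tables)) {
        ofreq <- genotype_frequencies(genotype_tables[[breed]], ln)
      } else {
        fv <- freq_vector(freq_table, breed, ln)
        fixed <- names(fv)[fv >= 1 - 1e-9]
        if (length(fixed) == 1) ofreq <- stats::setNames(1, paste(fixed, fixed, sep = "/"))
      }
      if (is.null(ofreq)) return(NA_real_)
      rnd_out(assignment_probability(ofreq, standard$allowed_genotypes[[ln]]))
    }, numeric(1))
    rows[[breed]] <- data.frame(
      breed = breed, n = n_breed %||% NA_integer_,
      delta_mc1r = rnd_out(d_used$value), delta_mode = mode,
      delta_mc1r_combined = rnd_out(d_comb$value),
      delta_mc1r_avg = rnd_out(d_avg$value),
      delta_mc1r_min = rnd_out(d_avg$range[1]),
      delta_mc1r_max = rnd_out(d_avg$range[2]),
      delta_nr6a1 = rnd_out(d_nr$value),
      er_mc1r = rnd_out(er_m), er_nr6a1 = rnd_out(er_n),
      erc = rnd_out(erc), erc_combined = rnd_out(erc_comb),
      pmr_mc1r = pmr[["MC1R"]], pmr_nr6a1 = pmr[["NR6A1"]],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "rounding") <- rounding
  attr(out, "target") <- target
  class(out) <- c("ba_auth_summary", "data.frame")
  out
}
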