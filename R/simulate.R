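#' Specify a multi-breed genotype simulation
#'
#' Describes the populations to simulate: per breed, the number of adult
#' breeding animals (and optionally young pigs), and per-locus allele
#' frequencies from which diploid genotypes are drawn under random mating
#' (Hardy-Weinberg proportions). Phenotype fields are drawn per age class:
#' adults carry the standard phenotype; young pigs show the transient
#' non-standard values at the class-specific rates (defaults: red coat
#' 8.9%, half-hanging/raised ears 11%, absent dorsal mane 9%, the rates
#' observed in the monitored herd).
#'
#' @param breeds named list: breed -> list with `n` (adults), optional
#'   `n_young`, and `freqs` (named list locus -> named frequency vector
#'   summing to 1).
#' @param phenotype_rates list with elements `young` (named vector
#'   `red`, `nonstandard_ears`, `absent_linea`).
#' @param seed integer seed (mandatory).
#' @param loci locus definitions.
#' @return an object of class `"ba_sim_spec"`.
#' @export
simulation_spec <- function(breeds, phenotype_rates = NULL, seed, loci = default_loci()) {
  if (missing(seed)) stop_validation("a seed is mandatory in a simulation spec")
  phenotype_rates <- phenotype_rates %||%
    list(young = c(red = 0.089, nonstandard_ears = 0.11, absent_linea = 0.09))
  ry <- phenotype_rates$young
  if (any(ry < 0 | ry > 1)) stop_validation("phenotype rates must lie in [0, 1]")
  for (b in names(breeds)) {
    sp <- breeds[[b]]
    if (is.null(sp$n) || sp$n < 0) stop_validation("breed '%s': n must be >= 0", b)
    for (ln in names(sp$freqs)) {
      f <- sp$freqs[[ln]]
      if (any(f < 0)) stop_validation("breed '%s', locus %s: negative frequency", b, ln)
      if (abs(sum(f) - 1) > 1e-6) {
        stop_validation("breed '%s', locus %s: frequencies sum to %.4f, not 1", b, ln, sum(f))
      }
      check_allele(names(f), loci[[ln]], where = sprintf("simulation spec for %s", b))
    }
  }
  structure(list(breeds = breeds, phenotype_rates = phenotype_rates,
                 seed = as.integer(seed), loci = loci),
            class = "ba_sim_spec")
}

#' Simulate a population of diploid genotypes under Hardy-Weinberg
#' proportions
#'
#' For each animal and locus the two alleles are drawn independently from
#' the breed's allele-frequency vector. The draw is deterministic given the
#' spec's seed (each breed uses a sub-stream derived from the seed and the
#' breed's position in the spec), and the global RNG state is left
#' untouched.
#'
#' @param spec a [simulation_spec()].
#' @param breed breed name present in the spec.
#' @return a [population_sample()].
#' @examples
#' sp <- simulation_spec(list(MR = list(n = 50, freqs = list(
#'   MC1R = c(`E+` = 0.192, e = 0.808), NR6A1 = c(T = 1)))), seed = 1)
#' simulate_population(sp, "MR")
#' @export
simulate_population <- function(spec, breed) {
  bs <- spec$breeds[[breed]]
  if (is.null(bs)) stop_validation("breed '%s' not in simulation spec", breed)
  idx <- match(breed, names(spec$breeds))
  n_adult <- as.integer(bs$n)
  n_young <- as.integer(bs$n_young %||% 0)
  n <- n_adult + n_young
  with_local_seed(spec$seed + 7919L * idx, {
    cls <- c(rep(c("boar", "sow"), length.out = n_adult), rep("young", n_young))
    df <- data.frame(
      animal_id = sprintf("%s_%04d", gsub("[^A-Za-z0-9]", "", breed), seq_len(n)),
      breed = breed, class = cls, stringsAsFactors = FALSE)
    for (ln in names(spec$loci)) {
      f <- bs$freqs[[ln]]
      if (is.null(f)) {
        df[[paste0(ln, "_a1")]] <- NA_character_
        df[[paste0(ln, "_a2")]] <- NA_character_
        next
      }
      draws <- sample(names(f), 2 * n, replace = TRUE, prob = f)
      df[[paste0(ln, "_a1")]] <- draws[seq_len(n)]
      df[[paste0(ln, "_a2")]] <- draws[n + seq_len(n)]
    }
    ry <- spec$phenotype_rates$young
    young <- df$class == "young"
    df$coat_colour <- ifelse(young & stats::runif(n) < ry[["red"]], "red", "black_and_tan")
    ear_draw <- stats::runif(n)
    df$ears <- ifelse(young & ear_draw < ry[["nonstandard_ears"]],
                      ifelse(ear_draw < ry[["nonstandard_ears"]] / 2, "half_hanging", "raised"),
                      "bent_forward_parallel")
    df$linea_sparta <- ifelse(young & stats::runif(n) < ry[["absent_linea"]],
                              "absent", "present")
    population_sample(breed, df, spec$loci)
  })
}

#' Simulation spec mirroring the published breed panel
#'
#' Builds a [simulation_spec()] whose breeds, sample sizes and allele
#' frequencies are the shipped allele-frequency panel (13 populations),
#' enabling simulation of the whole study layout from one object.
#'
#' @param seed integer seed.
#' @return a `"ba_sim_spec"`.
#' @export
panel_simulation_spec <- function(seed) {
  ft <- mora_fixture("table2_panel")
  breeds <- list()
  for (b in freq_breeds(ft)) {
    freqs <- list()
    for (ln in unique(ft$locus)) {
      f <- freq_vector(ft, b, ln)
      f <- f[f > 0]
      freqs[[ln]] <- f / sum(f)  # renormalise printed rounding drift
    }
    breeds[[b]] <- list(n = attr(freq_vector(ft, b, "MC1R"), "n"), freqs = freqs)
  }
  simulation_spec(breeds, seed = seed)
}
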