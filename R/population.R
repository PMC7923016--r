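#' Build a population sample of diploid genotype records
#'
#' A population sample couples a name with a data frame of animal records and
#' the locus definitions the genotype columns refer to. The data frame must
#' carry `animal_id`, `breed`, `class` (one of `boar`, `sow`, `young`) and,
#' for every locus `L` in `loci`, the two allele columns `L_a1` and `L_a2`.
#' A genotype is missing when both allele columns are `NA`; a half-missing
#' genotype is rejected. Optional phenotype columns are `coat_colour`
#' (`black_and_tan`, `red`, `other`), `ears` (`bent_forward_parallel`,
#' `half_hanging`, `raised`, `other`) and `linea_sparta` (`present`,
#' `absent`), the dorsal bristle mane.
#'
#' @param name population/breed label.
#' @param data data frame of animal records as described above.
#' @param loci named list of [locus()] definitions.
#' @return an object of class `"ba_population"`.
#' @export
population_sample <- function(name, data, loci = default_loci()) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  req <- c("animal_id", "breed", "class")
  miss <- setdiff(req, names(data))
  if (length(miss)) stop_validation("missing required column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(data$animal_id)) {
    stop_validation("duplicated animal_id: %s", data$animal_id[duplicated(data$animal_id)][1])
  }
  bad_class <- setdiff(unique(data$class), c("boar", "sow", "young"))
  if (length(bad_class)) stop_validation("unknown class value '%s'", bad_class[1])
  if (is.null(names(loci)) || any(!nzchar(names(loci)))) {
    names(loci) <- vapply(loci, function(l) l$name, character(1))
  }
  for (lname in names(loci)) {
    loc <- loci[[lname]]
    c1 <- paste0(lname, "_a1"); c2 <- paste0(lname, "_a2")
    if (!all(c(c1, c2) %in% names(data))) {
      stop_validation("missing allele columns %s/%s for locus %s", c1, c2, lname)
    }
    a1 <- data[[c1]]; a2 <- data[[c2]]
    half <- xor(is.na(a1), is.na(a2))
    if (any(half)) {
      stop_validation("row %d: half-missing genotype at locus %s (mark both alleles missing)",
                      which(half)[1], lname)
    }
    for (i in which(!is.na(a1))) {
      for (al in c(a1[i], a2[i])) {
        if (!(al %in% loc$alleles)) {
          stop_validation("row %d (animal %s): allele '%s' is not defined for locus %s",
                          i, data$animal_id[i], al, lname)
        }
      }
    }
  }
  for (ph in c("coat_colour", "ears", "linea_sparta")) {
    if (!ph %in% names(data)) data[[ph]] <- NA_character_
  }
  ok <- list(coat_colour = c("black_and_tan", "red", "other"),
             ears = c("bent_forward_parallel", "half_hanging", "raised", "other"),
             linea_sparta = c("present", "absent"))
  for (ph in names(ok)) {
    bad <- setdiff(unique(data[[ph]][!is.na(data[[ph]])]), ok[[ph]])
    if (length(bad)) stop_validation("unknown %s value '%s'", ph, bad[1])
  }
  rownames(data) <- NULL
  structure(list(name = name, data = data, loci = loci), class = "ba_population")
}

#' @export
print.ba_population <- function(x, ...) {
  cat(sprintf("<population> %s: %d animals, loci: %s\n",
              x$name, nrow(x$data), paste(names(x$loci), collapse = ", ")))
  invisible(x)
}

#' Number of animals in a sample
#' @param sample a `"ba_population"`.
#' @return integer count.
#' @export
n_animals <- function(sample) nrow(sample$data)

# Subset a population sample by animal ids, preserving class and loci.
subset_sample <- function(sample, ids) {
  keep <- sample$data$animal_id %in% ids
  population_sample(sample$name, sample$data[keep, , drop = FALSE], sample$loci)
}

# Canonical genotype keys for one locus (NA for missing).
sample_genotypes <- function(sample, lname) {
  geno(sample$data[[paste0(lname, "_a1")]], sample$data[[paste0(lname, "_a2")]])
}
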