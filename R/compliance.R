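#' Call an MC1R (Extension-locus) allele from PCR-RFLP patterns
#'
#' Implements the published restriction-assay decision tree for the five
#' major Extension alleles, from already-scored cut/uncut band states:
#' * *HhaI* (GCGC) cuts every allele except `e`;
#' * *BstUI* (CGCG) cuts every allele except `e` and `ED1`;
#' * *BspHI* (TCATGA) cuts `ED2` and `EP` but not `E+`;
#' * the CC indel fragment length separates `ED2` (168 bp) from `EP` (170 bp).
#'
#' The tree is consulted in that order: HhaI uncut calls `e`; otherwise an
#' uncut BstUI calls `ED1`; otherwise an uncut BspHI calls `E+`; otherwise
#' the indel fragment decides `ED2` vs `EP`. Assay states the reached branch
#' needs must be known, and any supplied state that contradicts the called
#' allele's published pattern raises an inconsistency error. BspHI behaviour
#' on `e`/`ED1` and indel lengths outside the two published values are not
#' part of the published truth table and are never consulted for those
#' alleles.
#'
#' @param hhai,bstui,bsphi restriction states: `"cut"`, `"uncut"` or
#'   `"unknown"`.
#' @param indel_bp indel fragment length in bp (168 or 170), or `NA`.
#' @return single allele code (character).
#' @examples
#' call_mc1r_allele(hhai = "uncut")                                  # "e"
#' call_mc1r_allele(hhai = "cut", bstui = "cut", bsphi = "uncut")    # "E+"
#' @export
call_mc1r_allele <- function(hhai = "unknown", bstui = "unknown",
                             bsphi = "unknown", indel_bp = NA) {
  st <- function(x, nm) {
    x <- match.arg(x, c("unknown", "cut", "uncut"))
    x
  }
  hhai <- st(hhai); bstui <- st(bstui); bsphi <- st(bsphi)
  if (!is.na(indel_bp) && !indel_bp %in% c(168, 170)) {
    stop_validation("indel fragment of %s bp is outside the published truth table (168/170)",
                    format(indel_bp))
  }
  if (hhai == "unknown" && bstui == "unknown" && bsphi == "unknown" && is.na(indel_bp)) {
    stop_validation("at least one assay result is required for a call attempt")
  }
  # published truth table (NA = behaviour unstated, never checked)
  truth <- list(
    `e`   = list(hhai = "uncut", bstui = "uncut", bsphi = NA,      indel = NA),
    `ED1` = list(hhai = "cut",   bstui = "uncut", bsphi = NA,      indel = NA),
    `E+`  = list(hhai = "cut",   bstui = "cut",   bsphi = "uncut", indel = NA),
    `ED2` = list(hhai = "cut",   bstui = "cut",   bsphi = "cut",   indel = 168),
    `EP`  = list(hhai = "cut",   bstui = "cut",   bsphi = "cut",   indel = 170))
  need <- function(x, assay) {
    if (x == "unknown") {
      stop_validation("ambiguous call: the %s assay result is required at this branch", assay)
    }
    x
  }
  allele <-
    if (need(hhai, "HhaI") == "uncut") "e"
    else if (need(bstui, "BstUI") == "uncut") "ED1"
    else if (need(bsphi, "BspHI") == "uncut") "E+"
    else {
      if (is.na(indel_bp)) {
        stop_validation("ambiguous call: the CC-indel fragment length is required at this branch")
      }
      if (indel_bp == 168) "ED2" else "EP"
    }
  tt <- truth[[allele]]
  for (assay in c("hhai", "bstui", "bsphi")) {
    obs <- get(assay)
    if (obs != "unknown" && !is.na(tt[[assay]]) && obs != tt[[assay]]) {
      stop_validation("inconsistent pattern: %s=%s contradicts the published pattern of allele %s",
                      assay, obs, allele)
    }
  }
  if (!is.na(indel_bp) && !is.na(tt$indel) && indel_bp != tt$indel) {
    stop_validation("inconsistent pattern: indel %d bp contradicts allele %s", indel_bp, allele)
  }
  allele
}

#' Call an NR6A1 allele from the MspI PCR-RFLP pattern
#'
#' *MspI* cuts the 203-bp amplicon when the wild-type allele (`C`) is
#' present; an uncut fragment carries the domestic allele (`T`).
#'
#' @param mspi_cut `"cut"`, `"uncut"` or `"unknown"`.
#' @return `"C"` or `"T"`.
#' @export
call_nr6a1_allele <- function(mspi_cut) {
  mspi_cut <- match.arg(mspi_cut, c("unknown", "cut", "uncut"))
  if (mspi_cut == "unknown") {
    stop_validation("ambiguous call: the MspI assay result is required")
  }
  if (mspi_cut == "cut") "C" else "T"
}

#' Define a Herd-Book breed standard
#'
#' A breed standard couples the allowed genotypes per locus with the
#' phenotype rules by age class. Phenotype rules list, per class, the
#' tolerated values of `coat_colour`, `ears` and `linea_sparta`; traits
#' whose non-standard values are tolerated in class `young` simply list all
#' values there.
#'
#' @param allowed_genotypes named list: locus -> character vector of allowed
#'   genotypes (any allele order; canonicalised internally).
#' @param phenotype_rules named list: class -> list of allowed values per
#'   phenotype trait.
#' @param loci named list of [locus()] definitions.
#' @param name label for the standard.
#' @return an object of class `"ba_standard"`.
#' @seealso [mora_romagnola_standard()] for the shipped default.
#' @export
breed_standard <- function(allowed_genotypes, phenotype_rules, loci = default_loci(),
                           name = "custom") {
  if (!length(allowed_genotypes)) stop_validation("allowed_genotypes must be non-empty")
  for (ln in names(allowed_genotypes)) {
    if (!ln %in% names(loci)) stop_validation("no locus definition for '%s'", ln)
    g <- geno_key(allowed_genotypes[[ln]])
    if (!length(g)) stop_validation("allowed genotype set for %s is empty", ln)
    alleles <- unique(as.vector(geno_split(g)))
    check_allele(alleles, loci[[ln]], where = "allowed genotypes")
    allowed_genotypes[[ln]] <- g
  }
  structure(list(name = name, allowed_genotypes = allowed_genotypes,
                 phenotype_rules = phenotype_rules, loci = loci),
            class = "ba_standard")
}

#' The redefined Mora Romagnola Herd-Book standard
#'
#' Genotype descriptors added to the breed standard after the whole-herd
#' genotyping campaign: allowed MC1R genotypes `e/e`, `E+/e`, `E+/E+` and
#' allowed NR6A1 genotype `T/T`. Phenotype descriptors: adults must be black
#' and tan with ears bent forward and parallel to the muzzle and the dorsal
#' bristle mane ("Linea sparta") present; young pigs may transiently show
#' red coat, half-hanging or raised ears and an absent mane, so every value
#' is tolerated in class `young`.
#'
#' @return a `"ba_standard"` object.
#' @export
mora_romagnola_standard <- function() {
  adult <- list(coat_colour = "black_and_tan",
                ears = "bent_forward_parallel",
                linea_sparta = "present")
  young <- list(coat_colour = c("black_and_tan", "red", "other"),
                ears = c("bent_forward_parallel", "half_hanging", "raised", "other"),
                linea_sparta = c("present", "absent"))
  breed_standard(
    allowed_genotypes = list(MC1R = c("e/e", "E+/e", "E+/E+"), NR6A1 = "T/T"),
    phenotype_rules = list(boar = adult, sow = adult, young = young),
    name = "Mora Romagnola")
}

#' Read / write a breed standard as a YAML config
#'
#' @param path file path.
#' @param loci locus definitions for validation.
#' @return `read_breed_standard()` returns a `"ba_standard"`;
#'   `write_breed_standard()` returns `path` invisibly.
#' @export
read_breed_standard <- function(path, loci = default_loci()) {
  cfg <- yaml::read_yaml(path)
  breed_standard(cfg$allowed_genotypes, cfg$phenotype_rules, loci = loci,
                 name = cfg$name %||% "config")
}

#' @rdname read_breed_standard
#' @param standard a `"ba_standard"`.
#' @export
write_breed_standard <- function(standard, path) {
  yaml::write_yaml(list(name = standard$name,
                        allowed_genotypes = standard$allowed_genotypes,
                        phenotype_rules = standard$phenotype_rules), path)
  invisible(path)
}

#' Check one animal record against a breed standard
#'
#' Rules are evaluated in fixed precedence — phenotype first, then MC1R,
#' then the remaining genotype loci — mirroring the two-stage
#' phenotyping-then-genotyping workflow. An animal failing several rules
#' records all reasons but its primary reason (used for counting) is the
#' first in precedence. Phenotype traits whose values are tolerated for the
#' animal's class are recorded but never grounds for exclusion; a missing
#' genotype at a standard locus makes the status `indeterminate` rather
#' than excluded.
#'
#' @param record single-row data frame (one animal) in
#'   [population_sample()] column layout.
#' @param standard a `"ba_standard"`.
#' @return list with `status` (`"retained"`, `"excluded"`,
#'   `"indeterminate"`), `reasons` (character vector, possibly empty) and
#'   `primary_reason`.
#' @export
check_record <- function(record, standard) {
  reasons <- character(0)
  cls <- record$class
  rules <- standard$phenotype_rules[[cls]]
  if (is.null(rules)) stop_validation("no phenotype rules for class '%s'", cls)
  trait_reason <- c(coat_colour = "phenotype_coat", ears = "phenotype_ears",
                    linea_sparta = "phenotype_linea_sparta")
  for (trait in names(trait_reason)) {
    val <- record[[trait]]
    if (!is.null(val) && !is.na(val) && !(val %in% rules[[trait]])) {
      reasons <- c(reasons, trait_reason[[trait]])
    }
  }
  indeterminate <- FALSE
  for (ln in names(standard$allowed_genotypes)) {
    g <- geno(record[[paste0(ln, "_a1")]], record[[paste0(ln, "_a2")]])
    if (is.na(g)) { indeterminate <- TRUE; next }
    if (!(g %in% standard$allowed_genotypes[[ln]])) {
      reasons <- c(reasons, paste0("genotype_", ln))
    }
  }
  status <- if (length(reasons)) "excluded" else if (indeterminate) "indeterminate" else "retained"
  list(status = status, reasons = reasons,
       primary_reason = if (length(reasons)) reasons[1] else NA_character_)
}

#' Apply the Herd-Book filter to a population sample
#'
#' Partitions a sample into retained and excluded animals under a breed
#' standard, with machine-readable reasons and one primary reason per
#' excluded animal (so that multi-rule animals are not double counted).
#' Animals with a missing genotype at a standard locus and no failed rule
#' are listed as indeterminate, separate from both groups.
#'
#' @param sample a [population_sample()].
#' @param standard a `"ba_standard"`; default [mora_romagnola_standard()].
#' @return an object of class `"ba_compliance"`: list with `retained`
#'   (animal ids), `excluded` (data frame `animal_id`, `primary_reason`,
#'   `reasons`), `indeterminate` (ids), `counts` (named integer vector per
#'   primary reason), and `retained_sample` (a [population_sample()] of the
#'   retained animals, for downstream frequency recomputation).
#' @examples
#' \dontrun{
#' rep <- apply_herdbook_filter(mora_fixture("table1_mora"))
#' rep$counts  # phenotype_coat 1, genotype_MC1R 12, genotype_NR6A1 2
#' }
#' @export
apply_herdbook_filter <- function(sample, standard = mora_romagnola_standard()) {
  if (n_animals(sample) == 0) stop_validation("sample is empty")
  df <- sample$data
  status <- character(nrow(df)); primary <- character(nrow(df)); all_r <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    res <- check_record(df[i, , drop = FALSE], standard)
    status[i] <- res$status
    primary[i] <- res$primary_reason
    all_r[i] <- paste(res$reasons, collapse = ";")
  }
  excluded <- data.frame(animal_id = df$animal_id[status == "excluded"],
                         primary_reason = primary[status == "excluded"],
                         reasons = all_r[status == "excluded"],
                         stringsAsFactors = FALSE)
  counts <- table(factor(excluded$primary_reason,
                         levels = c("phenotype_coat", "phenotype_ears",
                                    "phenotype_linea_sparta",
                                    paste0("genotype_", names(standard$allowed_genotypes)))))
  retained_ids <- df$animal_id[status == "retained"]
  structure(list(
    standard = standard$name,
    retained = retained_ids,
    excluded = excluded,
    indeterminate = df$animal_id[status == "indeterminate"],
    counts = c(counts),
    retained_sample = subset_sample(sample, retained_ids)),
    class = "ba_compliance")
}

#' @export
print.ba_compliance <- function(x, ...) {
  cat(sprintf("<compliance report> standard: %s\n", x$standard))
  cat(sprintf("  retained: %d  excluded: %d  indeterminate: %d\n",
              length(x$retained), nrow(x$excluded), length(x$indeterminate)))
  nz <- x$counts[x$counts > 0]
  if (length(nz)) {
    cat("  exclusions by primary reason:\n")
    for (r in names(nz)) cat(sprintf("    %s: %d\n", r, nz[[r]]))
  }
  invisible(x)
}

#' Write a compliance report to disk
#'
#' Emits a per-animal CSV (`animal_id,status,reasons`) and a JSON summary.
#'
#' @param report a `"ba_compliance"`.
#' @param csv_path,json_path output paths (`NULL` to skip either).
#' @return invisibly, a list of the paths written.
#' @export
write_compliance_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    grp <- function(ids, status, reasons = rep("", length(ids))) {
      data.frame(animal_id = ids, status = rep(status, length(ids)),
                 reasons = reasons, stringsAsFactors = FALSE)
    }
    rows <- rbind(
      grp(report$retained, "retained"),
      grp(report$excluded$animal_id, "excluded", report$excluded$reasons),
      grp(report$indeterminate, "indeterminate"))
    utils::write.table(rows, csv_path, sep = ",", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(standard = report$standard,
                              n_retained = length(report$retained),
                              n_excluded = nrow(report$excluded),
                              n_indeterminate = length(report$indeterminate),
                              counts = as.list(report$counts)),
                         json_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(list(csv = csv_path, json = json_path))
}
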