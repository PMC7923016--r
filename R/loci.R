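#' Define a marker locus
#'
#' A locus is a short name plus the ordered set of allele codes it can carry,
#' with optional free-text variant descriptors (e.g. the genomic or protein
#' change the assay targets).
#'
#' @param name short locus identifier (e.g. `"MC1R"`).
#' @param alleles character vector of allele codes, unique, at least one;
#'   a polymorphic locus needs at least two.
#' @param meta optional character vector of variant descriptors.
#' @return an object of class `"ba_locus"`.
#' @examples
#' locus("NR6A1", c("C", "T"), meta = "g.299084751C>T (p.P192L)")
#' @export
locus <- function(name, alleles, meta = character()) {
  if (!is.character(name) || length(name) != 1 || !nzchar(name)) {
    stop_validation("locus `name` must be a non-empty string")
  }
  alleles <- as.character(alleles)
  if (length(alleles) < 1 || any(!nzchar(alleles)) || anyNA(alleles)) {
    stop_validation("locus '%s': allele codes must be non-empty strings", name)
  }
  if (anyDuplicated(alleles)) {
    stop_validation("locus '%s': allele codes must be unique", name)
  }
  structure(list(name = name, alleles = alleles, meta = as.character(meta)),
            class = "ba_locus")
}

#' @export
print.ba_locus <- function(x, ...) {
  cat("<locus> ", x$name, ": ", paste(x$alleles, collapse = ", "), "\n", sep = "")
  if (length(x$meta)) cat("  ", paste(x$meta, collapse = "; "), "\n", sep = "")
  invisible(x)
}

#' Extension-locus (MC1R) definition
#'
#' The five major alleles at the porcine *Extension* coat-colour locus:
#' wild type `E+`, the dominant-black alleles `ED1` (Asian origin) and
#' `ED2` (European origin), `EP` (spotted/white breeds) and the recessive
#' red allele `e` fixed in Duroc.
#'
#' @return a `"ba_locus"` object.
#' @export
locus_mc1r <- function() {
  locus("MC1R", c("E+", "ED1", "ED2", "EP", "e"),
        meta = c("c.367G>A", "c.727G>A", "c.729G>A", "CC indel at c.67"))
}

#' NR6A1 vertebral-number locus definition
#'
#' The missense variant g.299084751C>T (p.P192L): `T` is the domestic allele
#' associated with increased vertebral number; wild boars carry `C`.
#'
#' @return a `"ba_locus"` object.
#' @export
locus_nr6a1 <- function() {
  locus("NR6A1", c("C", "T"), meta = "g.299084751C>T (p.P192L)")
}

#' Default two-marker panel
#'
#' @return named list of the MC1R and NR6A1 locus definitions.
#' @export
default_loci <- function() {
  list(MC1R = locus_mc1r(), NR6A1 = locus_nr6a1())
}

#' Canonical genotype key
#'
#' Genotypes are unordered allele pairs: `geno("e", "E+")` and
#' `geno("E+", "e")` denote the same diploid genotype. The canonical key
#' sorts the two allele codes in C byte order and joins them with `/`.
#'
#' @param a,b allele codes (vectorised).
#' @return character vector of canonical `"a/b"` keys.
#' @examples
#' geno("e", "E+")  # "E+/e"
#' @export
geno <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (length(a) != length(b)) stop_validation("allele vectors must have equal length")
  out <- character(length(a))
  for (i in seq_along(a)) {
    if (is.na(a[i]) || is.na(b[i])) { out[i] <- NA_character_; next }
    pair <- sort_c(c(a[i], b[i]))
    out[i] <- paste(pair, collapse = "/")
  }
  out
}

# Canonicalise a "x/y" genotype string (possibly unordered).
geno_key <- function(g) {
  if (length(g) == 0) return(character())
  vapply(g, function(s) {
    if (is.na(s)) return(NA_character_)
    parts <- strsplit(s, "/", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop_validation("malformed genotype string '%s'", s)
    geno(parts[1], parts[2])
  }, character(1), USE.NAMES = FALSE)
}

# Split canonical keys back into a 2-column allele matrix.
geno_split <- function(keys) {
  parts <- strsplit(keys, "/", fixed = TRUE)
  t(vapply(parts, function(p) p[1:2], character(2)))
}

# All distinct unordered genotypes for an allele set, canonical keys.
all_genotypes <- function(alleles) {
  alleles <- sort_c(alleles)
  k <- length(alleles)
  out <- character(0)
  for (i in seq_len(k)) for (j in i:k) out <- c(out, paste(alleles[i], alleles[j], sep = "/"))
  out
}

check_allele <- function(allele, loc, where = "") {
  bad <- !is.na(allele) & !(allele %in% loc$alleles)
  if (any(bad)) {
    stop_validation("allele '%s' is not defined for locus %s%s",
                    allele[bad][1], loc$name,
                    if (nzchar(where)) paste0(" (", where, ")") else "")
  }
  invisible(TRUE)
}
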