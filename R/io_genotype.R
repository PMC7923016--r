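#' Read a delimited genotype table
#'
#' Reads one animal record per row from a delimited text file with mandatory
#' header `animal_id,breed,class`, two allele columns `L_a1,L_a2` per locus
#' `L`, and optional phenotype columns `coat_colour,ears,linea_sparta`.
#' The missing-value token (empty field or `NA`) yields an explicitly
#' missing genotype; unknown allele symbols are rejected with the offending
#' row and locus named.
#'
#' @param path file path.
#' @param loci named list of [locus()] definitions expected in the file.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @param name population name; defaults to the single breed in the file.
#' @return a [population_sample()].
#' @export
read_genotype_table <- function(path, loci = default_loci(), sep = ",", name = NULL) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""), colClasses = "character",
                          check.names = FALSE)
  req <- c("animal_id", "breed", "class",
           as.vector(outer(names(loci), c("_a1", "_a2"), paste0)))
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop_validation("malformed header in %s: missing column(s) %s",
                    path, paste(miss, collapse = ", "))
  }
  if (is.null(name)) {
    name <- unique(df$breed)
    if (length(name) != 1) name <- "multi-breed"
  }
  population_sample(name, df, loci)
}

#' Write a delimited genotype table
#'
#' Inverse of [read_genotype_table()]; write-then-read preserves every
#' genotype count exactly.
#'
#' @param sample a [population_sample()].
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(sample, path, sep = ",") {
  utils::write.table(sample$data, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

# Deterministic 2-digit allele codes: lexicographic (C byte order) symbol order.
genepop_codes <- function(loc) {
  al <- sort_c(loc$alleles)
  if (length(al) > 99) {
    stop_validation("locus %s has %d alleles; the 2-digit GENEPOP encoding supports at most 99",
                    loc$name, length(al))
  }
  stats::setNames(sprintf("%02d", seq_along(al)), al)
}

#' Write samples in GENEPOP format
#'
#' Emits the classic GENEPOP flat format (4-digit diploid encoding, one
#' locus name per line, `Pop` separators) so that results can be
#' cross-validated with external population-genetics software. Allele codes
#' are assigned deterministically by lexicographic (C byte order) symbol
#' order and the mapping is recorded on the title line. Missing genotypes
#' are encoded `0000`.
#'
#' @param samples list of [population_sample()] objects sharing the same loci.
#' @param path output file path.
#' @param title title line content.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(samples, path, title = "breedauth export") {
  if (inherits(samples, "ba_population")) samples <- list(samples)
  loci <- samples[[1]]$loci
  for (s in samples) {
    if (!identical(names(s$loci), names(loci))) {
      stop_validation("all samples must share the same loci")
    }
  }
  codes <- lapply(loci, genepop_codes)
  legend <- paste(vapply(names(loci), function(ln) {
    paste0(ln, ":", paste(names(codes[[ln]]), codes[[ln]], sep = "=", collapse = ","))
  }, character(1)), collapse = "; ")
  lines <- c(paste0(title, " [allele codes by lexicographic symbol order: ", legend, "]"),
             names(loci))
  for (s in samples) {
    lines <- c(lines, "Pop")
    for (i in seq_len(nrow(s$data))) {
      gcodes <- vapply(names(loci), function(ln) {
        a1 <- s$data[[paste0(ln, "_a1")]][i]
        a2 <- s$data[[paste0(ln, "_a2")]][i]
        if (is.na(a1) || is.na(a2)) return("0000")
        paste0(codes[[ln]][[a1]], codes[[ln]][[a2]])
      }, character(1))
      lines <- c(lines, paste0(s$data$animal_id[i], " ,  ", paste(gcodes, collapse = " ")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a GENEPOP file written by [write_genepop()]
#'
#' Decodes the 4-digit diploid encoding back to allele symbols using the
#' same deterministic lexicographic code assignment. Populations are named
#' `pop1`, `pop2`, ... unless overridden.
#'
#' @param path GENEPOP file path.
#' @param loci named list of [locus()] definitions matching the file's loci.
#' @param names optional character vector of population names.
#' @return list of [population_sample()] objects.
#' @export
read_genepop <- function(path, loci = default_loci(), names = NULL) {
  lines <- readLines(path)
  if (length(lines) < 3) stop_validation("not a GENEPOP file: %s", path)
  body <- lines[-1]
  pop_at <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (!length(pop_at)) stop_validation("no Pop separator in %s", path)
  locus_names <- trimws(body[seq_len(pop_at[1] - 1)])
  # locus names may also be comma-separated on one line
  locus_names <- unlist(strsplit(locus_names, ",\\s*"))
  if (!identical(locus_names, base::names(loci))) {
    stop_validation("loci in file (%s) do not match supplied definitions (%s)",
                    paste(locus_names, collapse = ","), paste(base::names(loci), collapse = ","))
  }
  decode <- lapply(loci, function(l) {
    cd <- genepop_codes(l)
    stats::setNames(base::names(cd), cd)
  })
  bounds <- c(pop_at, length(body) + 1L)
  out <- vector("list", length(pop_at))
  for (p in seq_along(pop_at)) {
    rows <- body[seq(bounds[p] + 1L, bounds[p + 1L] - 1L)]
    rows <- rows[nzchar(trimws(rows))]
    recs <- lapply(rows, function(r) {
      halves <- strsplit(r, ",")[[1]]
      if (length(halves) < 2) stop_validation("malformed individual line: '%s'", r)
      id <- trimws(halves[1])
      gcodes <- strsplit(trimws(paste(halves[-1], collapse = ",")), "\\s+")[[1]]
      if (length(gcodes) != length(loci)) {
        stop_validation("individual '%s': expected %d genotype fields, got %d",
                        id, length(loci), length(gcodes))
      }
      rec <- list(animal_id = id, breed = NA_character_, class = "sow")
      for (j in seq_along(loci)) {
        ln <- base::names(loci)[j]; gc <- gcodes[j]
        if (gc == "0000") {
          rec[[paste0(ln, "_a1")]] <- NA_character_
          rec[[paste0(ln, "_a2")]] <- NA_character_
        } else {
          c1 <- substr(gc, 1, 2); c2 <- substr(gc, 3, 4)
          if (is.na(decode[[ln]][c1]) || is.na(decode[[ln]][c2])) {
            stop_validation("individual '%s': unknown allele code '%s' at %s", id, gc, ln)
          }
          rec[[paste0(ln, "_a1")]] <- decode[[ln]][[c1]]
          rec[[paste0(ln, "_a2")]] <- decode[[ln]][[c2]]
        }
      }
      as.data.frame(rec, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, recs)
    pname <- if (!is.null(names) && length(names) >= p) names[p] else paste0("pop", p)
    df$breed <- pname
    out[[p]] <- population_sample(pname, df, loci)
  }
  out
}
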