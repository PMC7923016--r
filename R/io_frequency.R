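#' Construct an allele-frequency table
#'
#' The exchange currency between pipeline stages: a long-form table with one
#' row per breed x locus x allele, carrying the allele frequency and the
#' number of animals the breed x locus estimate is based on.
#'
#' @param df data frame with columns `breed`, `n`, `locus`, `allele`, `freq`.
#' @param tol allowed deviation of per breed-locus frequency sums from 1.
#'   Printed tables drift by rounding, so the reading default is 0.015;
#'   tables derived from counts are exact.
#' @param on_violation `"error"` or `"warning"` when a sum exceeds `tol`.
#' @return an object of class `"ba_freq_table"` (a data frame).
#' @export
allele_freq_table <- function(df, tol = 0.015, on_violation = c("error", "warning")) {
  on_violation <- match.arg(on_violation)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  req <- c("breed", "n", "locus", "allele", "freq")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop_validation("missing column(s): %s", paste(miss, collapse = ", "))
  df$n <- as.integer(df$n); df$freq <- as.numeric(df$freq)
  if (any(is.na(df$freq)) || any(df$freq < 0 | df$freq > 1)) {
    stop_validation("allele frequencies must lie in [0, 1]")
  }
  if (any(is.na(df$n)) || any(df$n < 1)) stop_validation("n_animals must be >= 1")
  key <- paste(df$breed, df$locus, sep = "\r")
  sums <- tapply(df$freq, key, sum)
  bad <- which(abs(sums - 1) > tol)
  if (length(bad)) {
    msg <- sprintf("frequencies for %s sum to %.4f (tolerance %.3f)",
                   gsub("\r", " / ", names(sums)[bad[1]]), sums[bad[1]], tol)
    if (on_violation == "error") stop_validation("%s", msg) else warning(msg, call. = FALSE)
  }
  df <- df[, req]
  rownames(df) <- NULL
  class(df) <- c("ba_freq_table", "data.frame")
  df
}

#' Read a long-form allele-frequency table
#'
#' Delimited text with header `breed,n,locus,allele,freq`.
#'
#' @inheritParams allele_freq_table
#' @param path file path.
#' @param sep field separator.
#' @return a `"ba_freq_table"`.
#' @export
read_frequency_table <- function(path, sep = ",", tol = 0.015,
                                 on_violation = c("error", "warning")) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  allele_freq_table(df, tol = tol, on_violation = match.arg(on_violation))
}

#' Write a long-form allele-frequency table
#' @param ft a `"ba_freq_table"`.
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(ft, path, sep = ",") {
  utils::write.table(ft, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Breeds present in a frequency table
#' @param ft a `"ba_freq_table"`.
#' @return character vector of breed names, in order of first appearance.
#' @export
freq_breeds <- function(ft) unique(ft$breed)

#' Extract one breed-locus frequency vector
#'
#' @param ft a `"ba_freq_table"`.
#' @param breed,locus row selectors.
#' @return named numeric vector of allele frequencies with attribute `n`
#'   (number of animals).
#' @export
freq_vector <- function(ft, breed, locus) {
  rows <- ft$breed == breed & ft$locus == locus
  if (!any(rows)) stop_validation("no entry for breed '%s' at locus '%s'", breed, locus)
  v <- stats::setNames(ft$freq[rows], ft$allele[rows])
  attr(v, "n") <- unique(ft$n[rows])[1]
  v
}
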