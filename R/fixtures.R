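#' Packaged reference datasets from the published study tables
#'
#' Rebuilds, from the printed tables, the datasets every pipeline stage can
#' be exercised on without any download:
#'
#' * `"table1_mora"` — the 357 genotyped Mora Romagnola breeding pigs
#'   (110 boars, 247 sows) as a [population_sample()], with the published
#'   genotype counts at MC1R (225 e/e, 109 E+/e, 11 E+/E+, 5 E+/ED2,
#'   5 ED2/e, 1 E+/ED1, 1 ED1/ED2) and NR6A1 (355 T/T, 1 T/C, 1 C/C), the
#'   one red-coated adult sow (genotype e/e and T/T) flagged in the
#'   phenotype columns, and the ED2/e carrier recorded as a boar. The
#'   MC1R genotypes of the two NR6A1 C-carrier sows are not printed; this
#'   synthetic reconstruction assumes e/e, the only assumption that
#'   reproduces the recomputed retained-sample allele counts (131 E+ /
#'   553 e).
#' * `"table2_panel"` — the 13-population allele-frequency panel as a
#'   `"ba_freq_table"` (printed 3-decimal values).
#' * `"mora_2010_2014"` — the earlier 74-pig sample: MC1R allele counts
#'   26 E+ / 122 e (frequencies 0.176 / 0.824), NR6A1 fixed for T.
#'
#' @param name one of `"table1_mora"`, `"table2_panel"`, `"mora_2010_2014"`.
#' @return see above; `"mora_2010_2014"` returns a list with `n` and
#'   `allele_counts`.
#' @export
mora_fixture <- function(name = c("table1_mora", "table2_panel", "mora_2010_2014")) {
  name <- match.arg(name)
  switch(name,
    table1_mora = build_table1_sample(),
    table2_panel = read_frequency_table(
      system.file("extdata", "table2_allele_frequencies.csv", package = "breedauth",
                  mustWork = TRUE)),
    mora_2010_2014 = list(
      n = 74L,
      allele_counts = list(MC1R = c(`E+` = 26L, e = 122L), NR6A1 = c(T = 148L)))
  )
}

build_table1_sample <- function() {
  row <- function(m1, m2, n1, n2, class, coat = "black_and_tan") {
    data.frame(MC1R_a1 = m1, MC1R_a2 = m2, NR6A1_a1 = n1, NR6A1_a2 = n2,
               class = class, coat_colour = coat, stringsAsFactors = FALSE)
  }
  rep_rows <- function(df, times) df[rep(1, times), , drop = FALSE]
  special <- rbind(
    row("e", "e", "T", "T", "sow", coat = "red"),       # the red-coated adult sow
    row("e", "e", "T", "C", "sow"),                     # C carrier, assumed e/e
    row("e", "e", "C", "C", "sow"),                     # C carrier, assumed e/e
    row("ED2", "e", "T", "T", "boar"),                  # the ED2/e boar
    rep_rows(row("ED2", "e", "T", "T", "sow"), 4),
    rep_rows(row("E+", "ED2", "T", "T", "sow"), 5),
    row("E+", "ED1", "T", "T", "sow"),
    row("ED1", "ED2", "T", "T", "sow"))
  std <- rbind(
    rep_rows(row("e", "e", "T", "T", "boar"), 109),
    rep_rows(row("e", "e", "T", "T", "sow"), 113),
    rep_rows(row("E+", "e", "T", "T", "sow"), 109),
    rep_rows(row("E+", "E+", "T", "T", "sow"), 11))
  df <- rbind(special, std)
  df$animal_id <- sprintf("MR_%03d", seq_len(nrow(df)))
  df$breed <- "Mora Romagnola"
  df$ears <- "bent_forward_parallel"
  df$linea_sparta <- "present"
  population_sample("Mora Romagnola", df, default_loci())
}
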