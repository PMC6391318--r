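#' Packaged study tables
#'
#' The package ships plain-TSV transcriptions of the study's four data
#' tables so every analysis can be rerun from printed data:
#' \describe{
#'   \item{table1}{The 13 disease-associated 20-SNP haplotypes (columns
#'     A--M) with per-haplotype family counts and the Joseph-lineage
#'     reference column.}
#'   \item{table2}{Genotype counts for 4 SNPs in patients (n = 109) and
#'     control spouses (n = 49), with the printed Hardy-Weinberg and
#'     case-control p-values kept for reference.}
#'   \item{table3}{Frequencies of the 22 six-SNP haplotypes in control and
#'     disease chromosomes with the printed delta values.}
#'   \item{table4}{The 41 seven-STR disease haplotypes of the four major
#'     lineages (A: 10, B: 12, D: 8, G: 11 families) and the printed age
#'     estimates. "Fam 1" appears under both lineages A and D and is kept
#'     verbatim in both (distinct \code{row_id}); Fam 33's annotated
#'     \code{(AAAC)n} value "7 (5)" is stored as 7 with the 5 in
#'     \code{AAAC_annot}.}
#' }
#'
#' @param name One of \code{"table1"}, \code{"table2"}, \code{"table3"},
#'   \code{"table4"}.
#' @return \code{table1}: a list with \code{alleles} (20 x 13 character
#'   matrix, rownames = rs ids), \code{joseph} (named reference vector),
#'   and \code{counts} (named integer vector of families per haplotype).
#'   \code{table2}/\code{table3}: data frames mirroring the printed
#'   layout. \code{table4}: a list with \code{haplotypes} (a
#'   \code{str_haplotypes} set with \code{lineage}, \code{family},
#'   \code{row_id} and \code{AAAC_annot} columns) and \code{meta}
#'   (per-lineage 20-SNP haplotype strings and printed ages).
#' @export
load_fixture <- function(name = c("table1", "table2", "table3", "table4")) {
  name <- match.arg(name)
  switch(name,
    table1 = load_table1(),
    table2 = load_table2(),
    table3 = load_table3(),
    table4 = load_table4())
}

load_table1 <- function() {
  df <- utils::read.delim(fh_extdata("table1.tsv"), stringsAsFactors = FALSE,
                          check.names = FALSE)
  counts_df <- utils::read.delim(fh_extdata("table1_counts.tsv"),
                                 stringsAsFactors = FALSE)
  alleles <- as.matrix(df[, setdiff(names(df), c("rs_id", "joseph"))])
  rownames(alleles) <- df$rs_id
  joseph <- stats::setNames(df$joseph, df$rs_id)
  counts <- stats::setNames(as.integer(counts_df$n_families), counts_df$label)
  stopifnot(identical(colnames(alleles), names(counts)))
  list(alleles = alleles, joseph = joseph, counts = counts)
}

load_table2 <- function() {
  df <- utils::read.delim(fh_extdata("table2.tsv"), stringsAsFactors = FALSE,
                          na.strings = ".")
  df
}

load_table3 <- function() {
  df <- utils::read.delim(fh_extdata("table3.tsv"), stringsAsFactors = FALSE,
                          na.strings = ".")
  df$delta_printed <- as.numeric(df$delta_printed)
  df
}

load_table4 <- function() {
  df <- utils::read.delim(fh_extdata("table4.tsv"), stringsAsFactors = FALSE,
                          na.strings = ".")
  meta <- utils::read.delim(fh_extdata("table4_meta.tsv"),
                            stringsAsFactors = FALSE)
  haps <- str_haplotypes(as.matrix(df[, str_locus_names()]),
                         family = df$family, disease_flag = TRUE)
  haps$lineage <- df$lineage
  haps$row_id <- paste(df$lineage, df$family, sep = ":")
  haps$AAAC_annot <- df$AAAC_annot
  attr(haps, "marker_cols") <- str_locus_names()
  list(haplotypes = haps, meta = meta)
}

#' STR haplotypes of one lineage from the packaged table
#'
#' @param lineage One of \code{"A"}, \code{"B"}, \code{"D"}, \code{"G"}.
#' @param fixtures Optionally a preloaded \code{load_fixture("table4")}.
#' @return A \code{str_haplotypes} set for that lineage.
#' @export
lineage_str_haplotypes <- function(lineage, fixtures = load_fixture("table4")) {
  lineage <- match.arg(lineage, c("A", "B", "D", "G"))
  haps <- fixtures$haplotypes
  out <- haps[haps$lineage == lineage, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "marker_cols") <- attr(haps, "marker_cols")
  class(out) <- class(haps)
  out
}
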