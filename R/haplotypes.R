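#' Haplotype sets
#'
#' A haplotype set is a data frame with one row per chromosome: bookkeeping
#' columns (\code{family}, \code{disease_flag}, and for SNP haplotypes
#' \code{inference}) followed by one column per marker. SNP haplotypes hold
#' bases over the panel's SNPs; STR haplotypes hold positive integer repeat
#' counts over the seven flanking microsatellites in physical column order
#' (\code{TAT_223}, \code{GT_199}, \code{ATA_194}, \code{AC_21},
#' \code{AAAC}, \code{GT}, \code{AC_190}).
#'
#' @param alleles Character matrix (rows = haplotypes, named columns =
#'   markers).
#' @param family Character vector of source families (recycled).
#' @param disease_flag Logical: in phase with the expansion (recycled).
#' @param inference How the phase was obtained: \code{"segregation"},
#'   \code{"em"} or \code{"fixture"}.
#' @return A \code{snp_haplotypes} / \code{str_haplotypes} data frame.
#' @rdname haplotype-sets
#' @export
snp_haplotypes <- function(alleles, family = NA_character_,
                           disease_flag = FALSE, inference = "fixture") {
  alleles <- as.matrix(alleles)
  if (is.null(colnames(alleles))) stop("allele matrix needs marker colnames")
  df <- data.frame(family = rep_len(family, nrow(alleles)),
                   disease_flag = rep_len(disease_flag, nrow(alleles)),
                   inference = rep_len(inference, nrow(alleles)),
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(alleles, stringsAsFactors = FALSE))
  structure(df, marker_cols = colnames(alleles),
            class = c("snp_haplotypes", "data.frame"))
}

#' @param repeats Integer matrix of repeat counts (rows = haplotypes).
#' @rdname haplotype-sets
#' @export
str_haplotypes <- function(repeats, family = NA_character_,
                           disease_flag = FALSE) {
  repeats <- as.matrix(repeats)
  if (is.null(colnames(repeats))) colnames(repeats) <- str_locus_names()
  storage.mode(repeats) <- "integer"
  if (any(repeats < 1, na.rm = TRUE)) stop("STR repeat counts must be >= 1")
  df <- data.frame(family = rep_len(family, nrow(repeats)),
                   disease_flag = rep_len(disease_flag, nrow(repeats)),
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(repeats))
  structure(df, marker_cols = colnames(repeats),
            class = c("str_haplotypes", "data.frame"))
}

#' Locus names of the 7-STR haplotype, in physical column order
#' @return Character vector of length 7.
#' @export
str_locus_names <- function() {
  c("TAT_223", "GT_199", "ATA_194", "AC_21", "AAAC", "GT", "AC_190")
}

#' Extract the marker matrix of a haplotype set
#' @param haps A haplotype set.
#' @return The allele (character) or repeat-count (integer) matrix.
#' @export
hap_matrix <- function(haps) {
  cols <- attr(haps, "marker_cols")
  if (is.null(cols)) {
    cols <- setdiff(names(haps), c("family", "disease_flag", "inference",
                                   "lineage", "row_id", "AAAC_annot"))
  }
  as.matrix(haps[, cols, drop = FALSE])
}

#' Write haplotypes to a tab-separated file
#'
#' Writes one row per haplotype with a header; the output round-trips
#' through [read_haplotypes()]. All haplotypes in one call must share one
#' marker panel (identical marker columns).
#'
#' @param haps A haplotype set, or a list of haplotype sets over the same
#'   markers (they are stacked).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_haplotypes <- function(haps, path) {
  if (is.list(haps) && !is.data.frame(haps)) {
    if (length(haps) == 0) stop("cannot write an empty haplotype list")
    panels <- unique(lapply(haps, function(h) attr(h, "marker_cols")))
    if (length(panels) != 1) {
      stop("mixed marker panels in one write_haplotypes() call")
    }
    cls <- unique(vapply(haps, function(h) class(h)[1], ""))
    if (length(cls) != 1) {
      stop("mixed marker panels in one write_haplotypes() call")
    }
    haps <- do.call(rbind, haps)
  }
  if (!is.data.frame(haps) || nrow(haps) == 0) {
    stop("cannot write an empty haplotype set")
  }
  utils::write.table(haps, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read haplotypes written by [write_haplotypes()]
#'
#' The haplotype kind is inferred from the marker columns: all-integer
#' columns are read as STR repeat counts, otherwise as SNP alleles.
#'
#' @param path Path to a haplotype TSV.
#' @return A \code{snp_haplotypes} or \code{str_haplotypes} set.
#' @export
read_haplotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta <- intersect(c("family", "disease_flag", "inference", "lineage",
                      "row_id", "AAAC_annot"), names(df))
  marker_cols <- setdiff(names(df), meta)
  mat <- as.matrix(df[, marker_cols, drop = FALSE])
  if (is.numeric(mat)) {
    str_haplotypes(mat, family = df$family, disease_flag = df$disease_flag)
  } else {
    snp_haplotypes(mat, family = df$family, disease_flag = df$disease_flag,
                   inference = if ("inference" %in% meta) df$inference
                               else "fixture")
  }
}
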