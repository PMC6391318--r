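#' Ancestral lineage references
#'
#' The two described ancestral SNP backgrounds of the expansion, given over
#' the six core SNPs (rs12590497, rs16999141, rs1048755, rs12895357,
#' rs7158733, rs3092822): Joseph = T-T-A-C-A-C and Machado = G-C-G-G-C-A.
#' The 20-SNP extended reference is available for the Joseph lineage only
#' (from the packaged table); no extended Machado reference is published
#' for this marker set, and none is invented here.
#'
#' @param name \code{"Joseph"} or \code{"Machado"}.
#' @param extended If \code{TRUE}, return the Joseph 20-SNP vector
#'   (errors for Machado).
#' @return Named character vector of reference alleles.
#' @export
lineage_reference <- function(name = c("Joseph", "Machado"),
                              extended = FALSE) {
  name <- match.arg(name)
  if (extended) {
    if (name == "Machado") {
      stop("no extended 20-SNP Machado reference is available for this panel")
    }
    return(load_fixture("table1")$joseph)
  }
  core <- core_six_snps()
  if (name == "Joseph") {
    stats::setNames(c("T", "T", "A", "C", "A", "C"), core)
  } else {
    stats::setNames(c("G", "C", "G", "G", "C", "A"), core)
  }
}

#' rs ids of the six core SNPs, in haplotype-string order
#' @return Character vector of length 6.
#' @export
core_six_snps <- function() {
  c("rs12590497", "rs16999141", "rs1048755", "rs12895357", "rs7158733",
    "rs3092822")
}

#' Classify a six-SNP haplotype against the ancestral lineages
#'
#' Exact matches are labelled \code{"Joseph"} or \code{"Machado"};
#' anything else is \code{"novel"} and reported with its divergent sites
#' relative to the nearer reference (fewest mismatches; equidistant
#' haplotypes report both references as ties).
#'
#' @param hap Character vector of 6 alleles in [core_six_snps()] order
#'   (a \code{"T-T-A-C-A-C"}-style string is also accepted).
#' @return A \code{lineage_call} list: \code{label}, \code{nearest}
#'   (reference name(s); ties kept), \code{divergent_sites} (data frame
#'   \code{rs_id}, \code{ref_allele}, \code{obs_allele} vs the first
#'   nearest reference), \code{tie} (logical).
#' @export
classify_six_snp <- function(hap) {
  hap <- split_hap(hap)
  if (length(hap) != 6) stop("six-SNP haplotype must have 6 alleles")
  names(hap) <- core_six_snps()
  refs <- list(Joseph = lineage_reference("Joseph"),
               Machado = lineage_reference("Machado"))
  d <- vapply(refs, function(r) sum(r != hap), 0L)
  nearest <- names(d)[d == min(d)]
  label <- if (min(d) == 0) nearest[1] else "novel"
  ref <- refs[[nearest[1]]]
  div <- data.frame(rs_id = names(ref)[ref != hap],
                    ref_allele = unname(ref[ref != hap]),
                    obs_allele = unname(hap[ref != hap]),
                    stringsAsFactors = FALSE)
  structure(list(label = label, nearest = nearest, divergent_sites = div,
                 tie = length(nearest) > 1, distance = min(d)),
            class = "lineage_call")
}

split_hap <- function(hap) {
  if (length(hap) == 1 && grepl("-", hap, fixed = TRUE)) {
    hap <- strsplit(hap, "-", fixed = TRUE)[[1]]
  }
  as.character(hap)
}

#' Divergences of a 20-SNP haplotype from the Joseph lineage
#'
#' @param hap Character vector of 20 alleles ordered as the packaged
#'   20-SNP table rows (see \code{load_fixture("table1")$joseph}), or a
#'   named vector covering those rs ids.
#' @return A \code{lineage_call} with the sites where the haplotype
#'   differs from the Joseph reference; the divergence count equals the
#'   Hamming distance to the Joseph vector.
#' @export
diff_from_joseph20 <- function(hap) {
  ref <- lineage_reference("Joseph", extended = TRUE)
  hap <- split_hap(hap)
  if (!is.null(names(hap)) && all(names(ref) %in% names(hap))) {
    hap <- hap[names(ref)]
  }
  if (length(hap) != length(ref)) {
    stop("20-SNP haplotype must have ", length(ref), " alleles")
  }
  names(hap) <- names(ref)
  ok <- !is.na(hap)
  bad <- ok & (ref != hap)
  div <- data.frame(rs_id = names(ref)[bad],
                    ref_allele = unname(ref[bad]),
                    obs_allele = unname(hap[bad]),
                    stringsAsFactors = FALSE)
  structure(list(label = if (nrow(div) == 0) "Joseph" else "novel",
                 nearest = "Joseph", divergent_sites = div, tie = FALSE,
                 distance = nrow(div)),
            class = "lineage_call")
}

#' @export
print.lineage_call <- function(x, ...) {
  cat(sprintf("lineage_call: %s (nearest %s, %d divergent site%s%s)\n",
              x$label, paste(x$nearest, collapse = "/"), x$distance,
              if (x$distance == 1) "" else "s",
              if (x$tie) ", tied" else ""))
  if (nrow(x$divergent_sites) > 0) print(x$divergent_sites)
  invisible(x)
}

#' Tabulate disease haplotypes across families
#'
#' Summarises a set of per-family disease haplotypes (as in the packaged
#' 20-SNP table): the number of distinct haplotypes, the number of
#' family-haplotype assignments, and per-site allele segregation counts
#' (how many families' disease chromosomes carry each allele).
#'
#' @param alleles Character matrix of haplotypes (rows = SNPs with rs-id
#'   rownames, columns = haplotype labels), as in
#'   \code{load_fixture("table1")$alleles}.
#' @param counts Named integer vector of families per haplotype column.
#' @return A list: \code{n_distinct} distinct haplotypes,
#'   \code{n_family_assignments} (sum of counts; can exceed the number of
#'   study families when a family segregates two disease haplotypes),
#'   \code{site_counts} (data frame \code{rs_id}, \code{allele},
#'   \code{n_families}).
#' @export
tabulate_lineages <- function(alleles, counts) {
  stopifnot(ncol(alleles) == length(counts),
            identical(colnames(alleles), names(counts)))
  keys <- apply(alleles, 2, paste, collapse = "")
  site_counts <- do.call(rbind, lapply(rownames(alleles), function(rs) {
    tab <- tapply(counts, alleles[rs, ], sum)
    data.frame(rs_id = rs, allele = names(tab),
               n_families = as.integer(tab), stringsAsFactors = FALSE)
  }))
  rownames(site_counts) <- NULL
  list(n_distinct = length(unique(keys)),
       n_family_assignments = sum(counts),
       site_counts = site_counts)
}

#' Families whose disease haplotype carries a given allele
#'
#' @param tab Result of [tabulate_lineages()].
#' @param rs_id,allele Site and allele of interest.
#' @return Integer count of families.
#' @export
families_with_allele <- function(tab, rs_id, allele) {
  sc <- tab$site_counts
  hit <- sc$rs_id == rs_id & sc$allele == allele
  if (!any(hit)) 0L else sc$n_families[hit]
}
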