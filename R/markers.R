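#' Load a marker manifest into a marker panel
#'
#' Reads a tab-separated manifest describing the SNPs and STRs flanking the
#' (CAG)n repeat of \emph{ATXN3} and returns them as an ordered marker panel.
#' The manifest must have columns \code{marker_id}, \code{rs_id},
#' \code{kind} (\code{SNP} or \code{STR}), \code{offset_kb} (kilobases from
#' the (CAG)n anchor, negative upstream) and \code{domain} (comma-separated
#' bases for a SNP, an integer range \code{min-max} of repeat counts for an
#' STR). Markers are sorted by physical offset; the (CAG)n anchor sits at
#' offset zero, between the last upstream and first downstream marker.
#'
#' @param path Path to the manifest file.
#' @return A \code{marker_panel}: a data frame with one row per marker,
#'   ordered by \code{offset_kb}, a list column \code{domain_parsed}, and an
#'   attribute \code{anchor_index} giving the number of upstream markers
#'   (the anchor lies between positions \code{anchor_index} and
#'   \code{anchor_index + 1}).
#' @seealso [default_marker_panel()] for the shipped 27-marker panel.
#' @export
load_marker_manifest <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = NULL)
  required <- c("marker_id", "rs_id", "kind", "offset_kb", "domain")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("marker manifest is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df$marker_id)) {
    dup <- unique(df$marker_id[duplicated(df$marker_id)])
    stop("duplicate marker_id in manifest: ", paste(dup, collapse = ", "))
  }
  rs <- df$rs_id[df$rs_id != "." & !is.na(df$rs_id)]
  if (anyDuplicated(rs)) {
    stop("duplicate rs_id in manifest: ",
         paste(unique(rs[duplicated(rs)]), collapse = ", "))
  }
  bad_kind <- setdiff(unique(df$kind), c("SNP", "STR"))
  if (length(bad_kind) > 0) {
    stop("unknown marker kind: ", paste(bad_kind, collapse = ", "))
  }
  offset <- suppressWarnings(as.numeric(df$offset_kb))
  if (anyNA(offset)) {
    stop("unparseable offset_kb for marker(s): ",
         paste(df$marker_id[is.na(offset)], collapse = ", "))
  }
  df$offset_kb <- offset
  df$rs_id[df$rs_id == "."] <- NA_character_
  df$domain_parsed <- mapply(parse_domain, df$domain, df$kind, df$marker_id,
                             SIMPLIFY = FALSE, USE.NAMES = FALSE)
  df <- df[order(df$offset_kb), , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            anchor_index = sum(df$offset_kb < 0),
            class = c("marker_panel", "data.frame"))
}

parse_domain <- function(spec, kind, id) {
  if (kind == "SNP") {
    alleles <- strsplit(spec, ",", fixed = TRUE)[[1]]
    alleles <- trimws(alleles)
    if (length(alleles) < 1 || !all(alleles %in% c("A", "C", "G", "T"))) {
      stop("SNP ", id, " has a domain outside {A,C,G,T}: ", spec)
    }
    alleles
  } else {
    parts <- suppressWarnings(as.integer(strsplit(spec, "-", fixed = TRUE)[[1]]))
    if (length(parts) != 2 || anyNA(parts) || parts[1] < 1 ||
        parts[2] < parts[1]) {
      stop("STR ", id, " needs an integer repeat range 'min-max' >= 1: ", spec)
    }
    parts
  }
}

#' The default ATXN3 flanking-marker panel
#'
#' The 27-marker panel shipped with the package: 20 SNPs within a few
#' kilobases of the (CAG)n plus 7 flanking STRs whose names carry their
#' distance in kilobases where known (e.g. \code{TAT_223} is 223 kb away).
#' The anchor lies between rs10467856 and rs12895357.
#'
#' @return A \code{marker_panel} of 27 markers.
#' @export
default_marker_panel <- function() {
  load_marker_manifest(fh_extdata("markers.tsv"))
}

fh_extdata <- function(file) {
  system.file("extdata", file, package = "founderhap", mustWork = TRUE)
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("marker_panel: %d markers (%d SNP, %d STR), anchor after position %d\n",
              nrow(x), sum(x$kind == "SNP"), sum(x$kind == "STR"),
              attr(x, "anchor_index")))
  print.data.frame(x[, c("marker_id", "rs_id", "kind", "offset_kb", "domain")],
                   ...)
  invisible(x)
}

#' Marker ids of the SNPs (or STRs) in a panel
#' @param panel A \code{marker_panel}.
#' @return Character vector of marker ids in physical order.
#' @rdname panel-accessors
#' @export
snp_markers <- function(panel) panel$marker_id[panel$kind == "SNP"]

#' @rdname panel-accessors
#' @export
str_markers <- function(panel) panel$marker_id[panel$kind == "STR"]

#' Check one allele against a marker's domain
#' @param panel A \code{marker_panel}.
#' @param marker_id Marker to check against.
#' @param allele Allele as read from a genotype file (character).
#' @return \code{TRUE} if the allele lies in the marker's domain.
#' @keywords internal
allele_in_domain <- function(panel, marker_id, allele) {
  i <- match(marker_id, panel$marker_id)
  if (is.na(i)) stop("unknown marker: ", marker_id)
  dom <- panel$domain_parsed[[i]]
  if (panel$kind[i] == "SNP") {
    allele %in% dom
  } else {
    rep_n <- suppressWarnings(as.integer(allele))
    !is.na(rep_n) && rep_n >= dom[1] && rep_n <= dom[2]
  }
}
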