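#' Load a genotype table
#'
#' Reads a tab-separated genotype matrix (rows = individuals, columns =
#' markers, first column \code{individual_id}) where each cell is an
#' unordered allele pair \code{"a/b"} or \code{"."} for missing. SNP cells
#' hold bases, STR cells repeat counts. Every allele is validated against
#' the panel's domain; missing data stay explicit.
#'
#' @param path Path to the genotype file.
#' @param panel A \code{marker_panel} the columns must belong to.
#' @return A \code{genotype_table}: a long data frame with columns
#'   \code{individual_id}, \code{marker_id}, \code{a1}, \code{a2}
#'   (characters; both \code{NA} when missing).
#' @export
load_genotypes <- function(path, panel) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = NULL)
  if (names(df)[1] != "individual_id") names(df)[1] <- "individual_id"
  marker_cols <- names(df)[-1]
  unknown <- setdiff(marker_cols, panel$marker_id)
  if (length(unknown) > 0) {
    stop("unknown marker column(s): ", paste(unknown, collapse = ", "))
  }
  rows <- lapply(marker_cols, function(m) {
    cells <- as.character(df[[m]])
    parsed <- parse_genotype_cells(cells, m, panel, df$individual_id)
    data.frame(individual_id = df$individual_id, marker_id = m,
               a1 = parsed$a1, a2 = parsed$a2, stringsAsFactors = FALSE)
  })
  genotype_table(do.call(rbind, rows))
}

parse_genotype_cells <- function(cells, marker_id, panel, ids) {
  a1 <- a2 <- rep(NA_character_, length(cells))
  keep <- !(cells %in% c(".", "", "./."))
  if (any(keep)) {
    parts <- strsplit(cells[keep], "/", fixed = TRUE)
    ok <- lengths(parts) == 2
    if (!all(ok)) {
      stop("malformed genotype cell for ", marker_id, " in individual(s) ",
           paste(ids[keep][!ok], collapse = ", "))
    }
    a1[keep] <- trimws(vapply(parts, `[`, "", 1))
    a2[keep] <- trimws(vapply(parts, `[`, "", 2))
    for (al in unique(c(a1[keep], a2[keep]))) {
      if (!allele_in_domain(panel, marker_id, al)) {
        stop("allele '", al, "' outside the domain of marker ", marker_id)
      }
    }
  }
  list(a1 = a1, a2 = a2)
}

#' Construct a genotype table from a long data frame
#'
#' @param df Data frame with columns \code{individual_id}, \code{marker_id},
#'   \code{a1}, \code{a2} (alleles as character, \code{NA} = missing).
#' @return A \code{genotype_table}.
#' @export
genotype_table <- function(df) {
  required <- c("individual_id", "marker_id", "a1", "a2")
  if (!all(required %in% names(df))) {
    stop("genotype table needs columns ", paste(required, collapse = ", "))
  }
  if (any(is.na(df$a1) != is.na(df$a2))) {
    stop("half-missing genotype: a1 and a2 must be missing together")
  }
  rownames(df) <- NULL
  structure(df[required], class = c("genotype_table", "data.frame"))
}

#' Look up one genotype
#'
#' @param gt A \code{genotype_table}.
#' @param individual_id,marker_id Entry to fetch.
#' @return Character vector of the two alleles, or \code{NULL} when the
#'   entry is missing or absent.
#' @export
genotype_of <- function(gt, individual_id, marker_id) {
  i <- which(gt$individual_id == individual_id & gt$marker_id == marker_id)
  if (length(i) == 0 || is.na(gt$a1[i[1]])) return(NULL)
  c(gt$a1[i[1]], gt$a2[i[1]])
}
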