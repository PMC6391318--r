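#' Construct a pedigree from an individual table
#'
#' A pedigree is one family's individual table with referential integrity
#' enforced: parent ids either resolve within the family or are absent, no
#' individual is its own ancestor, and the expansion-carrier flag agrees
#' with the number of expanded chromosomes carried (0, 1, or 2; a patient
#' homozygous for the expansion carries 2).
#'
#' @param df Data frame with columns \code{individual_id}, \code{family_id},
#'   \code{father_id}, \code{mother_id} (\code{NA} when absent), \code{sex}
#'   (\code{"male"}, \code{"female"}, \code{"unknown"}), \code{affected}
#'   (\code{"affected"}, \code{"unaffected"}, \code{"unknown"}) and
#'   \code{expansion_count} (integer 0/1/2, \code{NA} when unknown).
#' @param study_mode If \code{TRUE}, additionally require at least two
#'   generations and at least four members (the family-selection rule used
#'   for the disease cohort).
#' @return A \code{pedigree} object (a validated data frame).
#' @export
pedigree <- function(df, study_mode = FALSE) {
  required <- c("individual_id", "family_id", "father_id", "mother_id",
                "sex", "affected", "expansion_count")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("pedigree table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (length(unique(df$family_id)) != 1) {
    stop("a pedigree holds exactly one family")
  }
  if (anyDuplicated(df$individual_id)) {
    stop("duplicate individual_id within family ", df$family_id[1])
  }
  for (col in c("father_id", "mother_id")) {
    ref <- df[[col]]
    bad <- !is.na(ref) & !(ref %in% df$individual_id)
    if (any(bad)) {
      stop("parent id referenced but undefined in family ", df$family_id[1],
           ": ", paste(unique(ref[bad]), collapse = ", "))
    }
  }
  check_acyclic(df)
  df$expansion_count <- as.integer(df$expansion_count)
  if (any(!is.na(df$expansion_count) & !(df$expansion_count %in% 0:2))) {
    stop("expansion_count must be 0, 1, or 2")
  }
  df$expansion_carrier <- ifelse(is.na(df$expansion_count), "unknown",
                                 ifelse(df$expansion_count >= 1, "yes", "no"))
  if (study_mode) {
    if (nrow(df) < 4) {
      stop("family ", df$family_id[1], " has fewer than 4 members")
    }
    if (all(is.na(df$father_id) & is.na(df$mother_id))) {
      stop("family ", df$family_id[1], " has a single generation")
    }
  }
  rownames(df) <- NULL
  structure(df, class = c("pedigree", "data.frame"))
}

check_acyclic <- function(df) {
  idx <- function(id) match(id, df$individual_id)
  for (i in seq_len(nrow(df))) {
    seen <- integer(0)
    frontier <- i
    while (length(frontier) > 0) {
      j <- frontier[1]
      frontier <- frontier[-1]
      parents <- stats::na.omit(c(idx(df$father_id[j]), idx(df$mother_id[j])))
      if (any(parents == i)) {
        stop("cyclic parentage involving individual ", df$individual_id[i],
             " in family ", df$family_id[1])
      }
      new <- setdiff(parents, seen)
      seen <- c(seen, new)
      frontier <- c(frontier, new)
    }
  }
  invisible(TRUE)
}

#' Load pedigrees from a PED-like file
#'
#' Reads a whitespace-separated file with the six standard pedigree columns
#' (family, individual, father, mother, sex, affection) plus an optional
#' seventh column giving the number of expanded chromosomes carried
#' (\code{expansion_count}, 0/1/2). \code{0} in the parent columns means
#' "absent"; sex is coded 1 = male, 2 = female, 0 = unknown; affection is
#' coded 2 = affected, 1 = unaffected, 0 = unknown. When the expansion
#' column is absent, affected individuals are assumed to carry one expanded
#' chromosome and unaffected individuals none (unknown stays unknown), the
#' convention appropriate to a fully penetrant dominant expansion.
#'
#' @param path Path to the pedigree file.
#' @param study_mode Passed to [pedigree()]: enforce the two-generation /
#'   four-member family-selection rule.
#' @return A named list with one \code{pedigree} per family id.
#' @export
load_pedigree <- function(path, study_mode = FALSE) {
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 6 || ncol(raw) > 7) {
    stop("pedigree file needs 6 columns (family, individual, father, mother, ",
         "sex, affection) plus an optional expansion_count column")
  }
  names(raw)[1:6] <- c("family_id", "individual_id", "father_id", "mother_id",
                       "sex_code", "aff_code")
  sex <- c("0" = "unknown", "1" = "male", "2" = "female")[raw$sex_code]
  aff <- c("0" = "unknown", "1" = "unaffected", "2" = "affected")[raw$aff_code]
  if (anyNA(sex)) stop("sex must be coded 0/1/2")
  if (anyNA(aff)) stop("affection must be coded 0/1/2")
  if (ncol(raw) == 7) {
    exp_count <- suppressWarnings(as.integer(raw[[7]]))
    if (anyNA(exp_count)) stop("expansion_count must be an integer 0/1/2")
  } else {
    exp_count <- ifelse(aff == "affected", 1L,
                        ifelse(aff == "unaffected", 0L, NA_integer_))
  }
  df <- data.frame(individual_id = raw$individual_id,
                   family_id = raw$family_id,
                   father_id = ifelse(raw$father_id == "0", NA_character_,
                                      raw$father_id),
                   mother_id = ifelse(raw$mother_id == "0", NA_character_,
                                      raw$mother_id),
                   sex = unname(sex), affected = unname(aff),
                   expansion_count = exp_count,
                   stringsAsFactors = FALSE)
  out <- lapply(split(df, df$family_id), pedigree, study_mode = study_mode)
  out[unique(df$family_id)]
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("pedigree: family %s, %d individuals (%d expansion carriers)\n",
              x$family_id[1], nrow(x), sum(x$expansion_count >= 1,
                                           na.rm = TRUE)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Founders of a pedigree
#'
#' Individuals with neither parent recorded in the family.
#' @param ped A \code{pedigree}.
#' @return Character vector of individual ids.
#' @export
founders <- function(ped) {
  ped$individual_id[is.na(ped$father_id) & is.na(ped$mother_id)]
}
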