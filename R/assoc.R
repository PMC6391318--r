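#' Allele counts and frequencies from genotype counts
#'
#' @param g Integer vector \code{c(n_hom_ref, n_het, n_hom_alt)}.
#' @return List with \code{ref}, \code{alt} allele counts
#'   (\code{2*n_hom + n_het}) and \code{freq} (length-2 frequencies over
#'   \code{2n} chromosomes). \code{ref + alt == 2 * sum(g)} always.
#' @export
allele_counts <- function(g) {
  g <- as.integer(g)
  stopifnot(length(g) == 3, all(g >= 0))
  if (sum(g) == 0) stop("all-zero genotype counts")
  ref <- 2L * g[1] + g[2]
  alt <- 2L * g[3] + g[2]
  list(ref = ref, alt = alt,
       freq = c(ref = ref, alt = alt) / (2 * sum(g)))
}

#' Hardy-Weinberg equilibrium test
#'
#' Two conventions are exposed because small genotype classes make the
#' chi-square approximation poor. \code{"exact"} (default) enumerates every
#' heterozygote count compatible with the observed allele counts and sums
#' the probabilities of all configurations no more probable than the
#' observed one. \code{"chi_square_gof"} compares observed genotype counts
#' to the p^2, 2pq, q^2 expectations with 1 degree of freedom, no
#' continuity correction. For a monomorphic marker the exact test is
#' degenerate and returns p = 1 with a warning.
#'
#' @param g Integer vector \code{c(n_hom_ref, n_het, n_hom_alt)}.
#' @param method \code{"exact"} or \code{"chi_square_gof"}.
#' @return An object of class \code{htest}.
#' @export
hwe_test <- function(g, method = c("exact", "chi_square_gof")) {
  method <- match.arg(method)
  g <- as.integer(g)
  stopifnot(length(g) == 3, all(g >= 0), sum(g) > 0)
  n <- sum(g)
  n_ref <- 2L * g[1] + g[2]
  n_alt <- 2L * g[3] + g[2]
  if (method == "chi_square_gof") {
    p <- n_ref / (2 * n)
    q <- 1 - p
    expd <- n * c(p^2, 2 * p * q, q^2)
    if (any(expd == 0)) {
      stat <- 0
      pval <- 1
    } else {
      stat <- sum((g - expd)^2 / expd)
      pval <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    }
    out <- list(statistic = c("X-squared" = stat), parameter = c(df = 1),
                p.value = pval,
                method = "Hardy-Weinberg chi-square goodness of fit",
                data.name = deparse(g))
  } else {
    if (n_ref == 0 || n_alt == 0) {
      warning("monomorphic marker: exact HWE test is degenerate, p = 1")
      pval <- 1
    } else {
      probs <- hwe_het_probabilities(n_ref, n_alt)
      p_obs <- probs[as.character(g[2])]
      pval <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
    }
    out <- list(statistic = c(n_het = g[2]), parameter = NULL,
                p.value = unname(pval),
                method = "Hardy-Weinberg exact test (full enumeration)",
                data.name = deparse(g))
  }
  class(out) <- "htest"
  out
}

# probability of each heterozygote count given allele counts, under the
# null of random union of gametes; named by heterozygote count
hwe_het_probabilities <- function(n_ref, n_alt) {
  n <- (n_ref + n_alt) / 2
  rare <- min(n_ref, n_alt)
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    n_aa <- (rare - h) / 2
    n_AA <- n - n_aa - h
    lfactorial(n) - lfactorial(n_AA) - lfactorial(h) - lfactorial(n_aa) +
      h * log(2) + lfactorial(n_ref) + lfactorial(n_alt) - lfactorial(2 * n)
  }, 0)
  # normalise in log space for numerical safety
  p <- exp(logp - max(logp))
  stats::setNames(p / sum(p), hets)
}

#' Case-control allele chi-square test
#'
#' Pearson chi-square on the 2x2 table of allele counts, df = 1, no
#' continuity correction.
#'
#' @param case,control Length-2 integer vectors \code{c(ref, alt)} of
#'   allele counts.
#' @return An object of class \code{htest}.
#' @export
allele_chi_square <- function(case, control) {
  tab <- rbind(case = as.integer(case), control = as.integer(control))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("a margin of the allele table is zero")
  }
  suppressWarnings(stats::chisq.test(tab, correct = FALSE))
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact hypergeometric enumeration; the two-sided p-value is the sum of
#' the probabilities of all tables (at fixed margins) at most as probable
#' as the observed one.
#'
#' @param a,b,c,d Cell counts: \code{a}, \code{b} = first row,
#'   \code{c}, \code{d} = second row.
#' @return An object of class \code{htest}.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  m <- a + c
  n_col2 <- b + d
  k <- a + b
  if (m + n_col2 == 0 || k == 0 || (c + d) == 0 || m == 0 || n_col2 == 0) {
    stop("degenerate 2x2 table (empty margin)")
  }
  support <- max(0, k - n_col2):min(k, m)
  probs <- stats::dhyper(support, m, n_col2, k)
  p_obs <- stats::dhyper(a, m, n_col2, k)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  out <- list(statistic = c(a = a), parameter = NULL, p.value = p,
              method = "Fisher exact test (two-sided, tables at most as probable)",
              data.name = sprintf("2x2 table (%d,%d;%d,%d)", a, b, c, d))
  class(out) <- "htest"
  out
}

#' Per-haplotype Fisher exact tests from case/control haplotype counts
#'
#' For each haplotype, builds the 2x2 presence/absence table (this
#' haplotype vs all others, cases vs controls) and applies
#' [fisher_exact_2x2()].
#'
#' @param case_counts,control_counts Named integer vectors of haplotype
#'   counts (same haplotype set).
#' @return Data frame with \code{haplotype}, case/control counts and the
#'   two-sided \code{p_value}.
#' @export
fisher_haplotype_test <- function(case_counts, control_counts) {
  stopifnot(length(case_counts) == length(control_counts))
  if (length(case_counts) < 2 && is.null(names(case_counts))) {
    stop("need counts over at least two haplotype classes")
  }
  haps <- names(case_counts)
  if (is.null(haps)) haps <- paste0("h", seq_along(case_counts))
  n_case <- sum(case_counts)
  n_ctrl <- sum(control_counts)
  p <- vapply(seq_along(case_counts), function(i) {
    fisher_exact_2x2(case_counts[i], n_case - case_counts[i],
                     control_counts[i], n_ctrl - control_counts[i])$p.value
  }, 0)
  data.frame(haplotype = haps, case = as.integer(case_counts),
             control = as.integer(control_counts), p_value = p,
             stringsAsFactors = FALSE)
}

#' Linkage-disequilibrium delta statistic
#'
#' The population-attributable-risk statistic
#' \deqn{\delta = (F_d - F_c) / (1 - F_c)} where \eqn{F_d} and \eqn{F_c}
#' are the haplotype (or allele) frequencies on disease and control
#' chromosomes. \eqn{\delta(F, F) = 0}, \eqn{\delta(x, 0) = x}, and the
#' value is returned signed (negative when the haplotype is rarer in
#' disease chromosomes).
#'
#' @param f_disease Frequency on disease chromosomes, in \[0, 1\].
#' @param f_control Frequency on control chromosomes, in \[0, 1).
#' @return A \code{delta_result} list: \code{f_disease}, \code{f_control},
#'   \code{delta}.
#' @export
delta_statistic <- function(f_disease, f_control) {
  stopifnot(f_disease >= 0, f_disease <= 1, f_control >= 0)
  if (f_control >= 1) stop("delta is undefined for a control frequency of 1")
  structure(list(f_disease = f_disease, f_control = f_control,
                 delta = (f_disease - f_control) / (1 - f_control)),
            class = "delta_result")
}

#' @export
print.delta_result <- function(x, ...) {
  cat(sprintf("delta = %.3f (Fd = %.3f, Fc = %.3f)\n", x$delta, x$f_disease,
              x$f_control))
  invisible(x)
}

#' Delta statistics for a haplotype frequency table
#'
#' Applies [delta_statistic()] to every row of a six-SNP haplotype
#' frequency table (as in \code{load_fixture("table3")}) that is present
#' on disease chromosomes, and flags rows where the computed value
#' disagrees with a printed reference value at 3 decimals (the packaged
#' table contains one internally inconsistent printed delta, for
#' T-T-G-G-A-C, where the formula gives a negative value).
#'
#' @param tab Data frame with columns \code{haplotype},
#'   \code{freq_control}, \code{freq_mjd} and optionally
#'   \code{delta_printed}.
#' @return The table with computed \code{delta} (signed, full precision),
#'   \code{delta_3dp}, and \code{note} flagging printed-value
#'   discrepancies.
#' @export
delta_table <- function(tab = load_fixture("table3")) {
  delta <- mapply(function(fd, fc) delta_statistic(fd, fc)$delta,
                  tab$freq_mjd, tab$freq_control)
  delta[tab$freq_mjd == 0] <- NA_real_
  out <- tab
  out$delta <- delta
  out$delta_3dp <- round(delta, 3)
  out$note <- ""
  if ("delta_printed" %in% names(tab)) {
    bad <- !is.na(tab$delta_printed) & !is.na(out$delta_3dp) &
      out$delta_3dp != tab$delta_printed
    out$note[bad] <- "computed delta disagrees with printed value"
  }
  out
}
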