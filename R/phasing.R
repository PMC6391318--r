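#' Phasing configuration
#'
#' @param posterior_threshold Haplotype pairs with posterior at or below
#'   this value are dropped from downstream haplotype lists. The default
#'   0.6 with a strict \code{>} comparison retains only pairs supported
#'   with probability greater than 0.6.
#' @param em_max_iterations,em_tolerance EM stopping rule: iterate until
#'   the observed-data log-likelihood improves by less than
#'   \code{em_tolerance} or \code{em_max_iterations} is reached.
#' @param seed Optional integer seed (only used by optional random
#'   restarts; the default estimator is deterministic).
#' @return A \code{phasing_config} list.
#' @export
phasing_config <- function(posterior_threshold = 0.6,
                           em_max_iterations = 1000,
                           em_tolerance = 1e-8,
                           seed = NULL) {
  stopifnot(posterior_threshold > 0, posterior_threshold <= 1,
            em_tolerance > 0, em_max_iterations >= 1)
  structure(list(posterior_threshold = posterior_threshold,
                 em_max_iterations = em_max_iterations,
                 em_tolerance = em_tolerance,
                 seed = seed),
            class = "phasing_config")
}

#' Marker id of the expansion pseudo-marker
#'
#' The (CAG)n expansion is carried through phasing as a binary pseudo-marker
#' at the anchor position ("E" = expanded, "N" = normal), so "in phase with
#' the expansion" is an ordinary phase query.
#' @return The string \code{"MJD_EXP"}.
#' @export
expansion_marker <- function() "MJD_EXP"

expansion_genotype <- function(count) {
  if (is.na(count)) return(NULL)
  switch(as.character(count),
         "0" = c("N", "N"), "1" = c("E", "N"), "2" = c("E", "E"))
}

#' Phase a family by Mendelian segregation
#'
#' For every non-founding individual and every marker, the phase (paternal
#' vs maternal origin of the two alleles) is fixed whenever Mendelian
#' transmission forces it: the child is homozygous, or exactly one
#' parent-of-origin assignment of the heterozygous alleles is compatible
#' with the parents' genotypes (e.g. one parent homozygous). Markers whose
#' phase is not forced are left unresolved, never guessed. Founder carriers
#' are phased through their transmitted gametes: the alleles co-transmitted
#' with the expansion form their disease-side haplotype. A child allele
#' absent from both compatible parental assignments is a Mendelian
#' inconsistency and aborts phasing of the family with a report naming
#' every offending individual and marker.
#'
#' @param ped A [pedigree()].
#' @param gt A [genotype_table()] covering the family's individuals.
#' @param panel A \code{marker_panel}.
#' @return A \code{phased_set}: list with \code{family_id}, \code{pairs}
#'   (per individual: named allele vectors \code{pat} and \code{mat} over
#'   the panel markers plus the expansion pseudo-marker, \code{NA} where
#'   unresolved; \code{resolved} flags; \code{posterior} 1 at resolved
#'   markers; \code{method}; \code{disease_side} in
#'   \code{c("a","b","both","unknown")} with "a" = paternal), and
#'   \code{conflicts} (markers where a founder's reconstructed gametes
#'   disagree, indicating within-family recombination).
#' @export
phase_by_segregation <- function(ped, gt, panel) {
  markers <- c(panel$marker_id, expansion_marker())
  geno <- function(id, m) {
    if (m == expansion_marker()) {
      expansion_genotype(ped$expansion_count[match(id, ped$individual_id)])
    } else {
      genotype_of(gt, id, m)
    }
  }
  mendel_errors <- list()
  pairs <- list()
  for (id in ped$individual_id) {
    row <- ped[ped$individual_id == id, ]
    pat <- mat <- stats::setNames(rep(NA_character_, length(markers)), markers)
    resolved <- stats::setNames(rep(FALSE, length(markers)), markers)
    is_founder <- is.na(row$father_id) && is.na(row$mother_id)
    for (m in markers) {
      g <- geno(id, m)
      if (is.null(g)) next
      if (is_founder) next
      gf <- if (!is.na(row$father_id)) geno(row$father_id, m) else NULL
      gm <- if (!is.na(row$mother_id)) geno(row$mother_id, m) else NULL
      from_f <- if (is.null(gf)) unique(g) else unique(gf)
      from_m <- if (is.null(gm)) unique(g) else unique(gm)
      if (g[1] == g[2]) {
        if (!(g[1] %in% from_f) || !(g[1] %in% from_m)) {
          mendel_errors[[length(mendel_errors) + 1]] <-
            data.frame(individual_id = id, marker_id = m,
                       stringsAsFactors = FALSE)
          next
        }
        pat[m] <- mat[m] <- g[1]
        resolved[m] <- TRUE
      } else {
        v1 <- (g[1] %in% from_f) && (g[2] %in% from_m)
        v2 <- (g[2] %in% from_f) && (g[1] %in% from_m)
        if (!v1 && !v2) {
          mendel_errors[[length(mendel_errors) + 1]] <-
            data.frame(individual_id = id, marker_id = m,
                       stringsAsFactors = FALSE)
        } else if (v1 && !v2) {
          pat[m] <- g[1]; mat[m] <- g[2]; resolved[m] <- TRUE
        } else if (v2 && !v1) {
          pat[m] <- g[2]; mat[m] <- g[1]; resolved[m] <- TRUE
        }
      }
    }
    pairs[[id]] <- list(individual_id = id, pat = pat, mat = mat,
                        resolved = resolved,
                        posterior = ifelse(resolved, 1, NA_real_),
                        method = "segregation",
                        expansion_count = row$expansion_count,
                        is_founder = is_founder,
                        disease_side = "unknown",
                        gametes = list())
  }
  if (length(mendel_errors) > 0) {
    err <- do.call(rbind, mendel_errors)
    stop("Mendelian inconsistency in family ", ped$family_id[1], ": ",
         paste(sprintf("%s@%s", err$individual_id, err$marker_id),
               collapse = ", "))
  }

  # reconstruct founder gametes from their children's resolved paternal or
  # maternal alleles (one gamete per child; no intra-panel recombination
  # assumed)
  conflicts <- list()
  for (id in ped$individual_id) {
    kids_f <- ped$individual_id[!is.na(ped$father_id) & ped$father_id == id]
    kids_m <- ped$individual_id[!is.na(ped$mother_id) & ped$mother_id == id]
    gametes <- list()
    for (k in kids_f) {
      gam <- pairs[[k]]$pat
      gam[!pairs[[k]]$resolved] <- NA
      gametes[[k]] <- gam
    }
    for (k in kids_m) {
      gam <- pairs[[k]]$mat
      gam[!pairs[[k]]$resolved] <- NA
      gametes[[k]] <- gam
    }
    pairs[[id]]$gametes <- gametes
    if (pairs[[id]]$is_founder && !is.na(pairs[[id]]$expansion_count) &&
        pairs[[id]]$expansion_count == 1 && length(gametes) > 0) {
      e_side <- !is.na(vapply(gametes, `[`, "", expansion_marker())) &
        vapply(gametes, `[`, "", expansion_marker()) == "E"
      merged_e <- merge_gametes(gametes[e_side])
      merged_n <- merge_gametes(gametes[!e_side &
        !is.na(vapply(gametes, `[`, "", expansion_marker()))])
      for (m in c(merged_e$conflicts, merged_n$conflicts)) {
        conflicts[[length(conflicts) + 1]] <-
          data.frame(individual_id = id, marker_id = m,
                     stringsAsFactors = FALSE)
      }
      pat <- pairs[[id]]$pat
      mat <- pairs[[id]]$mat
      if (!is.null(merged_e$hap)) {
        pat[!is.na(merged_e$hap)] <- merged_e$hap[!is.na(merged_e$hap)]
      }
      if (!is.null(merged_n$hap)) {
        mat[!is.na(merged_n$hap)] <- merged_n$hap[!is.na(merged_n$hap)]
      }
      pat[expansion_marker()] <- "E"
      mat[expansion_marker()] <- "N"
      # complete the opposite side from the founder's own genotype
      for (m in markers) {
        g <- geno(id, m)
        if (is.null(g)) next
        if (!is.na(pat[m]) && is.na(mat[m]) && pat[m] %in% g) {
          mat[m] <- if (g[1] == pat[m]) g[2] else g[1]
        } else if (!is.na(mat[m]) && is.na(pat[m]) && mat[m] %in% g) {
          pat[m] <- if (g[1] == mat[m]) g[2] else g[1]
        }
      }
      pairs[[id]]$pat <- pat
      pairs[[id]]$mat <- mat
      pairs[[id]]$resolved <- !is.na(pat) & !is.na(mat)
      pairs[[id]]$posterior <- ifelse(pairs[[id]]$resolved, 1, NA_real_)
    }
  }
  for (id in names(pairs)) {
    p <- pairs[[id]]
    if (!is.na(p$expansion_count) && p$expansion_count == 2) {
      pairs[[id]]$disease_side <- "both"
    } else if (isTRUE(p$resolved[expansion_marker()]) &&
               !is.na(p$expansion_count) && p$expansion_count == 1) {
      pairs[[id]]$disease_side <-
        if (p$pat[expansion_marker()] == "E") "a" else "b"
    } else if (p$is_founder && !is.na(p$expansion_count) &&
               p$expansion_count == 1 &&
               isTRUE(p$pat[expansion_marker()] == "E")) {
      pairs[[id]]$disease_side <- "a"
    }
  }
  conflicts <- if (length(conflicts) > 0) do.call(rbind, conflicts) else
    data.frame(individual_id = character(0), marker_id = character(0))
  structure(list(family_id = ped$family_id[1], pairs = pairs,
                 conflicts = conflicts, markers = markers),
            class = "phased_set")
}

merge_gametes <- function(gams) {
  if (length(gams) == 0) {
    return(list(hap = NULL, conflicts = character(0)))
  }
  markers <- names(gams[[1]])
  hap <- stats::setNames(rep(NA_character_, length(markers)), markers)
  conf <- character(0)
  for (m in markers) {
    vals <- unique(stats::na.omit(vapply(gams, `[`, "", m)))
    if (length(vals) == 1) hap[m] <- vals
    if (length(vals) > 1) conf <- c(conf, m)
  }
  list(hap = hap, conflicts = conf)
}

#' @export
print.phased_set <- function(x, ...) {
  n_res <- vapply(x$pairs, function(p) sum(p$resolved), 0L)
  cat(sprintf("phased_set: family %s, %d individuals, %d/%d markers resolved on average\n",
              x$family_id, length(x$pairs),
              round(mean(n_res)), length(x$markers)))
  invisible(x)
}

#' Disease haplotype(s) co-segregating with the expansion in one family
#'
#' Collects, across all phased expansion carriers, the haplotype in phase
#' with the expansion, and reduces them to the family's disease
#' haplotype(s) by consensus. Observations are grouped into at most k
#' compatible clusters, where k is the number of expanded chromosomes
#' entering the family through its founders (one for a typical dominant
#' family; two when both parental lines carry an expansion, as in the
#' family of a homozygous patient). Carriers whose expansion-phased
#' haplotypes cannot be reconciled within k clusters indicate within-family
#' recombination and raise an error naming the family.
#'
#' @param phased A \code{phased_set} from [phase_by_segregation()].
#' @param ped The matching [pedigree()].
#' @param panel The \code{marker_panel} used for phasing.
#' @return A list with \code{snp} (a \code{snp_haplotypes} set, one row per
#'   disease haplotype; \code{NA} at markers no carrier resolved),
#'   \code{str} (matching \code{str_haplotypes}, \code{NULL} when the
#'   panel holds no STRs), and \code{n_chromosomes} (carrier-side
#'   observations per haplotype).
#' @export
disease_haplotype_for_family <- function(phased, ped, panel) {
  obs <- list()
  for (p in phased$pairs) {
    side <- p$disease_side
    if (side == "a") obs[[length(obs) + 1]] <- p$pat
    if (side == "b") obs[[length(obs) + 1]] <- p$mat
    if (side == "both") {
      obs[[length(obs) + 1]] <- p$pat
      obs[[length(obs) + 1]] <- p$mat
    }
  }
  if (length(obs) == 0) {
    stop("no phased expansion carrier in family ", phased$family_id)
  }
  founder_ids <- founders(ped)
  k <- sum(ped$expansion_count[ped$individual_id %in% founder_ids],
           na.rm = TRUE)
  k <- max(k, 1L)
  obs <- obs[order(-vapply(obs, function(o) sum(!is.na(o)), 0L))]
  clusters <- list()
  sizes <- integer(0)
  for (o in obs) {
    placed <- FALSE
    for (ci in seq_along(clusters)) {
      cons <- clusters[[ci]]
      both <- !is.na(cons) & !is.na(o)
      if (all(cons[both] == o[both])) {
        cons[is.na(cons)] <- o[is.na(cons)]
        clusters[[ci]] <- cons
        sizes[ci] <- sizes[ci] + 1L
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      clusters[[length(clusters) + 1]] <- o
      sizes <- c(sizes, 1L)
    }
  }
  if (length(clusters) > k) {
    stop("carriers of family ", phased$family_id,
         " disagree on the co-segregating haplotype (",
         length(clusters), " incompatible haplotypes for ", k,
         " founder expansion(s)); possible within-family recombination")
  }
  snp_ids <- snp_markers(panel)
  str_ids <- str_markers(panel)
  snp_mat <- do.call(rbind, lapply(clusters, function(cons) cons[snp_ids]))
  colnames(snp_mat) <- snp_ids
  snp <- snp_haplotypes(snp_mat, family = phased$family_id,
                        disease_flag = TRUE, inference = "segregation")
  str <- NULL
  if (length(str_ids) > 0) {
    str_mat <- do.call(rbind, lapply(clusters, function(cons) {
      suppressWarnings(as.integer(cons[str_ids]))
    }))
    colnames(str_mat) <- str_ids
    str <- str_haplotypes(str_mat, family = phased$family_id,
                          disease_flag = TRUE)
  }
  list(snp = snp, str = str, n_chromosomes = sizes)
}

#' EM estimation of haplotype frequencies from unphased genotypes
#'
#' Classic expectation-maximisation over the haplotype pairs compatible
#' with each (unrelated) individual's multilocus genotype. Missing
#' genotypes are marginalised over the marker's domain. Frequencies are
#' initialised uniformly over every haplotype compatible with at least one
#' individual, making the estimator deterministic. The observed-data
#' log-likelihood is non-decreasing across iterations; iteration stops once
#' it improves by less than \code{config$em_tolerance}.
#'
#' @param gt A [genotype_table()] of unrelated individuals.
#' @param panel A \code{marker_panel}.
#' @param markers Markers to phase over (default: the panel's SNPs).
#' @param config A [phasing_config()].
#' @return A list with \code{frequencies} (named, summing to 1),
#'   \code{pairs} (data frame: \code{individual_id}, \code{hap_a},
#'   \code{hap_b}, \code{posterior}, \code{retained} — posteriors sum to 1
#'   within individual, and \code{retained} applies the strict
#'   \code{posterior > threshold} rule), \code{loglik} (trace),
#'   \code{n_iter} and \code{converged}.
#' @export
em_haplotype_frequencies <- function(gt, panel, markers = snp_markers(panel),
                                     config = phasing_config()) {
  ids <- unique(gt$individual_id)
  if (length(ids) < 1) stop("need at least one individual")
  pair_sets <- lapply(ids, function(id) {
    enumerate_pairs(gt, panel, id, markers)
  })
  names(pair_sets) <- ids
  universe <- sort(unique(unlist(lapply(pair_sets, function(ps) {
    c(ps$hap_a, ps$hap_b)
  }))))
  f <- stats::setNames(rep(1 / length(universe), length(universe)), universe)
  n2 <- 2 * length(ids)
  loglik <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(config$em_max_iterations)) {
    counts <- stats::setNames(numeric(length(universe)), universe)
    ll <- 0
    for (ps in pair_sets) {
      w <- ps$coef * f[ps$hap_a] * f[ps$hap_b]
      tot <- sum(w)
      if (tot <= 0) stop("no compatible haplotype pair for an individual")
      ll <- ll + log(tot)
      w <- w / tot
      for (j in seq_along(w)) {
        counts[ps$hap_a[j]] <- counts[ps$hap_a[j]] + w[j]
        counts[ps$hap_b[j]] <- counts[ps$hap_b[j]] + w[j]
      }
    }
    f <- counts / n2
    loglik <- c(loglik, ll)
    if (iter > 1 && abs(ll - loglik[iter - 1]) < config$em_tolerance) {
      converged <- TRUE
      break
    }
  }
  pairs <- do.call(rbind, lapply(ids, function(id) {
    ps <- pair_sets[[id]]
    w <- ps$coef * f[ps$hap_a] * f[ps$hap_b]
    w <- if (sum(w) > 0) w / sum(w) else rep(1 / length(w), length(w))
    data.frame(individual_id = id, hap_a = ps$hap_a, hap_b = ps$hap_b,
               posterior = unname(w),
               retained = unname(w) > config$posterior_threshold,
               stringsAsFactors = FALSE)
  }))
  rownames(pairs) <- NULL
  list(frequencies = f, pairs = pairs, loglik = loglik,
       n_iter = length(loglik), converged = converged)
}

enumerate_pairs <- function(gt, panel, id, markers) {
  per_marker <- lapply(markers, function(m) {
    g <- genotype_of(gt, id, m)
    if (is.null(g)) {
      i <- match(m, panel$marker_id)
      dom <- panel$domain_parsed[[i]]
      if (panel$kind[i] == "STR") dom <- as.character(seq(dom[1], dom[2]))
      expand_ordered(dom)
    } else if (g[1] == g[2]) {
      list(c(g[1], g[1]))
    } else {
      list(c(g[1], g[2]), c(g[2], g[1]))
    }
  })
  n_comb <- prod(vapply(per_marker, length, 0L))
  if (n_comb > 2e5) {
    stop("too many compatible phase configurations for individual ", id,
         " (", n_comb, "); reduce markers or missingness")
  }
  h1 <- h2 <- matrix("", nrow = n_comb, ncol = length(markers))
  reps <- n_comb
  for (j in seq_along(markers)) {
    opts <- per_marker[[j]]
    k <- length(opts)
    reps <- reps / k
    idx <- rep(rep(seq_len(k), each = reps), length.out = n_comb)
    h1[, j] <- vapply(opts, `[`, "", 1)[idx]
    h2[, j] <- vapply(opts, `[`, "", 2)[idx]
  }
  key1 <- apply(h1, 1, paste, collapse = "-")
  key2 <- apply(h2, 1, paste, collapse = "-")
  a <- pmin(key1, key2)
  b <- pmax(key1, key2)
  keep <- !duplicated(paste(a, b, sep = "|"))
  a <- a[keep]; b <- b[keep]
  list(hap_a = a, hap_b = b, coef = ifelse(a == b, 1, 2))
}

expand_ordered <- function(dom) {
  out <- list()
  for (x in dom) for (y in dom) out[[length(out) + 1]] <- c(x, y)
  out
}
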