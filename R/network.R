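#' Mutational step distance between two STR haplotypes
#'
#' Two counting conventions over equal-length repeat-count vectors:
#' \describe{
#'   \item{locus_count}{number of loci whose repeat counts differ — one
#'     "step" per changed locus regardless of repeat distance;}
#'   \item{stepwise_sum}{sum over loci of the absolute repeat-count
#'     difference — the number of single-repeat mutations needed under a
#'     strict stepwise mutation model.}
#' }
#' Both are metrics: symmetric, zero only between identical haplotypes,
#' and satisfying the triangle inequality.
#'
#' @param h1,h2 Integer vectors of repeat counts (same length).
#' @param mode \code{"locus_count"} (default) or \code{"stepwise_sum"}.
#' @return Non-negative integer.
#' @export
step_distance <- function(h1, h2, mode = c("locus_count", "stepwise_sum")) {
  mode <- match.arg(mode)
  h1 <- as.integer(h1)
  h2 <- as.integer(h2)
  if (length(h1) != length(h2)) stop("haplotype length mismatch")
  if (mode == "locus_count") sum(h1 != h2) else sum(abs(h1 - h2))
}

step_distances_to <- function(mat, ref, mode) {
  if (mode == "locus_count") {
    rowSums(mat != matrix(ref, nrow(mat), length(ref), byrow = TRUE))
  } else {
    rowSums(abs(mat - matrix(ref, nrow(mat), length(ref), byrow = TRUE)))
  }
}

#' Modal (ancestral) STR haplotype of a sample
#'
#' The ancestral haplotype of a SNP-defined lineage is taken as the
#' locus-wise modal haplotype: at each locus the most frequent repeat
#' count in the sample. When a locus has tied modal alleles, candidate
#' ancestors over all tied combinations are compared and the one
#' minimising the total step distance to the sample is chosen; remaining
#' ties are broken toward the numerically smallest allele, locus by locus.
#' Every applied tie-break is reported.
#'
#' @param haps A \code{str_haplotypes} set or an integer matrix
#'   (rows = chromosomes).
#' @param mode Distance mode used for tie-breaking (see
#'   [step_distance()]).
#' @return A list: \code{haplotype} (named integer vector), \code{ties}
#'   (data frame \code{locus}, \code{candidates}, \code{chosen}; empty
#'   when no locus was tied).
#' @export
modal_haplotype <- function(haps, mode = c("locus_count", "stepwise_sum")) {
  mode <- match.arg(mode)
  mat <- if (is.matrix(haps)) haps else hap_matrix(haps)
  storage.mode(mat) <- "integer"
  if (nrow(mat) == 0) stop("empty haplotype sample")
  loci <- colnames(mat)
  if (is.null(loci)) loci <- paste0("L", seq_len(ncol(mat)))
  modal_sets <- lapply(seq_len(ncol(mat)), function(j) {
    tab <- table(mat[, j])
    sort(as.integer(names(tab)[tab == max(tab)]))
  })
  tied <- which(lengths(modal_sets) > 1)
  if (length(tied) == 0) {
    hap <- vapply(modal_sets, `[`, 0L, 1)
    names(hap) <- loci
    return(list(haplotype = hap,
                ties = data.frame(locus = character(0),
                                  candidates = character(0),
                                  chosen = integer(0))))
  }
  grid <- expand.grid(modal_sets[tied], KEEP.OUT.ATTRS = FALSE)
  base <- vapply(modal_sets, `[`, 0L, 1)
  candidates <- t(apply(grid, 1, function(row) {
    hap <- base
    hap[tied] <- as.integer(row)
    hap
  }))
  totals <- apply(candidates, 1, function(hap) {
    sum(step_distances_to(mat, hap, mode))
  })
  best <- which(totals == min(totals))
  # residual tie: numerically smallest allele, locus by locus
  pick <- best[do.call(order, as.data.frame(candidates[best, , drop = FALSE]))[1]]
  hap <- candidates[pick, ]
  names(hap) <- loci
  ties <- data.frame(
    locus = loci[tied],
    candidates = vapply(modal_sets[tied], paste, "", collapse = "/"),
    chosen = unname(hap[tied]),
    stringsAsFactors = FALSE)
  list(haplotype = hap, ties = ties)
}

#' Minimum-spanning network over distinct STR haplotypes
#'
#' Builds the minimum-spanning network of the sample's distinct haplotypes
#' under the chosen step distance: Kruskal's construction in which all
#' co-minimal edges are retained (every edge of some minimum spanning
#' tree), yielding a network rather than an arbitrarily tie-broken tree.
#' Node sizes carry haplotype multiplicities; the locus-wise modal
#' haplotype is marked as the ancestral node (added as an inferred,
#' zero-multiplicity median node if it was not observed).
#'
#' @param haps A \code{str_haplotypes} set or integer matrix of repeat
#'   counts (rows = chromosomes, possibly repeated).
#' @param mode Distance mode, see [step_distance()].
#' @return A \code{haplotype_network}: list with \code{graph} (an igraph
#'   object; vertex attributes \code{label}, \code{multiplicity},
#'   \code{ancestral}, \code{inferred}; edge attribute \code{weight}),
#'   \code{nodes} (data frame of distinct haplotypes), \code{ancestral}
#'   (node label), \code{ties} (modal tie report) and \code{mode}.
#' @export
build_network <- function(haps, mode = c("locus_count", "stepwise_sum")) {
  mode <- match.arg(mode)
  mat <- if (is.matrix(haps)) haps else hap_matrix(haps)
  storage.mode(mat) <- "integer"
  if (nrow(mat) == 0) stop("empty haplotype sample")
  keys <- apply(mat, 1, paste, collapse = "-")
  modal <- modal_haplotype(mat, mode)
  anc_key <- paste(modal$haplotype, collapse = "-")
  uniq <- !duplicated(keys)
  nodes <- mat[uniq, , drop = FALSE]
  labels <- keys[uniq]
  mult <- as.integer(table(keys)[labels])
  inferred <- rep(FALSE, length(labels))
  if (!(anc_key %in% labels)) {
    nodes <- rbind(nodes, modal$haplotype)
    labels <- c(labels, anc_key)
    mult <- c(mult, 0L)
    inferred <- c(inferred, TRUE)
  }
  n <- length(labels)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- labels
  igraph::V(g)$label <- labels
  igraph::V(g)$multiplicity <- mult
  igraph::V(g)$ancestral <- labels == anc_key
  igraph::V(g)$inferred <- inferred
  if (n > 1) {
    d <- matrix(0L, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d[i, j] <- step_distance(nodes[i, ], nodes[j, ], mode)
      }
    }
    edges <- msn_edges(d)
    if (nrow(edges) > 0) {
      g <- igraph::add_edges(g, t(as.matrix(edges[, c("i", "j")])),
                             weight = edges$w)
    }
  }
  structure(list(graph = g,
                 nodes = data.frame(label = labels,
                                    multiplicity = mult,
                                    ancestral = labels == anc_key,
                                    inferred = inferred,
                                    as.data.frame(nodes, row.names = NULL),
                                    stringsAsFactors = FALSE),
                 ancestral = anc_key, ties = modal$ties, mode = mode),
            class = "haplotype_network")
}

# all-co-minimal Kruskal: at each weight level, keep every edge of that
# weight joining components as they stood before the level was processed
msn_edges <- function(d) {
  n <- nrow(d)
  comp <- seq_len(n)
  out <- list()
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  w <- d[upper.tri(d)]
  for (lev in sort(unique(w))) {
    at_level <- which(w == lev)
    before <- comp
    for (e in at_level) {
      i <- pairs[e, 1]; j <- pairs[e, 2]
      if (before[i] != before[j]) {
        out[[length(out) + 1]] <- data.frame(i = i, j = j, w = lev)
        if (comp[i] != comp[j]) {
          comp[comp == comp[j]] <- comp[i]
        }
      }
    }
    if (length(unique(comp)) == 1) break
  }
  if (length(out) == 0) {
    data.frame(i = integer(0), j = integer(0), w = numeric(0))
  } else {
    do.call(rbind, out)
  }
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf("haplotype_network (%s): %d nodes, %d edges, ancestral %s%s\n",
              x$mode, igraph::vcount(x$graph), igraph::ecount(x$graph),
              x$ancestral,
              if (any(x$nodes$inferred)) " (inferred median)" else ""))
  invisible(x)
}

#' Export a haplotype network to GraphML or DOT
#'
#' Writes the network with its multiplicity and ancestral-node annotations
#' in a format any generic graph reader can parse.
#'
#' @param net A \code{haplotype_network} from [build_network()].
#' @param path Output file path.
#' @param format \code{"graphml"} or \code{"dot"}.
#' @return \code{path}, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  if (!inherits(net, "haplotype_network")) {
    stop("export_network() needs a haplotype_network")
  }
  g <- net$graph
  if (format == "dot") {
    # DOT has no boolean type; write flags as 0/1
    for (at in c("ancestral", "inferred")) {
      g <- igraph::set_vertex_attr(g, at,
                                   value = as.integer(
                                     igraph::vertex_attr(g, at)))
    }
  }
  igraph::write_graph(g, path, format = format)
  invisible(path)
}
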