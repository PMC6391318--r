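#' Simulate disease chromosomes descending from a founder haplotype
#'
#' Star genealogy: each of \code{n_chromosomes} descends independently
#' from the founder for \code{t_generations}. Per generation, every locus
#' mutates with probability \code{model$mu} by one repeat unit up or down
#' (equal probability, floored at 1 repeat), and with probability
#' \code{model$c} the segment downstream of a uniformly chosen inter-locus
#' breakpoint is replaced by a draw from the background haplotype pool.
#' The star genealogy is exactly the generative model under which the
#' dating identity \eqn{E[\lambda] = \varepsilon t} holds, where
#' \eqn{\lambda} counts the generations in which a chromosome changed;
#' those realized change counts are recorded in the truth output (the
#' observable locus-count distance to the founder underestimates them
#' once loci start changing twice).
#'
#' @param founder Integer vector of founder repeat counts (length
#'   \code{model$n_loci}).
#' @param n_chromosomes Number of independent descendant chromosomes.
#' @param t_generations Generations of evolution (>= 0).
#' @param model A [rate_model()].
#' @param background_pool Integer matrix of background haplotypes
#'   (recombination donors); required when \code{model$c > 0}.
#' @param background_freqs Optional draw frequencies for the pool rows
#'   (default uniform; must sum to 1).
#' @param seed Integer seed; the whole simulation runs under it.
#' @return A list: \code{haplotypes} (a \code{str_haplotypes} set) and
#'   \code{truth} (data frame per chromosome: \code{n_changed_generations},
#'   \code{n_mutation_events}, \code{n_recombination_events}; plus the
#'   parameter echo as attributes).
#' @export
simulate_founder_sample <- function(founder, n_chromosomes, t_generations,
                                    model = rate_model(),
                                    background_pool = NULL,
                                    background_freqs = NULL,
                                    seed = 1) {
  founder <- as.integer(founder)
  stopifnot(n_chromosomes >= 1, t_generations >= 0,
            length(founder) == model$n_loci, all(founder >= 1))
  if (model$c > 0 && is.null(background_pool)) {
    stop("recombination (c > 0) requires a background haplotype pool")
  }
  if (!is.null(background_pool)) {
    background_pool <- as.matrix(background_pool)
    storage.mode(background_pool) <- "integer"
    stopifnot(ncol(background_pool) == model$n_loci)
    if (is.null(background_freqs)) {
      background_freqs <- rep(1 / nrow(background_pool),
                              nrow(background_pool))
    }
    stopifnot(abs(sum(background_freqs) - 1) < 1e-8)
  }
  L <- model$n_loci
  out <- withr_seed(seed, {
    if (model$c == 0) {
      sim_star_no_recomb(founder, n_chromosomes, t_generations, model$mu)
    } else {
      sim_star_generations(founder, n_chromosomes, t_generations, model,
                           background_pool, background_freqs)
    }
  })
  mat <- out$mat
  colnames(mat) <- names(founder) %||% str_locus_names()[seq_len(L)]
  haps <- str_haplotypes(mat, family = sprintf("sim%03d",
                                               seq_len(n_chromosomes)),
                         disease_flag = TRUE)
  truth <- out$truth
  attr(truth, "founder") <- founder
  attr(truth, "model") <- model
  attr(truth, "t_generations") <- t_generations
  attr(truth, "seed") <- seed
  list(haplotypes = haps, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exact shortcut for c = 0: per locus, the per-generation Bernoulli(mu)
# process yields Binomial(t, mu) events; their generation stamps are a
# uniform draw without replacement, so changed-generation counts are the
# union size across loci
sim_star_no_recomb <- function(founder, n, t, mu) {
  L <- length(founder)
  mat <- matrix(founder, n, L, byrow = TRUE)
  n_changed <- n_events <- integer(n)
  for (i in seq_len(n)) {
    k <- stats::rbinom(L, t, mu)
    gens <- integer(0)
    for (l in seq_len(L)) {
      if (k[l] == 0) next
      steps <- sample(c(-1L, 1L), k[l], replace = TRUE)
      val <- founder[l]
      for (s in steps) val <- max(1L, val + s)
      mat[i, l] <- val
      gens <- c(gens, sample.int(t, k[l]))
    }
    n_events[i] <- sum(k)
    n_changed[i] <- length(unique(gens))
  }
  list(mat = mat,
       truth = data.frame(chromosome = seq_len(n),
                          n_changed_generations = n_changed,
                          n_mutation_events = n_events,
                          n_recombination_events = 0L))
}

sim_star_generations <- function(founder, n, t, model, pool, freqs) {
  L <- model$n_loci
  mat <- matrix(founder, n, L, byrow = TRUE)
  n_changed <- n_mut <- n_rec <- integer(n)
  for (g in seq_len(t)) {
    mut <- matrix(stats::runif(n * L) < model$mu, n, L)
    if (any(mut)) {
      steps <- matrix(0L, n, L)
      steps[mut] <- sample(c(-1L, 1L), sum(mut), replace = TRUE)
      mat <- pmax(1L, mat + steps)
    }
    rec <- stats::runif(n) < model$c
    for (i in which(rec)) {
      bp <- sample.int(L - 1, 1)
      donor <- pool[sample.int(nrow(pool), 1, prob = freqs), ]
      mat[i, (bp + 1):L] <- donor[(bp + 1):L]
    }
    changed <- rowSums(mut) > 0 | rec
    n_changed <- n_changed + changed
    n_mut <- n_mut + rowSums(mut)
    n_rec <- n_rec + rec
  }
  list(mat = mat,
       truth = data.frame(chromosome = seq_len(n),
                          n_changed_generations = n_changed,
                          n_mutation_events = n_mut,
                          n_recombination_events = n_rec))
}

#' Simulate a nuclear (or three-generation) family with unphased genotypes
#'
#' Founders draw haplotype pairs from a pool; children inherit one
#' haplotype from each parent with no intra-panel recombination. The
#' expansion travels on the pool haplotypes flagged as disease
#' chromosomes, so its pseudo-marker co-segregates perfectly by
#' construction. Genotypes are emitted unphased; the phased truth is
#' retained for validation.
#'
#' @param panel A \code{marker_panel}; the pool columns must cover its
#'   markers.
#' @param pool Character matrix of pool haplotypes (rows = haplotypes,
#'   columns = marker ids; STR repeat counts as characters are fine).
#' @param disease Logical vector: which pool rows carry the expansion.
#' @param freqs Draw frequencies over pool rows (default uniform).
#' @param n_children Children per couple (>= 1).
#' @param n_generations 2 (couple + children) or 3 (the first child
#'   marries a new founder and has \code{n_children} children).
#' @param founder_haps Optional named list overriding the random pool
#'   draws for founders: \code{list(individual_id = c(i, j))} row indices.
#' @param family_id Family identifier.
#' @param seed Integer seed.
#' @return A list: \code{pedigree}, \code{genotypes} (a
#'   [genotype_table()]), and \code{truth} (per individual: named allele
#'   vectors \code{pat}, \code{mat} over the markers plus the expansion
#'   pseudo-marker).
#' @export
simulate_family <- function(panel, pool, disease = NULL, freqs = NULL,
                            n_children = 2, n_generations = 2,
                            founder_haps = NULL, family_id = "FAM1",
                            seed = 1) {
  pool <- as.matrix(pool)
  if (nrow(pool) == 0) stop("empty haplotype pool")
  markers <- colnames(pool)
  if (is.null(markers) || !all(markers %in% panel$marker_id)) {
    stop("pool columns must be marker ids of the panel")
  }
  if (is.null(disease)) disease <- rep(FALSE, nrow(pool))
  if (is.null(freqs)) freqs <- rep(1 / nrow(pool), nrow(pool))
  stopifnot(length(disease) == nrow(pool), n_children >= 1,
            n_generations %in% c(2, 3))
  withr_seed(seed, {
    draw <- function(id) {
      if (!is.null(founder_haps) && id %in% names(founder_haps)) {
        founder_haps[[id]]
      } else {
        sample.int(nrow(pool), 2, replace = TRUE, prob = freqs)
      }
    }
    truth <- list()
    rows <- list()
    add_ind <- function(id, father, mother, sex, pat_hap, mat_hap) {
      exp_count <- sum(disease[c(attr(pat_hap, "pool_row"),
                                 attr(mat_hap, "pool_row"))])
      rows[[length(rows) + 1]] <<- data.frame(
        individual_id = id, family_id = family_id,
        father_id = father, mother_id = mother, sex = sex,
        affected = if (exp_count >= 1) "affected" else "unaffected",
        expansion_count = as.integer(exp_count), stringsAsFactors = FALSE)
      truth[[id]] <<- list(pat = hap_with_exp(pat_hap),
                           mat = hap_with_exp(mat_hap))
    }
    hap_of <- function(i) {
      h <- pool[i, ]
      attr(h, "pool_row") <- i
      h
    }
    hap_with_exp <- function(h) {
      out <- c(h, if (disease[attr(h, "pool_row")]) "E" else "N")
      names(out) <- c(markers, expansion_marker())
      out
    }
    transmit <- function(id) {
      side <- sample(c("pat", "mat"), 1)
      h <- truth[[id]][[side]]
      gam <- h[markers]
      attr(gam, "pool_row") <- attr_pool_row(h)
      gam
    }
    attr_pool_row <- function(h) {
      # recover the pool row from content + expansion state
      is_e <- h[expansion_marker()] == "E"
      for (i in seq_len(nrow(pool))) {
        if (disease[i] == is_e && all(pool[i, ] == h[markers])) return(i)
      }
      stop("internal: transmitted haplotype not in pool")
    }
    f1 <- draw("F1"); m1 <- draw("M1")
    add_ind("F1", NA, NA, "male", hap_of(f1[1]), hap_of(f1[2]))
    add_ind("M1", NA, NA, "female", hap_of(m1[1]), hap_of(m1[2]))
    kids <- paste0("C", seq_len(n_children))
    for (k in kids) {
      add_ind(k, "F1", "M1", sample(c("male", "female"), 1),
              transmit("F1"), transmit("M1"))
    }
    if (n_generations == 3) {
      s1 <- draw("S1")
      add_ind("S1", NA, NA, "female", hap_of(s1[1]), hap_of(s1[2]))
      for (g in paste0("G", seq_len(n_children))) {
        add_ind(g, kids[1], "S1", sample(c("male", "female"), 1),
                transmit(kids[1]), transmit("S1"))
      }
    }
    ped_df <- do.call(rbind, rows)
    gt <- do.call(rbind, lapply(ped_df$individual_id, function(id) {
      data.frame(individual_id = id, marker_id = markers,
                 a1 = unname(truth[[id]]$pat[markers]),
                 a2 = unname(truth[[id]]$mat[markers]),
                 stringsAsFactors = FALSE)
    }))
    list(pedigree = pedigree(ped_df), genotypes = genotype_table(gt),
         truth = truth)
  })
}

#' Parameter-recovery experiment for founder dating
#'
#' Runs the full ancestor-inference, step-counting and age-estimation
#' pipeline on simulated star genealogies across a grid of true ages and
#' aggregates the recovery accuracy of \eqn{\hat t = \hat\lambda /
#' \varepsilon}.
#'
#' @param t_grid True ages in generations.
#' @param n_chromosomes Chromosomes per replicate.
#' @param n_reps Replicates per grid point (>= 50 for stable medians; the
#'   \code{t = 0} degenerate grid point is allowed and recovers 0
#'   exactly).
#' @param model A [rate_model()].
#' @param mode Distance mode used for \eqn{\hat\lambda}.
#' @param founder Founder haplotype for the simulations.
#' @param n_boot Bootstrap resamples per replicate for the +/- 2 SE
#'   coverage column (0 skips the bootstrap, returning \code{NA}
#'   coverage).
#' @param seed Integer seed for the whole experiment.
#' @return Data frame with one row per grid point: \code{t_true},
#'   \code{median_t_hat}, \code{median_rel_error} (median of
#'   \eqn{|\hat t - t| / t}), \code{mean_signed_rel_error},
#'   \code{coverage_2se}. The pooled median relative error across the
#'   whole grid is attached as attribute \code{pooled_median_rel_error},
#'   and the per-replicate results as attribute \code{replicates}.
#' @export
recovery_experiment <- function(t_grid = c(100, 300, 500),
                                n_chromosomes = 10, n_reps = 200,
                                model = rate_model(),
                                mode = c("locus_count", "stepwise_sum"),
                                founder = c(10, 20, 10, 13, 7, 16, 15),
                                n_boot = 0, seed = 1) {
  mode <- match.arg(mode)
  eps <- per_generation_change(model)
  reps <- withr_seed(seed, {
    do.call(rbind, lapply(t_grid, function(t_true) {
      do.call(rbind, lapply(seq_len(n_reps), function(r) {
        sim <- sim_star_no_recomb(as.integer(founder), n_chromosomes,
                                  t_true, model$mu)
        anc <- modal_haplotype(sim$mat, mode)$haplotype
        lambda <- mean(step_distances_to(sim$mat, anc, mode))
        t_hat <- lambda / eps
        cover <- NA
        if (n_boot > 0 && n_chromosomes >= 2) {
          ages <- vapply(seq_len(n_boot), function(b) {
            idx <- sample.int(n_chromosomes, n_chromosomes, replace = TRUE)
            sub <- sim$mat[idx, , drop = FALSE]
            a <- modal_haplotype(sub, mode)$haplotype
            mean(step_distances_to(sub, a, mode)) / eps *
              model$generation_years
          }, 0)
          se <- stats::sd(ages)
          age_hat <- t_hat * model$generation_years
          age_true <- t_true * model$generation_years
          cover <- abs(age_hat - age_true) <= 2 * se
        }
        data.frame(t_true = t_true, rep = r, lambda_hat = lambda,
                   t_hat = t_hat,
                   rel_error = if (t_true > 0) (t_hat - t_true) / t_true
                               else t_hat,
                   mean_changed = mean(sim$truth$n_changed_generations),
                   coverage = cover)
      }))
    }))
  })
  out <- do.call(rbind, lapply(unique(reps$t_true), function(t_true) {
    sub <- reps[reps$t_true == t_true, ]
    data.frame(t_true = t_true,
               median_t_hat = stats::median(sub$t_hat),
               median_rel_error = stats::median(abs(sub$rel_error)),
               mean_signed_rel_error = mean(sub$rel_error),
               mean_changed_generations = mean(sub$mean_changed),
               expected_changes = eps * t_true,
               coverage_2se = mean(sub$coverage))
  }))
  attr(out, "pooled_median_rel_error") <- stats::median(abs(reps$rel_error))
  attr(out, "replicates") <- reps
  out
}
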