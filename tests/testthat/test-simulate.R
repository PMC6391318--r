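founder7 <- c(10L, 20L, 10L, 13L, 7L, 16L, 15L)

test_that("degenerate simulations return the founder unchanged", {
  s0 <- simulate_founder_sample(founder7, 5, 0, seed = 1)
  expect_true(all(hap_matrix(s0$haplotypes) ==
                    matrix(founder7, 5, 7, byrow = TRUE)))
  expect_true(all(s0$truth$n_changed_generations == 0))

  s_mu0 <- simulate_founder_sample(founder7, 5, 200,
                                   rate_model(mu = 0, c = 0), seed = 1)
  expect_true(all(hap_matrix(s_mu0$haplotypes) ==
                    matrix(founder7, 5, 7, byrow = TRUE)))
})

test_that("simulations are reproducible under a fixed seed", {
  a <- simulate_founder_sample(founder7, 50, 300, seed = 99)
  b <- simulate_founder_sample(founder7, 50, 300, seed = 99)
  expect_identical(hap_matrix(a$haplotypes), hap_matrix(b$haplotypes))
  expect_identical(a$truth$n_mutation_events, b$truth$n_mutation_events)
})

test_that("realized change counts match the epsilon model and locus counts saturate", {
  model <- rate_model()
  eps <- per_generation_change(model)
  sim <- simulate_founder_sample(founder7, 2000, 300, model, seed = 7)
  changed <- sim$truth$n_changed_generations
  se <- sd(changed) / sqrt(length(changed))
  expect_lt(abs(mean(changed) - eps * 300), 3 * se)

  # per-locus change probability 1 - (1-mu)^t, summed over loci, at a
  # horizon where repeat hits are still rare
  sim100 <- simulate_founder_sample(founder7, 2000, 100, model, seed = 8)
  steps <- apply(hap_matrix(sim100$haplotypes), 1, function(h) {
    step_distance(h, founder7, "locus_count")
  })
  expected <- 7 * (1 - (1 - model$mu)^100)
  expect_lt(abs(mean(steps) - expected),
            3 * sd(steps) / sqrt(length(steps)))

  # for mu*t >> 0.1 the observable locus-count distance undercounts the
  # realized changes: dating from it degrades for old founders
  old <- simulate_founder_sample(founder7, 500, 3000, model, seed = 9)
  old_steps <- apply(hap_matrix(old$haplotypes), 1, function(h) {
    step_distance(h, founder7, "locus_count")
  })
  expect_lt(mean(old_steps), 0.9 * eps * 3000)
  expect_lt(mean(old_steps), mean(old$truth$n_changed_generations))
})

test_that("recombination replaces the downstream segment from the pool", {
  pool <- matrix(30L, 2, 7)
  model <- rate_model(mu = 0, c = 0.1)
  expect_error(simulate_founder_sample(founder7, 5, 10, model, seed = 1),
               "background")
  sim <- simulate_founder_sample(founder7, 100, 30, model,
                                 background_pool = pool, seed = 4)
  mat <- hap_matrix(sim$haplotypes)
  expect_true(any(sim$truth$n_recombination_events > 0))
  # the first locus is upstream of every breakpoint
  expect_true(all(mat[, 1] == founder7[1]))
  # every changed cell carries pool material (mu = 0)
  changed <- mat != matrix(founder7, 100, 7, byrow = TRUE)
  expect_true(all(mat[changed] == 30L))
  # recombined chromosomes are founder-prefix + donor-suffix
  rec <- which(sim$truth$n_recombination_events > 0)
  for (i in rec[seq_len(min(10, length(rec)))]) {
    is_donor <- mat[i, ] == 30L & founder7 != 30L
    if (any(is_donor)) {
      expect_true(all(diff(is_donor) >= 0))
    }
  }
})

test_that("family simulation respects the pool and co-segregates the expansion", {
  panel <- make_panel(snp_manifest(c("rs1", "rs2"), c("A,G", "T,C")))
  mono_pool <- matrix(c("A", "T"), 1, 2,
                      dimnames = list(NULL, c("rs1", "rs2")))
  sim <- simulate_family(panel, mono_pool, n_children = 2, seed = 3)
  gtm <- sim$genotypes
  expect_true(all(gtm$a1 == gtm$a2))

  pool <- rbind(c("A", "T"), c("G", "C"))
  colnames(pool) <- c("rs1", "rs2")
  sim2 <- simulate_family(panel, pool, disease = c(TRUE, FALSE),
                          n_children = 4, n_generations = 3,
                          founder_haps = list(F1 = c(1L, 2L)), seed = 5)
  ped <- sim2$pedigree
  for (id in ped$individual_id) {
    truth <- sim2$truth[[id]]
    n_e <- sum(c(truth$pat[expansion_marker()],
                 truth$mat[expansion_marker()]) == "E")
    expect_equal(ped$expansion_count[ped$individual_id == id], n_e)
  }
  expect_error(simulate_family(panel, pool[0, , drop = FALSE], seed = 1),
               "empty")

  sim3a <- simulate_family(panel, pool, n_children = 5, n_generations = 3,
                           seed = 12)
  sim3b <- simulate_family(panel, pool, n_children = 5, n_generations = 3,
                           seed = 12)
  expect_identical(sim3a$pedigree, sim3b$pedigree)
  expect_identical(sim3a$genotypes, sim3b$genotypes)
})

test_that("recovery is exact at t = 0 and scales inversely with mu", {
  res0 <- recovery_experiment(t_grid = 0, n_chromosomes = 10, n_reps = 20,
                              seed = 2)
  expect_equal(res0$median_t_hat, 0)
  expect_equal(res0$median_rel_error, 0)

  # dating the same diversity with a doubled mutation rate halves t-hat
  sim <- simulate_founder_sample(founder7, 50, 300, seed = 3)
  anc <- modal_haplotype(sim$haplotypes)$haplotype
  lam <- mean_steps(sim$haplotypes, anc)
  t_base <- estimate_age(lam, rate_model())$t_generations
  t_dbl <- estimate_age(lam, rate_model(mu = 2 * 5.6e-4))$t_generations
  ratio <- t_base / t_dbl
  expect_gt(ratio, 1.9)
  expect_lt(ratio, 2.1)
})

test_that("bootstrap coverage columns appear when requested", {
  res <- recovery_experiment(t_grid = 200, n_chromosomes = 10, n_reps = 10,
                             n_boot = 100, seed = 4)
  expect_true(res$coverage_2se >= 0 && res$coverage_2se <= 1)
  expect_false(is.na(res$coverage_2se))
})
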