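two_snp_panel <- function() {
  make_panel(snp_manifest(c("rs1", "rs2"), c("A,G", "T,C")))
}

test_that("a homozygous parent forces the child's phase with posterior 1", {
  panel <- two_snp_panel()
  ped <- trio_pedigree(exp_father = 0, exp_mother = 1, exp_child = 1)
  gt <- gt_from(list(F = c(rs1 = "A/A", rs2 = "T/T"),
                     M = c(rs1 = "A/G", rs2 = "T/C"),
                     C = c(rs1 = "A/G", rs2 = "T/C")))
  ph <- phase_by_segregation(ped, gt, panel)
  child <- ph$pairs$C
  expect_true(all(child$resolved[c("rs1", "rs2")]))
  expect_equal(unname(child$pat[c("rs1", "rs2")]), c("A", "T"))
  expect_equal(unname(child$mat[c("rs1", "rs2")]), c("G", "C"))
  expect_equal(unname(child$posterior["rs1"]), 1)
  # the expansion pseudo-marker phases like any marker: only the mother
  # carries it, so the child's expanded chromosome is maternal
  expect_equal(child$disease_side, "b")
})

test_that("uninformative double-heterozygous configurations stay ambiguous", {
  panel <- two_snp_panel()
  ped <- trio_pedigree()
  gt <- gt_from(list(F = c(rs1 = "A/G", rs2 = "T/C"),
                     M = c(rs1 = "A/G", rs2 = "T/C"),
                     C = c(rs1 = "A/G", rs2 = "T/C")))
  ph <- phase_by_segregation(ped, gt, panel)
  expect_false(any(ph$pairs$C$resolved[c("rs1", "rs2")]))
  expect_true(all(is.na(ph$pairs$C$pat[c("rs1", "rs2")])))
})

test_that("Mendelian inconsistencies abort phasing with a located report", {
  panel <- two_snp_panel()
  ped <- trio_pedigree()
  gt <- gt_from(list(F = c(rs1 = "A/A"), M = c(rs1 = "A/A"),
                     C = c(rs1 = "G/G")))
  expect_error(phase_by_segregation(ped, gt, panel),
               "Mendelian inconsistency.*C@rs1")
})

test_that("the homozygous patient carries the expansion on both sides", {
  panel <- make_panel(snp_manifest("rs1", "A,G"))
  ped <- pedigree(data.frame(
    individual_id = c("F", "M", "P", "S"), family_id = "FAM2",
    father_id = c(NA, NA, "F", "F"), mother_id = c(NA, NA, "M", "M"),
    sex = c("male", "female", "male", "female"),
    affected = c("affected", "affected", "affected", "unaffected"),
    expansion_count = c(1L, 1L, 2L, 0L), stringsAsFactors = FALSE))
  gt <- gt_from(list(F = c(rs1 = "A/A"), M = c(rs1 = "G/G"),
                     P = c(rs1 = "A/G"), S = c(rs1 = "A/G")))
  ph <- phase_by_segregation(ped, gt, panel)
  expect_equal(ph$pairs$P$disease_side, "both")
  # two distinct disease haplotypes enter through the two carrier parents
  dis <- disease_haplotype_for_family(ph, ped, panel)
  expect_equal(nrow(dis$snp), 2)
  expect_setequal(hap_matrix(dis$snp)[, "rs1"], c("A", "G"))
})

test_that("unanimous carriers yield one disease haplotype; disagreement errors", {
  panel <- make_panel(snp_manifest("rs1", "A,G"))
  ped <- pedigree(data.frame(
    individual_id = c("F", "M", "C1", "C2"), family_id = "FAM",
    father_id = c(NA, NA, "F", "F"), mother_id = c(NA, NA, "M", "M"),
    sex = c("male", "female", "male", "female"),
    affected = c("affected", "unaffected", "affected", "affected"),
    expansion_count = c(1L, 0L, 1L, 1L), stringsAsFactors = FALSE))
  gt <- gt_from(list(F = c(rs1 = "A/G"), M = c(rs1 = "G/G"),
                     C1 = c(rs1 = "A/G"), C2 = c(rs1 = "A/G")))
  ph <- phase_by_segregation(ped, gt, panel)
  dis <- disease_haplotype_for_family(ph, ped, panel)
  expect_equal(nrow(dis$snp), 1)
  expect_equal(unname(hap_matrix(dis$snp)[1, "rs1"]), "A")

  # same family but the two carrier children received different alleles
  # with the expansion: more haplotypes than founder expansions
  gt2 <- gt_from(list(F = c(rs1 = "A/G"), M = c(rs1 = "A/A"),
                      C1 = c(rs1 = "A/A"), C2 = c(rs1 = "A/G")))
  ph2 <- phase_by_segregation(ped, gt2, panel)
  expect_error(disease_haplotype_for_family(ph2, ped, panel),
               "disagree")
})

test_that("EM posterior is 1 for a single-site heterozygote and plain counting for homozygotes", {
  panel <- two_snp_panel()
  gt <- gt_from(list(i1 = c(rs1 = "A/G", rs2 = "T/T")))
  res <- em_haplotype_frequencies(gt, panel)
  expect_equal(nrow(res$pairs), 1)
  expect_equal(res$pairs$posterior, 1)
  expect_true(res$pairs$retained)

  gt2 <- gt_from(list(i1 = c(rs1 = "A/A", rs2 = "T/T"),
                      i2 = c(rs1 = "A/A", rs2 = "T/T"),
                      i3 = c(rs1 = "G/G", rs2 = "C/C")))
  res2 <- em_haplotype_frequencies(gt2, panel)
  expect_equal(unname(res2$frequencies[c("A-T", "G-C")]), c(2 / 3, 1 / 3))
})

test_that("EM marginalises missing genotypes over the marker domain", {
  panel <- two_snp_panel()
  gt <- genotype_table(data.frame(
    individual_id = c("i1", "i1", "i2", "i2"),
    marker_id = c("rs1", "rs2", "rs1", "rs2"),
    a1 = c(NA, "T", "A", "T"), a2 = c(NA, "T", "A", "T"),
    stringsAsFactors = FALSE))
  res <- em_haplotype_frequencies(gt, panel)
  # i1's pairs span the rs1 domain {A,G} with rs2 fixed at T
  i1 <- res$pairs[res$pairs$individual_id == "i1", ]
  expect_setequal(unique(c(i1$hap_a, i1$hap_b)), c("A-T", "G-T"))
  expect_equal(sum(i1$posterior), 1, tolerance = 1e-8)
  # the observed A-T haplotype dominates after sharing i1's mass
  expect_gt(res$frequencies["A-T"], res$frequencies["G-T"])
})

test_that("EM reaches the enumerable two-SNP fixed point and retains the resolved pair", {
  panel <- two_snp_panel()
  geno <- c(rep(list(c(rs1 = "A/A", rs2 = "T/T")), 4),
            rep(list(c(rs1 = "A/G", rs2 = "T/C")), 2))
  names(geno) <- paste0("i", 1:6)
  res <- em_haplotype_frequencies(gt_from(geno), panel)

  # independent oracle: one-dimensional EM recursion on the posterior w of
  # the A-T/G-C pairing for the two double heterozygotes
  w <- 0.5
  for (it in 1:500) {
    f_at <- (8 + 2 * w) / 12
    f_gc <- 2 * w / 12
    f_ac <- f_gt <- 2 * (1 - w) / 12
    w_new <- f_at * f_gc / (f_at * f_gc + f_ac * f_gt)
    if (abs(w_new - w) < 1e-12) break
    w <- w_new
  }
  expect_equal(unname(res$frequencies["A-T"]), (8 + 2 * w) / 12,
               tolerance = 1e-6)
  expect_equal(unname(res$frequencies["G-C"]), 2 * w / 12, tolerance = 1e-6)
  het <- res$pairs[res$pairs$individual_id == "i5", ]
  best <- het[which.max(het$posterior), ]
  expect_setequal(c(best$hap_a, best$hap_b), c("A-T", "G-C"))
  expect_gt(best$posterior, 0.6)
  expect_true(best$retained)
})

test_that("the EM log-likelihood is non-decreasing", {
  panel <- make_panel(snp_manifest(c("rs1", "rs2", "rs3"),
                                   c("A,G", "T,C", "A,C")))
  set.seed(7)
  for (rep in 1:5) {
    geno <- lapply(1:8, function(i) {
      g <- vapply(list(c("A", "G"), c("T", "C"), c("A", "C")), function(d) {
        paste(sample(d, 2, replace = TRUE), collapse = "/")
      }, "")
      names(g) <- c("rs1", "rs2", "rs3")
      g
    })
    names(geno) <- paste0("i", 1:8)
    res <- em_haplotype_frequencies(gt_from(geno), panel)
    expect_true(all(diff(res$loglik) >= -1e-8))
    expect_equal(sum(res$frequencies), 1, tolerance = 1e-8)
    by_ind <- tapply(res$pairs$posterior, res$pairs$individual_id, sum)
    expect_true(all(abs(by_ind - 1) < 1e-8))
  }
})

test_that("segregation phasing recovers simulated truth at every resolved marker", {
  panel <- make_panel(snp_manifest(paste0("rs", 1:5),
                                   rep(c("A,G", "T,C"), length.out = 5)))
  pool <- rbind(c("A", "T", "A", "T", "A"),
                c("G", "C", "G", "C", "G"),
                c("A", "C", "A", "C", "A"),
                c("G", "T", "G", "T", "G"))
  colnames(pool) <- paste0("rs", 1:5)
  disease <- c(TRUE, FALSE, FALSE, FALSE)
  for (seed in 1:15) {
    sim <- simulate_family(panel, pool, disease = disease, n_children = 3,
                           n_generations = sample(2:3, 1), seed = seed)
    ph <- phase_by_segregation(sim$pedigree, sim$genotypes, panel)
    for (id in sim$pedigree$individual_id) {
      p <- ph$pairs[[id]]
      truth <- sim$truth[[id]]
      is_founder <- id %in% founders(sim$pedigree)
      for (m in names(p$resolved)[p$resolved]) {
        if (!is_founder) {
          expect_equal(unname(p$pat[m]), unname(truth$pat[m]))
          expect_equal(unname(p$mat[m]), unname(truth$mat[m]))
        } else {
          # founder sides are disease/normal, not parental origin: the
          # inferred pair must equal the true pair up to a swap
          expect_setequal(unname(c(p$pat[m], p$mat[m])),
                          unname(c(truth$pat[m], truth$mat[m])))
        }
      }
      # markers forced by the trio configuration must actually be resolved
      if (!is_founder) {
        ped <- sim$pedigree
        f <- ped$father_id[ped$individual_id == id]
        mo <- ped$mother_id[ped$individual_id == id]
        for (m in paste0("rs", 1:5)) {
          child_g <- sort(c(truth$pat[m], truth$mat[m]))
          gf <- sort(unname(c(sim$truth[[f]]$pat[m], sim$truth[[f]]$mat[m])))
          gm <- sort(unname(c(sim$truth[[mo]]$pat[m],
                              sim$truth[[mo]]$mat[m])))
          forced <- child_g[1] == child_g[2] ||
            xor((child_g[1] %in% gf) && (child_g[2] %in% gm),
                (child_g[2] %in% gf) && (child_g[1] %in% gm))
          if (forced) expect_true(unname(p$resolved[m]))
        }
      }
    }
  }
})

test_that("the disease haplotype seeded in a founder is recovered by segregation", {
  panel <- make_panel(snp_manifest(paste0("rs", 1:4),
                                   rep("A,G", 4)))
  pool <- rbind(c("A", "A", "A", "A"),
                c("G", "G", "G", "G"),
                c("A", "G", "A", "G"))
  colnames(pool) <- paste0("rs", 1:4)
  disease <- c(TRUE, FALSE, FALSE)
  sim <- simulate_family(panel, pool, disease = disease, n_children = 4,
                         founder_haps = list(F1 = c(1L, 2L), M1 = c(2L, 3L)),
                         seed = 11)
  ph <- phase_by_segregation(sim$pedigree, sim$genotypes, panel)
  dis <- disease_haplotype_for_family(ph, sim$pedigree, panel)
  got <- hap_matrix(dis$snp)[1, ]
  expect_equal(unname(got[!is.na(got)]),
               unname(pool[1, !is.na(got)]))
})
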