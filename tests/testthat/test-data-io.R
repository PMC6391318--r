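test_that("the default panel has 27 ordered markers with the anchor placed", {
  panel <- default_marker_panel()
  expect_equal(nrow(panel), 27)
  expect_equal(sum(panel$kind == "SNP"), 20)
  expect_equal(sum(panel$kind == "STR"), 7)
  expect_false(is.unsorted(panel$offset_kb))
  ai <- attr(panel, "anchor_index")
  expect_equal(panel$rs_id[ai], "rs10467856")
  expect_equal(panel$rs_id[ai + 1], "rs12895357")
})

test_that("manifest loading validates structure and rejects bad input", {
  single <- make_panel(snp_manifest("rs1", "A,G"))
  expect_equal(nrow(single), 1)
  expect_error(make_panel(snp_manifest(c("rs12895357", "rs12895357"),
                                       c("C,G", "C,G"))),
               "duplicate marker_id")
  bad_kind <- snp_manifest("rs1", "A,G")
  bad_kind$kind <- "INDEL"
  expect_error(make_panel(bad_kind), "unknown marker kind")
  bad_off <- snp_manifest("rs1", "A,G")
  bad_off$offset_kb <- "upstream"
  expect_error(make_panel(bad_off), "unparseable offset")
  bad_dom <- snp_manifest("rs1", "A,N")
  expect_error(make_panel(bad_dom), "domain")
})

test_that("pedigree loading handles trios, the homozygous-patient family, and cycles", {
  ped_file <- tempfile()
  writeLines(c("FAM1 F 0 0 1 1 0",
               "FAM1 M 0 0 2 1 0",
               "FAM1 C F M 1 2 1"), ped_file)
  peds <- load_pedigree(ped_file)
  expect_length(peds, 1)
  expect_equal(nrow(peds$FAM1), 3)
  expect_equal(peds$FAM1$expansion_carrier,
               c("no", "no", "yes"))

  # both parents carriers, homozygous patient, unaffected sister
  hom_file <- tempfile()
  writeLines(c("FAM2 F 0 0 1 2 1",
               "FAM2 M 0 0 2 2 1",
               "FAM2 P F M 1 2 2",
               "FAM2 S F M 2 1 0"), hom_file)
  peds <- load_pedigree(hom_file, study_mode = TRUE)
  expect_equal(nrow(peds$FAM2), 4)
  expect_equal(peds$FAM2$expansion_count[peds$FAM2$individual_id == "P"], 2L)

  self_file <- tempfile()
  writeLines(c("FAM3 A A 0 1 1 0"), self_file)
  expect_error(load_pedigree(self_file), "cyclic")

  undef_file <- tempfile()
  writeLines(c("FAM4 A B 0 1 1 0"), undef_file)
  expect_error(load_pedigree(undef_file), "undefined")
})

test_that("cyclic parentage is rejected for any cycle length", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(3:7, 1)
    ids <- paste0("I", seq_len(n))
    # a parent cycle through all n individuals
    df <- data.frame(individual_id = ids, family_id = "FAM",
                     father_id = c(ids[-1], ids[1]),
                     mother_id = NA_character_,
                     sex = "unknown", affected = "unknown",
                     expansion_count = NA_integer_,
                     stringsAsFactors = FALSE)
    expect_error(pedigree(df), "cyclic")
    # breaking the cycle makes it valid
    df$father_id[n] <- NA
    expect_s3_class(pedigree(df), "pedigree")
  }
})

test_that("genotype loading parses pairs, keeps missing explicit, checks domains", {
  panel <- make_panel(data.frame(
    marker_id = c("A/G.485", "AC_21"), rs_id = c("rs56268847", "."),
    kind = c("SNP", "STR"), offset_kb = c(-0.4, -21),
    domain = c("A,G", "1-99"), stringsAsFactors = FALSE))
  gfile <- tempfile()
  writeLines(c("individual_id\tA/G.485\tAC_21",
               "ind1\tA/G\t12/13",
               "ind2\t.\t12/12"), gfile)
  gt <- load_genotypes(gfile, panel)
  expect_setequal(genotype_of(gt, "ind1", "A/G.485"), c("A", "G"))
  expect_null(genotype_of(gt, "ind2", "A/G.485"))
  expect_equal(genotype_of(gt, "ind2", "AC_21"), c("12", "12"))

  bad <- tempfile()
  writeLines(c("individual_id\tAC_21", "ind1\t12/Z"), bad)
  expect_error(load_genotypes(bad, panel), "outside the domain")
  unk <- tempfile()
  writeLines(c("individual_id\trs999", "ind1\tA/A"), unk)
  expect_error(load_genotypes(unk, panel), "unknown marker")
})

test_that("packaged fixtures match the printed tables structurally", {
  t1 <- load_fixture("table1")
  expect_equal(dim(t1$alleles), c(20, 13))
  expect_equal(sum(t1$counts), 51)
  expect_equal(unname(t1$counts[c("A", "B", "D", "G")]), c(10L, 12L, 8L, 11L))

  t2 <- load_fixture("table2")
  mjd_row <- t2[t2$rs_id == "rs56268847" & t2$group == "MJD", ]
  expect_equal(c(mjd_row$n_hom_ref, mjd_row$n_het, mjd_row$n_hom_alt),
               c(46, 60, 3))

  t3 <- load_fixture("table3")
  expect_equal(nrow(t3), 22)

  t4 <- load_fixture("table4")
  sizes <- table(t4$haplotypes$lineage)
  expect_equal(as.integer(sizes[c("A", "B", "D", "G")]),
               c(10L, 12L, 8L, 11L))
  a <- lineage_str_haplotypes("A", t4)
  expect_equal(nrow(a), 10)
  expect_equal(fam_row(a, "Fam 10"), c(10L, 20L, 10L, 13L, 7L, 16L, 15L))
  # Fam 1 appears verbatim under both A and D with distinct row ids
  dup <- t4$haplotypes[t4$haplotypes$family == "Fam 1", ]
  expect_setequal(dup$lineage, c("A", "D"))
  expect_equal(length(unique(dup$row_id)), 2)
  # the annotated (AAAC)n entry keeps 7 as primary value, 5 as annotation
  f33 <- t4$haplotypes[t4$haplotypes$family == "Fam 33", ]
  expect_equal(f33$AAAC, 7L)
  expect_equal(f33$AAAC_annot, 5)
})

test_that("haplotype writer round-trips and rejects empty or mixed input", {
  t4 <- load_fixture("table4")
  d <- lineage_str_haplotypes("D", t4)
  path <- tempfile(fileext = ".tsv")
  write_haplotypes(d, path)
  back <- read_haplotypes(path)
  expect_equal(nrow(back), 8)
  expect_equal(unname(hap_matrix(back)), unname(hap_matrix(d)))
  expect_s3_class(back, "str_haplotypes")

  snp <- snp_haplotypes(matrix(c("A", "G", "A", "A"), 2,
                               dimnames = list(NULL, c("rs1", "rs2"))),
                        family = c("f1", "f2"))
  path2 <- tempfile(fileext = ".tsv")
  write_haplotypes(snp, path2)
  back2 <- read_haplotypes(path2)
  expect_equal(unname(hap_matrix(back2)), unname(hap_matrix(snp)))

  expect_error(write_haplotypes(list(), tempfile()), "empty")
  expect_error(write_haplotypes(snp[0, ], tempfile()), "empty")
  expect_error(write_haplotypes(list(snp, d), tempfile()), "mixed")
})
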