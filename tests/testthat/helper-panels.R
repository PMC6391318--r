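# in-memory manifest -> marker_panel, exercising the reader
make_panel <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  load_marker_manifest(path)
}

snp_manifest <- function(ids, domains, offsets = seq_along(ids)) {
  data.frame(marker_id = ids, rs_id = ids, kind = "SNP",
             offset_kb = offsets, domain = domains,
             stringsAsFactors = FALSE)
}

# long genotype data frame from a named list: ind -> c(marker = "a/b")
gt_from <- function(geno) {
  rows <- lapply(names(geno), function(id) {
    g <- geno[[id]]
    parts <- strsplit(unname(g), "/", fixed = TRUE)
    data.frame(individual_id = id, marker_id = names(g),
               a1 = vapply(parts, `[`, "", 1),
               a2 = vapply(parts, `[`, "", 2),
               stringsAsFactors = FALSE)
  })
  genotype_table(do.call(rbind, rows))
}

trio_pedigree <- function(exp_father = 0, exp_mother = 1, exp_child = 1) {
  pedigree(data.frame(
    individual_id = c("F", "M", "C"),
    family_id = "FAM",
    father_id = c(NA, NA, "F"),
    mother_id = c(NA, NA, "M"),
    sex = c("male", "female", "unknown"),
    affected = ifelse(c(exp_father, exp_mother, exp_child) >= 1,
                      "affected", "unaffected"),
    expansion_count = c(exp_father, exp_mother, exp_child),
    stringsAsFactors = FALSE))
}

random_str_mat <- function(n, L = 7, lo = 5, hi = 25) {
  matrix(sample(lo:hi, n * L, replace = TRUE), n, L,
         dimnames = list(NULL, str_locus_names()[seq_len(L)]))
}

fam_row <- function(haps, fam) {
  unname(hap_matrix(haps)[haps$family == fam, ])
}
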