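# In-code fixture builders shared across the suite.

mk_var <- function(chrom = "chr1", pos = 100L, ref = "A", alt = "G",
                   gene = "GENE1", zygosity = "HET", clin_class = "VUS",
                   maf = NA_real_, vaf = 0.5, depth = 100L,
                   cip_has_plp = FALSE, score1 = "tolerated") {
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt, gene = gene,
    consequence = "missense_variant", zygosity = zygosity, vaf = vaf,
    depth = as.integer(depth), clin_class = clin_class,
    cip_has_plp = cip_has_plp, hgvs = NA_character_, flags = "",
    maf_popA = maf, score_pred1 = score1
  )
}

mk_vars <- function(...) dplyr::bind_rows(...)

mk_panel <- function(genes, modes, flags = "", id = "TESTPANEL") {
  raredx:::new_virtual_panel(
    tibble::tibble(
      gene = toupper(genes),
      modes = rep_len(modes, length(genes)),
      exception_flags = rep_len(flags, length(genes))
    ),
    id = id
  )
}

# Attach panel columns the way apply_panel() would.
with_panel_cols <- function(variants, modes = "AR", exceptions = "") {
  variants$panel_id <- "TESTPANEL"
  variants$panel_modes <- rep_len(modes, nrow(variants))
  variants$panel_exceptions <- rep_len(exceptions, nrow(variants))
  variants
}

write_test_vcf <- function(path, records, sample = "S1") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample)
  )
  writeLines(c(header, records), path)
  path
}

write_test_annotations <- function(path, df) {
  readr::write_tsv(df, path, progress = FALSE)
  path
}

write_panel_tsv <- function(path, rows) {
  readr::write_tsv(rows, path, progress = FALSE)
  path
}

panel_row <- function(panel_id = "P1", gene, modes = "AR", flags = "",
                      panel_name = "Panel one", category = "CAT1") {
  tibble::tibble(panel_id = panel_id, panel_name = panel_name,
                 category = category, subcategory = NA_character_,
                 gene = gene, modes = modes, exception_flags = flags)
}

trio_pedigree <- function(proband = "CH", father = "FA", mother = "MO",
                          genotypes = NULL, proband_sex = "FEMALE") {
  ped <- new_pedigree(tibble::tibble(
    sample_id = c(proband, father, mother),
    father_id = c(father, NA, NA),
    mother_id = c(mother, NA, NA),
    sex = c(proband_sex, "MALE", "FEMALE"),
    affected = c(TRUE, FALSE, FALSE)
  ))
  if (!is.null(genotypes)) ped <- set_pedigree_genotypes(ped, genotypes)
  ped
}
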