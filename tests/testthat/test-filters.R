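test_that("frequency filter applies the most permissive mode ceiling", {
  cfg <- filter_config()
  # AR-only gene, maf 0.05 over the 0.01 ceiling: removed
  v <- with_panel_cols(mk_var(maf = 0.05), modes = "AR")
  expect_equal(nrow(filter_frequency(v, cfg)), 0L)
  # same maf passes under nothing; 0.005 passes AR but not AD
  v2 <- with_panel_cols(mk_var(maf = 0.005), modes = "AD;AR")
  expect_equal(nrow(filter_frequency(v2, cfg)), 1L)
  v3 <- with_panel_cols(mk_var(maf = 0.005), modes = "AD")
  expect_equal(nrow(filter_frequency(v3, cfg)), 0L)
})

test_that("missing frequency data keeps the variant with a flag", {
  v <- with_panel_cols(mk_var(maf = NA_real_), modes = "AR")
  out <- filter_frequency(v)
  expect_equal(nrow(out), 1L)
  expect_true(grepl("NO_FREQUENCY_DATA", out$flags))
})

test_that("exception-flagged genes bypass the frequency ceiling", {
  v <- with_panel_cols(mk_var(maf = 0.05), modes = "AR",
                       exceptions = "KNOWN_PATHOGENIC")
  expect_equal(nrow(filter_frequency(v)), 1L)
})

test_that("the worst frequency across sources drives the decision", {
  v <- with_panel_cols(mk_var(maf = 1e-5), modes = "AR")
  v$maf_popB <- 0.3   # common in a second source
  expect_equal(nrow(filter_frequency(v)), 0L)
})

test_that("classification filter drops B/LB and applies the CIP dagger rule", {
  vars <- with_panel_cols(mk_vars(
    mk_var(pos = 1, clin_class = "P"),
    mk_var(pos = 2, clin_class = "LB"),
    mk_var(pos = 3, clin_class = "VUS"),
    mk_var(pos = 4, clin_class = "CIP", cip_has_plp = FALSE),
    mk_var(pos = 5, clin_class = "CIP", cip_has_plp = TRUE),
    mk_var(pos = 6, clin_class = "B"),
    mk_var(pos = 7, clin_class = "NONE")
  ))
  out <- filter_classification(vars)
  expect_equal(out$pos, c(1L, 3L, 5L, 7L))
  expect_equal(nrow(filter_classification(vars[0, ])), 0L)
})

test_that("zygosity filter implements the per-mode rule table", {
  # single VUS HET in an AR-only gene: removed
  v <- with_panel_cols(mk_var(zygosity = "HET", clin_class = "VUS"), modes = "AR")
  expect_equal(nrow(check_zygosity_consistency(v)), 0L)
  # two HETs in the same AR gene: both kept as compound-het material
  v2 <- with_panel_cols(mk_vars(
    mk_var(pos = 1, zygosity = "HET", clin_class = "VUS"),
    mk_var(pos = 2, zygosity = "HET", clin_class = "VUS")
  ), modes = "AR")
  expect_equal(nrow(check_zygosity_consistency(v2)), 2L)
  # a lone LP HET in an AR gene survives, flagged monoallelic
  v3 <- with_panel_cols(mk_var(zygosity = "HET", clin_class = "LP"), modes = "AR")
  out3 <- check_zygosity_consistency(v3)
  expect_equal(nrow(out3), 1L)
  expect_true(grepl("MONOALLELIC", out3$flags))
  # AD genes accept HET and HOM
  v4 <- with_panel_cols(mk_vars(
    mk_var(pos = 1, zygosity = "HET"), mk_var(pos = 2, zygosity = "HOM")
  ), modes = "AD")
  expect_equal(nrow(check_zygosity_consistency(v4)), 2L)
})

test_that("X-linked zygosity rules respect sample sex", {
  # XLR male: hemizygous passes, lone het VUS does not
  hem <- with_panel_cols(mk_var(chrom = "chrX", zygosity = "HEM"), modes = "XLR")
  expect_equal(nrow(check_zygosity_consistency(hem, sex = "MALE")), 1L)
  het <- with_panel_cols(mk_var(chrom = "chrX", zygosity = "HET", clin_class = "VUS"),
                         modes = "XLR")
  expect_equal(nrow(check_zygosity_consistency(het, sex = "MALE")), 0L)
  # XLR female: HOM passes; lone P HET kept (carrier/partial)
  hom <- with_panel_cols(mk_var(chrom = "chrX", zygosity = "HOM"), modes = "XLR")
  expect_equal(nrow(check_zygosity_consistency(hom, sex = "FEMALE")), 1L)
  hetp <- with_panel_cols(mk_var(chrom = "chrX", zygosity = "HET", clin_class = "P"),
                          modes = "XLR")
  outp <- check_zygosity_consistency(hetp, sex = "FEMALE")
  expect_equal(nrow(outp), 1L)
  expect_true(grepl("MONOALLELIC", outp$flags))
  # XLD: any non-reference genotype
  xld <- with_panel_cols(mk_var(chrom = "chrX", zygosity = "HET", clin_class = "VUS"),
                         modes = "XLD")
  expect_equal(nrow(check_zygosity_consistency(xld, sex = "FEMALE")), 1L)
})

test_that("hemizygous calls in a female sample are flagged, not silently dropped", {
  v <- with_panel_cols(mk_var(chrom = "chrX", zygosity = "HEM", clin_class = "P"),
                       modes = "XLD")
  expect_warning(out <- check_zygosity_consistency(v, sex = "FEMALE"), "hemizygous")
  expect_true(grepl("SEX_GENOTYPE_CONFLICT", out$flags))
})

test_that("exception-flagged genes bypass zygosity removal", {
  v <- with_panel_cols(mk_var(zygosity = "HET", clin_class = "VUS"), modes = "AR",
                       exceptions = "HYPOMORPHIC")
  expect_equal(nrow(check_zygosity_consistency(v)), 1L)
})

test_that("pure filters commute: cascade order equals intersection of keep-sets", {
  cfg <- sim_config(seed = 77, n_background = 300)
  sim <- simulate_variant_table(cfg)
  panel <- mk_panel(sim_gene_universe(cfg)$gene[1:80], "AD;AR")
  v <- apply_panel(sim$variants, panel)
  fc <- filter_config()
  a <- filter_classification(filter_frequency(v, fc), fc)
  b <- filter_frequency(filter_classification(v, fc), fc)
  expect_equal(sort(variant_key(a)), sort(variant_key(b)))
  # and both equal the intersection of individual keep-sets
  keep_f <- variant_key(filter_frequency(v, fc))
  keep_c <- variant_key(filter_classification(v, fc))
  expect_setequal(variant_key(a), intersect(keep_f, keep_c))
})

test_that("out-of-band VAF is flagged but never dropped", {
  v <- with_panel_cols(mk_vars(
    mk_var(pos = 1, zygosity = "HET", vaf = 0.12, clin_class = "P"),
    mk_var(pos = 2, zygosity = "HOM", vaf = 0.55, clin_class = "P"),
    mk_var(pos = 3, zygosity = "HET", vaf = 0.5, clin_class = "P")
  ), modes = "AD")
  out <- raredx:::flag_vaf_outliers(v)
  expect_equal(nrow(out), 3L)
  expect_equal(grepl("VAF_OUTLIER", out$flags), c(TRUE, TRUE, FALSE))
})
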