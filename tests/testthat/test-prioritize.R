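test_that("ranking puts clinical class before frequency before position", {
  vars <- with_panel_cols(mk_vars(
    mk_var(pos = 10, clin_class = "VUS", maf = 1e-5),
    mk_var(pos = 20, clin_class = "P", maf = 1e-3)
  ), modes = "AD")
  ranked <- rank_candidates(vars)
  expect_equal(ranked$clin_class, c("P", "VUS"))
  expect_equal(ranked$rank, 1:2)

  # two VUS differing only in frequency: rarer first
  vars2 <- with_panel_cols(mk_vars(
    mk_var(pos = 10, clin_class = "VUS", maf = 1e-3),
    mk_var(pos = 20, clin_class = "VUS", maf = 1e-6)
  ), modes = "AD")
  expect_equal(rank_candidates(vars2)$pos, c(20L, 10L))

  # full tie: genomic position breaks it, deterministically
  vars3 <- with_panel_cols(mk_vars(
    mk_var(pos = 300, clin_class = "VUS", maf = 1e-4),
    mk_var(pos = 100, clin_class = "VUS", maf = 1e-4)
  ), modes = "AD")
  r1 <- rank_candidates(vars3); r2 <- rank_candidates(vars3)
  expect_equal(r1$pos, c(100L, 300L))
  expect_identical(r1, r2)
})

test_that("a spiked homozygous P variant in an AR on-panel gene ranks first", {
  # background free of P/LP so the planted causal genotype must top the list
  cfg <- sim_config(seed = 21, n_background = 300,
                    class_mix = c(P = 0, LP = 0, VUS = 0.35, CIP = 0.05,
                                  LB = 0.2, B = 0.3, NONE = 0.1))
  lib <- sim_panel_library(cfg)
  panel <- get_panel(lib, "PNL01")
  ar_gene <- panel$gene[panel$modes == "AR"][1]
  sim <- simulate_variant_table(cfg, spikes = spike_spec(ar_gene, "HOM", "P"))
  res <- prioritize_case(sample_case("S1", sex = "FEMALE", panels = "PNL01"),
                         sim$variants, lib)
  expect_gte(nrow(res$candidates), 1L)
  expect_equal(variant_key(res$candidates[res$candidates$rank == 1, ]),
               sim$truth$key)
})

test_that("funnel counts are non-increasing and cover all six stages", {
  cfg <- sim_config(seed = 55, n_background = 250)
  lib <- sim_panel_library(cfg)
  res <- prioritize_case(sample_case("S1", panels = c("PNL01", "PNL03")),
                         simulate_variant_table(cfg)$variants, lib)
  expect_equal(res$funnel$stage,
               c("raw", "panel", "frequency", "classification", "zygosity", "final"))
  expect_true(all(diff(res$funnel$count) <= 0))
})

test_that("low-depth survivors are flagged for orthogonal confirmation", {
  cfg <- sim_config(seed = 9, n_background = 0)
  lib <- sim_panel_library(cfg)
  panel <- get_panel(lib, "PNL02")
  ad_gene <- panel$gene[grepl("AD", panel$modes)][1]
  spike <- spike_spec(ad_gene, "HET", "P")
  sim <- simulate_variant_table(cfg, spikes = spike)
  sim$variants$depth[variant_key(sim$variants) == sim$truth$key] <- 12L
  res <- prioritize_case(sample_case("S1", panels = "PNL02"), sim$variants, lib)
  hit <- res$candidates[variant_key(res$candidates) == sim$truth$key, ]
  expect_true(grepl("NEEDS_CONFIRMATION", hit$flags))
  # at depth 20 and over no flag is raised
  sim$variants$depth[variant_key(sim$variants) == sim$truth$key] <- 20L
  res2 <- prioritize_case(sample_case("S1", panels = "PNL02"), sim$variants, lib)
  hit2 <- res2$candidates[variant_key(res2$candidates) == sim$truth$key, ]
  expect_false(grepl("NEEDS_CONFIRMATION", hit2$flags))
})

test_that("unknown panel ids abort prioritization", {
  cfg <- sim_config(seed = 1, n_background = 10)
  lib <- sim_panel_library(cfg)
  expect_error(
    prioritize_case(sample_case("S1", panels = "NOPE"),
                    simulate_variant_table(cfg)$variants, lib),
    "unknown panel"
  )
})

test_that("cis-only compound-het material is dropped, trans pairs survive", {
  vars <- with_panel_cols(mk_vars(
    mk_var(pos = 10, gene = "G001", zygosity = "HET", clin_class = "VUS"),
    mk_var(pos = 20, gene = "G001", zygosity = "HET", clin_class = "VUS")
  ), modes = "AR")
  k <- variant_key(vars)
  cis_ped <- trio_pedigree(genotypes = tibble::tibble(
    sample_id = c("CH", "CH", "FA", "FA", "MO", "MO"),
    var_id = rep(k, 3), zygosity = c("HET", "HET", "HET", "HET", "REF", "REF")
  ))
  pairs <- detect_compound_het(vars, cis_ped, "CH")
  out <- raredx:::resolve_comphet(vars, pairs)
  expect_equal(nrow(out), 0L)
  trans_ped <- trio_pedigree(genotypes = tibble::tibble(
    sample_id = c("CH", "CH", "FA", "FA", "MO", "MO"),
    var_id = rep(k, 3), zygosity = c("HET", "HET", "HET", "REF", "REF", "HET")
  ))
  pairs2 <- detect_compound_het(vars, trans_ped, "CH")
  out2 <- raredx:::resolve_comphet(vars, pairs2)
  expect_equal(nrow(out2), 2L)
  expect_equal(out2$pairing, rev(k))
  expect_equal(unique(out2$pair_phase), "TRANS")
})

test_that("outcome classification follows the positive/uncertain/partial/unsolved taxonomy", {
  case <- sample_case("S1", sex = "FEMALE", panels = "X")  # panels unused here
  base <- function(...) {
    v <- with_panel_cols(mk_vars(...), modes = "AR")
    v$pairing <- NA_character_; v$pair_phase <- NA_character_
    rank_candidates(v)
  }
  # HOM LP in an AR gene: positive
  expect_equal(classify_outcome(base(mk_var(zygosity = "HOM", clin_class = "LP")),
                                case)$label, "POSITIVE")
  # lone HET P in an AR gene: partial
  expect_equal(classify_outcome(base(mk_var(zygosity = "HET", clin_class = "P")),
                                case)$label, "PARTIAL")
  # HOM VUS: uncertain
  expect_equal(classify_outcome(base(mk_var(zygosity = "HOM", clin_class = "VUS")),
                                case)$label, "UNCERTAIN")
  # nothing supportive: unsolved
  expect_equal(classify_outcome(base(mk_var(zygosity = "HOM", clin_class = "NONE")),
                                case)$label, "UNSOLVED")
})

test_that("comp-het pairs drive positive or uncertain depending on their classes", {
  case <- sample_case("S1", sex = "FEMALE", panels = "X")
  pair_case <- function(cls1, cls2) {
    v <- with_panel_cols(mk_vars(
      mk_var(pos = 10, zygosity = "HET", clin_class = cls1),
      mk_var(pos = 20, zygosity = "HET", clin_class = cls2)
    ), modes = "AR")
    k <- variant_key(v)
    v$pairing <- rev(k)
    v$pair_phase <- "UNKNOWN"
    classify_outcome(rank_candidates(v), case)$label
  }
  expect_equal(pair_case("P", "LP"), "POSITIVE")
  expect_equal(pair_case("P", "VUS"), "UNCERTAIN")
  expect_equal(pair_case("VUS", "VUS"), "UNCERTAIN")
})

test_that("classification never yields POSITIVE from VUS-only support", {
  case <- sample_case("S1", sex = "FEMALE", panels = "X")
  for (seed in 1:10) {
    cfg <- sim_config(seed = seed, n_background = 150,
                      class_mix = c(P = 0, LP = 0, VUS = 0.5, CIP = 0.1,
                                    LB = 0.1, B = 0.2, NONE = 0.1))
    lib <- sim_panel_library(cfg)
    res <- prioritize_case(sample_case("S1", panels = "PNL01"),
                           simulate_variant_table(cfg)$variants, lib)
    out <- classify_outcome(res)
    if (nrow(out$supporting) > 0 && all(!out$supporting$clin_class %in% c("P", "LP"))) {
      expect_false(out$label == "POSITIVE")
    }
  }
})

test_that("X-linked outcomes respect sex: hemizygous P is positive in a male", {
  v <- with_panel_cols(mk_var(chrom = "chrX", zygosity = "HEM", clin_class = "P"),
                       modes = "XLR")
  v$pairing <- NA_character_
  out <- classify_outcome(rank_candidates(v), sample_case("S1", sex = "MALE", panels = "X"))
  expect_equal(out$label, "POSITIVE")
})

test_that("carrier-mode cases report recessive P/LP hets as carrier findings", {
  v <- with_panel_cols(mk_var(zygosity = "HET", clin_class = "P"), modes = "AR")
  v$pairing <- NA_character_
  case <- sample_case("S1", sex = "FEMALE", mode = "CARRIER")
  out <- classify_outcome(rank_candidates(v), case)
  expect_equal(out$label, "CARRIER_FINDINGS")
  v2 <- with_panel_cols(mk_var(zygosity = "HET", clin_class = "VUS"), modes = "AR")
  v2$pairing <- NA_character_
  expect_equal(classify_outcome(rank_candidates(v2), case)$label, "UNSOLVED")
})

test_that("outcome labels partition simulated cohorts: one label per case", {
  labels <- vapply(1:15, function(i) {
    cfg <- sim_config(seed = 400 + i, n_background = 120)
    lib <- sim_panel_library(cfg)
    res <- prioritize_case(sample_case("S1", panels = "PNL01"),
                           simulate_variant_table(cfg)$variants, lib)
    classify_outcome(res)$label
  }, character(1))
  expect_true(all(labels %in% c("POSITIVE", "UNCERTAIN", "PARTIAL", "UNSOLVED")))
  summ <- summarize_cohort(tibble::tibble(sample_id = as.character(1:15), label = labels))
  pct <- with(summ$overall, pct_positive + pct_uncertain + pct_partial + pct_unsolved)
  expect_lt(abs(pct - 100), 0.11)
})
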