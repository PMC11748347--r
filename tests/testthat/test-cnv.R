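mk_cov <- function(depths, genes = NULL) {
  n <- nrow(depths)
  m <- tibble::tibble(
    chrom = "chr1", start = seq_len(n) * 1000L, end = seq_len(n) * 1000L + 149L,
    gene = if (is.null(genes)) rep("G1", n) else genes
  )
  for (j in seq_len(ncol(depths))) m[[sprintf("S%02d", j)]] <- depths[, j]
  m
}

test_that("normalisation removes library-size effects and sets per-sample medians to 1", {
  const <- mk_cov(matrix(100, nrow = 5, ncol = 4))
  norm <- normalize_matrix(const)
  expect_true(all(as.matrix(norm[raredx:::coverage_sample_cols(norm)]) == 1))

  # one sample at exactly half depth everywhere: identical after normalisation
  half <- mk_cov(cbind(matrix(100, 5, 3), rep(50, 5)))
  nh <- normalize_matrix(half)
  expect_equal(nh$S04, rep(1, 5))

  set.seed(42)
  rand <- mk_cov(matrix(rlnorm(60, log(200), 0.4), nrow = 10))
  nr <- normalize_matrix(rand)
  for (sc in raredx:::coverage_sample_cols(nr)) {
    expect_equal(median(nr[[sc]]), 1, tolerance = 1e-12)
  }

  zero <- mk_cov(cbind(matrix(100, 5, 3), rep(0, 5)))
  expect_error(normalize_matrix(zero), "S04")
})

test_that("reference statistics match a brute-force recomputation and mask bad targets", {
  set.seed(7)
  depths <- matrix(rlnorm(25, log(1), 0.1), nrow = 5)
  m <- mk_cov(depths)
  st <- reference_stats(m, "S01", cnv_params())
  # brute force over the four reference columns
  ref <- depths[, 2:5]
  for (t in 1:5) {
    expect_equal(st$ref_mean[t], mean(ref[t, ]))
    expect_equal(st$ref_sd[t], sd(ref[t, ]))
  }
  # low-mean target is masked
  m2 <- m; for (s in sprintf("S%02d", 2:5)) m2[[s]][3] <- 0.05
  st2 <- reference_stats(m2, "S01", cnv_params())
  expect_true(st2$masked[3])
  # noisy target (CV above the mask ceiling) is masked
  m3 <- m; m3$S02[4] <- 3; m3$S03[4] <- 0.2
  st3 <- reference_stats(m3, "S01", cnv_params())
  expect_true(st3$masked[4])
  expect_error(reference_stats(m[, 1:6], "S01", cnv_params()), "3 reference")
})

test_that("dose and z behave analytically on noise-free fixtures", {
  base <- mk_cov(matrix(1, nrow = 4, ncol = 5))
  st <- reference_stats(base, "S01", cnv_params())
  dz <- compute_dose_z(base, "S01", st, cnv_params())
  expect_equal(dz$dose, rep(1, 4))
  expect_equal(dz$z, rep(0, 4))

  # heterozygous deletion at half the reference level
  del <- base; del$S01[2] <- 0.5
  dz2 <- compute_dose_z(del, "S01", reference_stats(del, "S01", cnv_params()),
                        cnv_params())
  expect_equal(dz2$dose[2], 0.5)
  expect_equal(dz2$z[2], -0.5 / 0.05)  # sd floor drives the denominator

  # homozygous deletion: dose 0, strongly negative z
  hom <- base; hom$S01[3] <- 0
  dz3 <- compute_dose_z(hom, "S01", reference_stats(hom, "S01", cnv_params()),
                        cnv_params())
  expect_equal(dz3$dose[3], 0)
  expect_lt(dz3$z[3], -10)
})

test_that("calling requires both the dose and the z criterion", {
  tc <- tibble::tibble(
    chrom = "chr1", start = 1:4 * 1000L, end = 1:4 * 1000L + 149L,
    gene = "G1", sample_id = "S01",
    rel_depth = c(0.5, 0.75, 1.5, 1.0),
    dose = c(0.5, 0.75, 1.5, 1.0),
    z = c(-6, -6, 4, 0),
    state = "NEUTRAL"
  )
  out <- call_targets(tc, cnv_params())
  expect_equal(out$state, c("DEL", "NEUTRAL", "DUP", "NEUTRAL"))
  # masked targets stay masked whatever the dose
  tc$state <- "MASKED"
  expect_true(all(call_targets(tc, cnv_params())$state == "MASKED"))
})

test_that("event segmentation merges runs within genes and never bridges gaps", {
  mk_calls <- function(states, genes) tibble::tibble(
    chrom = "chr1", start = seq_along(states) * 1000L,
    end = seq_along(states) * 1000L + 149L, gene = genes, sample_id = "S01",
    rel_depth = 1, dose = ifelse(states == "DEL", 0.5, 1),
    z = ifelse(states == "DEL", -5, 0), state = states
  )
  # three consecutive DEL targets in one gene: one event
  ev <- segment_events(mk_calls(c("DEL", "DEL", "DEL"), rep("G1", 3)), cnv_params())
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$n_targets, 3L)
  expect_equal(ev$type, "DEL")
  # gene boundary splits events
  ev2 <- segment_events(mk_calls(c("DEL", "DEL"), c("G1", "G2")), cnv_params())
  expect_equal(nrow(ev2), 2L)
  # a neutral target breaks the run: DEL, NEUTRAL, DEL = two events
  ev3 <- segment_events(mk_calls(c("DEL", "NEUTRAL", "DEL"), rep("G1", 3)), cnv_params())
  expect_equal(nrow(ev3), 2L)
  # min_targets drops short events
  ev4 <- segment_events(mk_calls(c("DEL", "NEUTRAL", "DEL"), rep("G1", 3)),
                        cnv_params(min_targets = 2))
  expect_equal(nrow(ev4), 0L)
})

test_that("noise-free spikes are called exactly when the dose crosses a threshold", {
  # measured dose differs from the planted dose by <~1%: halving a few
  # targets nudges the spiked sample's own normalisation median
  for (dose in c(0.3, 0.5, 0.8, 1.0, 1.2, 1.5, 2.0)) {
    cfg <- sim_config(seed = 13, depth_noise = 0)
    cov <- simulate_coverage_matrix(cfg, n_targets = 30, n_samples = 6,
                                    spikes = tibble::tibble(sample = "S02",
                                                            gene = "CNVG02",
                                                            dose = dose))
    res <- call_cnvs(cov$matrix, samples = "S02")
    expected <- dose <= 0.7 || dose >= 1.3
    expect_equal(nrow(res$events) > 0, expected, info = sprintf("dose %.1f", dose))
    if (expected) {
      expect_equal(res$events$gene, "CNVG02")
      expect_equal(res$events$type, if (dose < 1) "DEL" else "DUP")
      expect_equal(res$events$mean_dose, dose, tolerance = 0.05)
      expect_equal(res$events$n_targets, 3L)
    }
  }
})

test_that("null z-scores are standard-normal-like and false events are rare", {
  n_rep <- 40
  zs <- c(); n_events <- 0; n_samples_total <- 0
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(seed = 5000 + r)
    cov <- simulate_coverage_matrix(cfg, n_targets = 20, n_samples = 24)
    norm <- normalize_matrix(cov$matrix)
    st <- reference_stats(norm, "S01", cnv_params())
    dz <- compute_dose_z(norm, "S01", st, cnv_params())
    zs <- c(zs, dz$z[!st$masked])
    res <- call_cnvs(cov$matrix, samples = sprintf("S%02d", 1:4))
    n_events <- n_events + nrow(res$events)
    n_samples_total <- n_samples_total + 4
  }
  expect_lt(abs(mean(zs)), 0.05)
  expect_gt(sd(zs), 0.9); expect_lt(sd(zs), 1.1)
  expect_lte(n_events / n_samples_total, 0.05)
})

test_that("ddCt identities hold exactly", {
  ct <- simulate_ct_table(tibble::tibble(sample_id = c("T0", "Tdel", "Tdup"),
                                         true_ddct = c(0, 1, -1)),
                          noise_sd = 0)
  res <- ddct_fold_change(ct)
  expect_equal(res$fold_change[res$sample_id == "T0"], 1)
  expect_equal(res$fold_change[res$sample_id == "Tdel"], 0.5)
  expect_equal(res$fold_change[res$sample_id == "Tdup"], 2)
  expect_equal(res$fold_change, 2^(-res$ddct))
})

test_that("ddCt fold changes are reciprocal under sign flips", {
  x <- c(0.25, 0.5, 1, 1.7, 3)
  ct <- simulate_ct_table(tibble::tibble(
    sample_id = c(sprintf("P%d", seq_along(x)), sprintf("M%d", seq_along(x))),
    true_ddct = c(x, -x)), noise_sd = 0)
  res <- ddct_fold_change(ct)
  plus <- res$fold_change[match(sprintf("P%d", seq_along(x)), res$sample_id)]
  minus <- res$fold_change[match(sprintf("M%d", seq_along(x)), res$sample_id)]
  expect_equal(plus * minus, rep(1, length(x)))
})

test_that("replicate Cts are averaged and missing reference assays error", {
  ct <- tibble::tibble(
    sample_id = c(rep("T1", 4), rep("NC", 4)),
    assay_id = rep(c("A", "A", "R", "R"), 2),
    role = rep(c("TARGET", "TARGET", "REFERENCE", "REFERENCE"), 2),
    calibrator = c(rep(FALSE, 4), rep(TRUE, 4)),
    replicate = rep(1:2, 4),
    ct = c(25.0, 25.2, 20.0, 20.2, 24.0, 24.2, 20.0, 20.2)
  )
  res <- ddct_fold_change(ct)
  expect_equal(res$ddct, 1)   # (25.1-20.1) - (24.1-20.1)
  expect_equal(res$fold_change, 0.5)
  expect_error(ddct_fold_change(dplyr::filter(ct, role == "TARGET" | calibrator)),
               "reference assay")
})
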