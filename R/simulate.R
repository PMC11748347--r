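#' Configuration of the synthetic-data generators
#'
#' Defines the study conditions every simulated fixture is drawn under:
#' a small invented genome (~400 genes, 1-10 exons each, one in 23 genes
#' on the X chromosome), a background of incidental variants with a
#' realistic clinical-class mix and log-uniform population frequencies,
#' and multiplicative lognormal depth noise for coverage matrices.
#'
#' @param seed Integer RNG seed; a fixed seed makes every generator
#'   byte-reproducible.
#' @param n_background Number of background (non-causal) variants per
#'   simulated case.
#' @param class_mix Named probabilities over the clinical classes
#'   `P, LP, VUS, CIP, LB, B, NONE`; must sum to 1. The default keeps
#'   causal-class background rare, as in real annotated panels where most
#'   calls are benign or unclassified.
#' @param maf_bounds Log-uniform bounds for background population allele
#'   frequencies.
#' @param maf_missing_rate Fraction of background variants absent from all
#'   frequency sources.
#' @param n_genes Size of the synthetic gene universe.
#' @param depth_mean Mean sequencing depth (reads) for simulated variant
#'   calls and coverage baselines.
#' @param depth_noise Lognormal sigma of multiplicative depth noise. The
#'   default 0.08 (about 8% per-target coefficient of variation after
#'   normalisation) emulates a well-behaved hybrid-capture batch, the
#'   operating point the default dose/z thresholds are calibrated for;
#'   raise it to stress the caller.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_background = 300L,
                       class_mix = c(P = 0.01, LP = 0.02, VUS = 0.30, CIP = 0.05,
                                     LB = 0.20, B = 0.32, NONE = 0.10),
                       maf_bounds = c(1e-6, 0.5),
                       maf_missing_rate = 0.10,
                       n_genes = 400L,
                       depth_mean = 200,
                       depth_noise = 0.08) {
  stopifnot(abs(sum(class_mix) - 1) < 1e-8,
            all(names(class_mix) %in% clin_levels),
            maf_bounds[1] > 0, maf_bounds[2] <= 1, maf_bounds[1] < maf_bounds[2])
  structure(list(seed = as.integer(seed), n_background = as.integer(n_background),
                 class_mix = class_mix, maf_bounds = maf_bounds,
                 maf_missing_rate = maf_missing_rate, n_genes = as.integer(n_genes),
                 depth_mean = depth_mean, depth_noise = depth_noise),
            class = "sim_config")
}

# Deterministic sub-seed so independent generators draw from independent
# streams while staying reproducible from one top-level seed.
sub_seed <- function(seed, offset) as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)

#' The synthetic gene universe
#'
#' Deterministic (seed-free) layout: genes `G001..Gnnn` on `chr1..chr22`,
#' every 23rd gene on `chrX`; gene *i* spans 10 kb starting at
#' `i * 100000` and carries `1 + (i mod 10)` exons.
#'
#' @param cfg A [sim_config()].
#' @return Tibble with `gene, chrom, start, end, n_exons`.
#' @export
sim_gene_universe <- function(cfg = sim_config()) {
  i <- seq_len(cfg$n_genes)
  slot <- (i - 1L) %% 23L + 1L
  tibble(
    gene = sprintf("G%03d", i),
    chrom = ifelse(slot == 23L, "chrX", paste0("chr", slot)),
    start = i * 100000L,
    end = i * 100000L + 9999L,
    n_exons = 1L + (i %% 10L)
  )
}

#' Exon intervals for the synthetic universe
#'
#' Each gene's exons are 150 bp, spaced 1 kb apart from the gene start.
#'
#' @param universe Output of [sim_gene_universe()].
#' @return Target tibble `chrom, start, end, gene, exon`.
#' @export
sim_exon_targets <- function(universe) {
  purrr::pmap_dfr(universe, function(gene, chrom, start, end, n_exons) {
    ex <- seq_len(n_exons)
    tibble(chrom = chrom, start = start + (ex - 1L) * 1000L,
           end = start + (ex - 1L) * 1000L + 149L, gene = gene, exon = ex)
  })
}

#' A deterministic synthetic panel library
#'
#' Builds `n_panels` partially overlapping virtual panels over the
#' synthetic universe. Inheritance modes are assigned per gene (X genes
#' draw from XLD/XLR, autosomal genes from AD/AR/AD;AR); a small fraction
#' of entries carry exception flags so the filter escape hatches are
#' exercised.
#'
#' @param cfg A [sim_config()].
#' @param n_panels Number of panels.
#' @param genes_per_panel Genes per panel.
#' @param exception_rate Probability an entry carries one exception flag.
#' @return A `panel_library` tibble.
#' @export
sim_panel_library <- function(cfg = sim_config(), n_panels = 6L,
                              genes_per_panel = 30L, exception_rate = 0.05) {
  universe <- sim_gene_universe(cfg)
  set.seed(sub_seed(cfg$seed, 11L))
  rows <- purrr::map_dfr(seq_len(n_panels), function(p) {
    genes <- sort(sample(universe$gene, genes_per_panel))
    on_x <- universe$chrom[match(genes, universe$gene)] == "chrX"
    modes <- ifelse(
      on_x,
      sample(c("XLR", "XLD"), length(genes), replace = TRUE, prob = c(0.7, 0.3)),
      sample(c("AR", "AD", "AD;AR"), length(genes), replace = TRUE,
             prob = c(0.5, 0.4, 0.1))
    )
    flags <- ifelse(runif(length(genes)) < exception_rate,
                    sample(exception_levels, length(genes), replace = TRUE), "")
    tibble(panel_id = sprintf("PNL%02d", p),
           panel_name = sprintf("Synthetic panel %02d", p),
           category = sprintf("CAT%d", (p - 1L) %% 3L + 1L),
           subcategory = NA_character_,
           gene = genes, modes = modes, exception_flags = flags)
  })
  # writing + re-reading through the canonical loader normalises tokens
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp), add = TRUE)
  readr::write_tsv(rows, tmp, progress = FALSE)
  load_panels(tmp)
}

#' Specify causal genotypes to plant in a simulated case
#'
#' @param gene Gene symbol (must exist in the universe).
#' @param pattern Genotype pattern: `"HET"`, `"HOM"`, `"HEM"` or
#'   `"COMPHET"` (two heterozygous variants in the gene).
#' @param class Clinical class of the planted variant(s).
#' @param maf Population frequency written to the annotation (default
#'   `NA`: absent from all sources).
#' @return One-row spike-specification tibble.
#' @export
spike_spec <- function(gene, pattern = c("HOM", "HET", "HEM", "COMPHET"),
                       class = "P", maf = 1e-5) {
  pattern <- match.arg(pattern)
  tibble(gene = toupper(gene), pattern = pattern, class = class, maf = maf)
}

#' Simulate an annotated variant table with planted causal genotypes
#'
#' Background variants are drawn across the synthetic universe per the
#' configured class mix and frequency distribution; spiked genotypes are
#' appended per specification and listed in a truth manifest so tests and
#' validation never re-derive truth from generator internals.
#'
#' @param cfg A [sim_config()].
#' @param spikes Spike-specification tibble ([spike_spec()] rows), or
#'   `NULL`.
#' @param sex Sample sex; on `chrX`, male genotypes are hemizygous.
#' @param universe Optional pre-built [sim_gene_universe()].
#' @return List with `variants` (variant tibble) and `truth` (manifest:
#'   `key, gene, pattern, class`).
#' @export
simulate_variant_table <- function(cfg = sim_config(), spikes = NULL,
                                   sex = "FEMALE", universe = NULL) {
  universe <- universe %||% sim_gene_universe(cfg)
  set.seed(sub_seed(cfg$seed, 23L))
  n_req <- cfg$n_background
  n <- max(n_req, 1L)  # vector-safe generation; truncated back below
  gi <- sample(nrow(universe), n, replace = TRUE)
  offset <- sample(0:9999, n, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1),
                USE.NAMES = FALSE)
  cls <- sample(names(cfg$class_mix), n, replace = TRUE, prob = cfg$class_mix)
  maf <- exp(runif(n, log(cfg$maf_bounds[1]), log(cfg$maf_bounds[2])))
  maf[runif(n) < cfg$maf_missing_rate] <- NA_real_
  on_x <- universe$chrom[gi] == "chrX"
  zyg <- ifelse(runif(n) < 0.85, "HET", "HOM")
  if (identical(sex, "MALE")) zyg[on_x] <- "HEM"
  depth <- rpois(n, cfg$depth_mean)
  vaf <- pmin(pmax(ifelse(zyg == "HET", 0.5, 1) + stats::rnorm(n, 0, 0.04), 0), 1)
  bg <- tibble(
    chrom = universe$chrom[gi],
    pos = universe$start[gi] + offset,
    ref = ref, alt = alt,
    gene = universe$gene[gi],
    consequence = sample(c("missense_variant", "synonymous_variant",
                           "stop_gained", "splice_region_variant"),
                         n, replace = TRUE, prob = c(0.5, 0.3, 0.1, 0.1)),
    zygosity = zyg, vaf = vaf, depth = as.integer(depth),
    clin_class = cls,
    cip_has_plp = cls == "CIP" & runif(n) < 0.5,
    hgvs = NA_character_, flags = "",
    maf_popA = maf,
    maf_popB = ifelse(is.na(maf), NA_real_, pmin(maf * exp(stats::rnorm(n, 0, 0.2)), 1)),
    score_pred1 = sample(c("deleterious", "tolerated"), n, TRUE),
    score_pred2 = sample(c("damaging", "benign"), n, TRUE)
  )
  bg <- bg[seq_len(min(n_req, nrow(bg))), , drop = FALSE]
  # avoid colliding keys within the background
  bg <- bg[!duplicated(variant_key(bg)), , drop = FALSE]

  spike_rows <- list(); truth <- list()
  if (!is.null(spikes) && nrow(spikes) > 0) {
    for (i in seq_len(nrow(spikes))) {
      sp <- spikes[i, ]
      gidx <- match(sp$gene, universe$gene)
      if (is.na(gidx)) abort(sprintf("spike gene '%s' not in the synthetic universe", sp$gene))
      n_var <- if (sp$pattern == "COMPHET") 2L else 1L
      zygs <- if (sp$pattern == "COMPHET") c("HET", "HET") else sp$pattern
      for (k in seq_len(n_var)) {
        row <- tibble(
          chrom = universe$chrom[gidx],
          pos = universe$start[gidx] + 500L + 37L * (i - 1L) + 13L * (k - 1L),
          ref = "A", alt = c("G", "T")[k],
          gene = sp$gene, consequence = "missense_variant",
          zygosity = zygs[k],
          vaf = if (zygs[k] == "HET") 0.5 else 1,
          depth = as.integer(cfg$depth_mean),
          clin_class = sp$class,
          cip_has_plp = sp$class == "CIP",
          hgvs = sprintf("%s:c.%d%s>%s", sp$gene, 500L + 13L * (k - 1L), "A", c("G", "T")[k]),
          flags = "",
          maf_popA = sp$maf, maf_popB = NA_real_,
          score_pred1 = "deleterious", score_pred2 = "damaging"
        )
        spike_rows[[length(spike_rows) + 1L]] <- row
        truth[[length(truth) + 1L]] <- tibble(
          key = variant_key(row), gene = sp$gene,
          pattern = sp$pattern, class = sp$class
        )
      }
    }
  }
  spike_tbl <- dplyr::bind_rows(spike_rows)
  if (nrow(spike_tbl) > 0) {
    # spiked genes carry only the planted genotypes, so recovery (or an
    # engineered miss) never hinges on incidental background in the gene
    bg <- bg[!bg$gene %in% spike_tbl$gene, , drop = FALSE]
  }
  variants <- dplyr::bind_rows(bg, spike_tbl)
  truth_tbl <- if (length(truth)) dplyr::bind_rows(truth) else
    tibble(key = character(), gene = character(),
           pattern = character(), class = character())
  list(variants = variants, truth = truth_tbl)
}

#' Simulate a Mendelian-consistent pedigree for a case
#'
#' For a trio, parental genotypes of the planted variants follow
#' inheritance: a homozygous child has two heterozygous parents; a
#' compound-het child inherits one allele from each parent (trans) unless
#' `cis = TRUE`, in which case one parent carries both and the child's
#' second allele is treated as de novo; hemizygous X variants come from a
#' carrier mother; lone heterozygous dominant variants arise de novo
#' (both parents reference), consistent with unaffected parents.
#'
#' @param proband_id Index-case sample id.
#' @param sex Proband sex.
#' @param truth Truth manifest from [simulate_variant_table()].
#' @param structure `"SINGLETON"` or `"TRIO"`.
#' @param cis Plant compound-het pairs in cis instead of trans.
#' @return A `pedigree` with proband and (for trios) parental genotypes.
#' @export
simulate_pedigree <- function(proband_id, sex = "FEMALE", truth = NULL,
                              structure = c("TRIO", "SINGLETON"), cis = FALSE) {
  structure <- match.arg(structure)
  if (structure == "SINGLETON") {
    members <- tibble(sample_id = proband_id, father_id = NA_character_,
                      mother_id = NA_character_, sex = sex, affected = TRUE)
    ped <- new_pedigree(members)
    if (!is.null(truth) && nrow(truth) > 0) {
      ped <- set_pedigree_genotypes(ped, tibble(
        sample_id = proband_id, var_id = truth$key,
        zygosity = ifelse(truth$pattern == "COMPHET", "HET", truth$pattern)
      ))
    }
    return(ped)
  }
  father <- paste0(proband_id, "_F"); mother <- paste0(proband_id, "_M")
  members <- tibble(
    sample_id = c(proband_id, father, mother),
    father_id = c(father, NA, NA),
    mother_id = c(mother, NA, NA),
    sex = c(sex, "MALE", "FEMALE"),
    affected = c(TRUE, FALSE, FALSE)
  )
  gts <- list()
  if (!is.null(truth) && nrow(truth) > 0) {
    comphet_genes <- unique(truth$gene[truth$pattern == "COMPHET"])
    for (g in comphet_genes) {
      keys <- truth$key[truth$gene == g & truth$pattern == "COMPHET"]
      for (j in seq_along(keys)) {
        gts[[length(gts) + 1L]] <- tibble(sample_id = proband_id, var_id = keys[j],
                                          zygosity = "HET")
        if (cis) {
          # both inherited alleles on the paternal haplotype
          carrier <- father
          gts[[length(gts) + 1L]] <- tibble(sample_id = carrier, var_id = keys[j],
                                            zygosity = "HET")
          gts[[length(gts) + 1L]] <- tibble(sample_id = mother, var_id = keys[j],
                                            zygosity = "REF")
        } else {
          carrier <- if (j %% 2L == 1L) father else mother
          other <- if (j %% 2L == 1L) mother else father
          gts[[length(gts) + 1L]] <- tibble(sample_id = carrier, var_id = keys[j],
                                            zygosity = "HET")
          gts[[length(gts) + 1L]] <- tibble(sample_id = other, var_id = keys[j],
                                            zygosity = "REF")
        }
      }
    }
    rest <- truth[truth$pattern != "COMPHET", , drop = FALSE]
    for (j in seq_len(nrow(rest))) {
      key <- rest$key[j]; pattern <- rest$pattern[j]
      gts[[length(gts) + 1L]] <- tibble(sample_id = proband_id, var_id = key,
                                        zygosity = pattern)
      parental <- switch(
        pattern,
        HOM = tibble(sample_id = c(father, mother), var_id = key,
                     zygosity = c("HET", "HET")),
        HEM = tibble(sample_id = c(father, mother), var_id = key,
                     zygosity = c("REF", "HET")),
        HET = tibble(sample_id = c(father, mother), var_id = key,
                     zygosity = c("REF", "REF"))
      )
      gts[[length(gts) + 1L]] <- parental
    }
  }
  ped <- new_pedigree(members)
  if (length(gts) > 0) ped <- set_pedigree_genotypes(ped, dplyr::bind_rows(gts))
  ped
}

#' Simulate a batch coverage matrix with optional CNV spikes
#'
#' Depth of target *t* in sample *s* is
#' `baseline(t) * size_factor(s) * lognormal_noise * dose`, where the dose
#' is 1 except on spiked (sample, target) cells. Baselines vary
#' lognormally around the configured mean depth; per-sample size factors
#' emulate library-size differences.
#'
#' @param cfg A [sim_config()].
#' @param n_targets,n_samples Matrix dimensions (`n_samples >= 4` so a
#'   held-out reference set of 3 remains).
#' @param spikes Tibble with `sample` (column name `S01`-style), `gene`,
#'   `dose`, or `NULL`; all exon targets of the gene are scaled.
#' @param targets_per_gene Number of consecutive targets per synthetic
#'   gene (genes named `CNVG01, ...`).
#' @return List with `matrix` (coverage tibble) and `truth`
#'   (`sample, gene, n_targets, dose`).
#' @export
simulate_coverage_matrix <- function(cfg = sim_config(), n_targets = 60L,
                                     n_samples = 8L, spikes = NULL,
                                     targets_per_gene = 3L) {
  if (n_samples < 4L) abort("n_samples must be at least 4")
  set.seed(sub_seed(cfg$seed, 57L))
  genes <- sprintf("CNVG%02d", ceiling(seq_len(n_targets) / targets_per_gene))
  baseline <- cfg$depth_mean * rlnorm(n_targets, 0, 0.25)
  size_factor <- rlnorm(n_samples, 0, 0.15)
  samples <- sprintf("S%02d", seq_len(n_samples))
  noise <- matrix(rlnorm(n_targets * n_samples, 0, cfg$depth_noise),
                  nrow = n_targets)
  depth <- outer(baseline, size_factor) * noise
  truth <- tibble(sample = character(), gene = character(),
                  n_targets = integer(), dose = numeric())
  if (!is.null(spikes) && nrow(spikes) > 0) {
    for (i in seq_len(nrow(spikes))) {
      sp <- spikes[i, ]
      rows <- which(genes == sp$gene)
      col <- match(sp$sample, samples)
      if (length(rows) == 0L || is.na(col)) {
        abort(sprintf("CNV spike (%s, %s) outside the simulated matrix",
                      sp$sample, sp$gene))
      }
      depth[rows, col] <- depth[rows, col] * sp$dose
      truth <- dplyr::bind_rows(truth, tibble(
        sample = sp$sample, gene = sp$gene,
        n_targets = length(rows), dose = sp$dose
      ))
    }
  }
  m <- tibble(
    chrom = "chr1",
    start = 1000L + (seq_len(n_targets) - 1L) * 500L,
    end = 1000L + (seq_len(n_targets) - 1L) * 500L + 149L,
    gene = genes
  )
  for (j in seq_len(n_samples)) m[[samples[j]]] <- depth[, j]
  list(matrix = m, truth = truth)
}

#' Simulate a qPCR Ct table with known copy-number states
#'
#' Builds technical-replicate Ct values for test samples of given true
#' delta-delta Ct (0 for two copies, +1 for a heterozygous deletion, -1
#' for a duplication) against two calibrator samples.
#'
#' @param samples Tibble with `sample_id, true_ddct`.
#' @param cfg A [sim_config()] (seed; Ct replicate noise is 0.05 cycles).
#' @param n_replicates Technical replicates per assay.
#' @param noise_sd Replicate standard deviation in cycles (0 for exact
#'   identities).
#' @return Ct tibble in [read_ct_table()] layout.
#' @export
simulate_ct_table <- function(samples, cfg = sim_config(), n_replicates = 3L,
                              noise_sd = 0.05) {
  set.seed(sub_seed(cfg$seed, 91L))
  base_target <- 24; base_ref <- 20
  calib <- tibble(sample_id = c("NC1", "NC2"), true_ddct = 0, calibrator = TRUE)
  all <- dplyr::bind_rows(mutate(samples, calibrator = FALSE), calib)
  purrr::pmap_dfr(all, function(sample_id, true_ddct, calibrator) {
    reps <- seq_len(n_replicates)
    dplyr::bind_rows(
      tibble(sample_id = sample_id, assay_id = "EXON_A", role = "TARGET",
             calibrator = calibrator, replicate = reps,
             ct = base_target + true_ddct + stats::rnorm(n_replicates, 0, noise_sd)),
      tibble(sample_id = sample_id, assay_id = "REF_GENE", role = "REFERENCE",
             calibrator = calibrator, replicate = reps,
             ct = base_ref + stats::rnorm(n_replicates, 0, noise_sd))
    )
  })
}

#' Pseudocontrol spike-in validation of the prioritization cascade
#'
#' Emulates validating the pipeline on pseudocontrol samples harbouring
#' known causal genotypes: each pseudocontrol case plants one causal
#' genotype compatible with its assigned virtual panel, runs the full
#' cascade and checks the planted variant(s) survive. Engineered
#' violations plant genotypes that break exactly one filter predicate;
#' each such spike must be missed, and the report attributes every miss to
#' the first cascade stage that removed it (`panel`, `frequency`,
#' `classification`, `zygosity`).
#'
#' @param cfg A [sim_config()].
#' @param n_cases Number of pseudocontrol cases.
#' @param violation `NULL` for fully compatible spikes, or one of
#'   `"panel"`, `"frequency"`, `"classification"`, `"zygosity"` to
#'   engineer that specific failure into every case.
#' @param fcfg A [filter_config()].
#' @return A `pseudocontrol_report`: list with `cases` (per-case tibble:
#'   `sample_id, panel_id, key, recovered, reason`), `n_spiked`,
#'   `n_recovered`, `recovery_pct`.
#' @export
run_pseudocontrol_validation <- function(cfg = sim_config(), n_cases = 20L,
                                         violation = NULL,
                                         fcfg = filter_config()) {
  universe <- sim_gene_universe(cfg)
  library <- sim_panel_library(cfg)
  panel_ids <- unique(library$panel_id)
  rows <- list()
  for (i in seq_len(n_cases)) {
    case_cfg <- cfg
    case_cfg$seed <- sub_seed(cfg$seed, 1000L + i)
    set.seed(sub_seed(cfg$seed, 2000L + i))
    pid <- sample(panel_ids, 1L)
    panel <- get_panel(library, pid)
    # pick an autosomal entry without exception flags so the engineered
    # violations are not rescued by an escape hatch
    cand <- panel[!has_exception(panel$exception_flags) &
                    !grepl("^XL", panel$modes), , drop = FALSE]
    if (nrow(cand) == 0L) cand <- panel
    entry <- cand[sample(nrow(cand), 1L), ]
    modes <- split_tokens(entry$modes)[[1]]
    mode <- modes[1]
    pattern <- if (mode == "AR") sample(c("HOM", "COMPHET"), 1L) else "HET"
    spike <- spike_spec(entry$gene, pattern = pattern, class = "P", maf = 1e-5)

    if (identical(violation, "panel")) {
      off <- setdiff(universe$gene, panel$gene)
      spike$gene <- sample(off, 1L)
    } else if (identical(violation, "frequency")) {
      spike$maf <- 0.2
    } else if (identical(violation, "classification")) {
      spike$class <- "B"
    } else if (identical(violation, "zygosity")) {
      # a lone non-P/LP heterozygote in a recessive-only gene cannot act
      ar_only <- cand[cand$modes == "AR", , drop = FALSE]
      if (nrow(ar_only) > 0) spike$gene <- ar_only$gene[sample(nrow(ar_only), 1L)]
      spike$pattern <- "HET"
      spike$class <- "VUS"
    }

    sim <- simulate_variant_table(case_cfg, spikes = spike, sex = "FEMALE",
                                  universe = universe)
    case <- sample_case(sprintf("PC%03d", i), sex = "FEMALE", panels = pid)
    res <- prioritize_case(case, sim$variants, library, cfg = fcfg)
    got <- if (nrow(res$candidates)) variant_key(res$candidates) else character()
    for (k in sim$truth$key) {
      recovered <- k %in% got
      reason <- if (recovered) NA_character_ else {
        miss_reason(sim$variants[variant_key(sim$variants) == k, ],
                    panel, fcfg, case$sex, res)
      }
      rows[[length(rows) + 1L]] <- tibble(
        sample_id = case$sample_id, panel_id = pid, key = k,
        pattern = sim$truth$pattern[sim$truth$key == k],
        recovered = recovered, reason = reason
      )
    }
  }
  cases <- dplyr::bind_rows(rows)
  structure(list(
    cases = cases,
    n_spiked = nrow(cases),
    n_recovered = sum(cases$recovered),
    recovery_pct = round_half_up(100 * sum(cases$recovered) / nrow(cases), 1)
  ), class = "pseudocontrol_report")
}

# First cascade stage whose predicate the missed spike fails.
miss_reason <- function(variant, panel, fcfg, sex, res) {
  if (nrow(variant) == 0L) return("absent")
  if (!toupper(variant$gene[1]) %in% panel$gene) return("panel")
  idx <- match(toupper(variant$gene[1]), panel$gene)
  variant$panel_modes <- panel$modes[idx]
  variant$panel_exceptions <- panel$exception_flags[idx]
  if (nrow(filter_frequency(variant, fcfg)) == 0L) return("frequency")
  if (nrow(filter_classification(variant, fcfg)) == 0L) return("classification")
  if (nrow(suppressWarnings(
    check_zygosity_consistency(variant, sex = sex, cfg = fcfg))) == 0L) {
    return("zygosity")
  }
  "unknown"
}

#' @export
print.pseudocontrol_report <- function(x, ...) {
  cat(sprintf("<pseudocontrol_report> %d/%d spiked genotype(s) recovered (%.1f%%)\n",
              x$n_recovered, x$n_spiked, x$recovery_pct))
  misses <- x$cases[!x$cases$recovered, , drop = FALSE]
  if (nrow(misses)) {
    cat("missed, by reason:\n")
    print(table(misses$reason))
  }
  invisible(x)
}
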