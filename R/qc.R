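#' Fold-80 base penalty
#'
#' Coverage-uniformity statistic for hybrid-capture panels: the mean
#' per-base depth divided by the 20th percentile of per-base depth
#' (linear-interpolation percentile, so the value is bit-reproducible).
#' Perfectly uniform coverage gives 1; the further above 1, the more
#' sequencing would be needed to lift the bottom 20% of bases to the mean.
#' When at least 20% of bases have zero depth the statistic is undefined
#' and `NA` is returned.
#'
#' @param per_base_depths Numeric vector of depths, one per target base.
#' @return A single number, or `NA` when the 20th percentile is zero.
#' @export
fold80_base_penalty <- function(per_base_depths) {
  if (length(per_base_depths) == 0L) abort("empty depth vector")
  p20 <- unname(stats::quantile(per_base_depths, probs = 0.2, type = 7))
  if (p20 <= 0) return(NA_real_)
  mean(per_base_depths) / p20
}

#' Fraction of bases covered at given depth thresholds
#'
#' @param per_base_depths Numeric vector of per-base depths.
#' @param thresholds Depth cutoffs (reads), e.g. `c(20, 30)`.
#' @return Tibble with `threshold` and `fraction` (proportion of bases at
#'   depth >= threshold).
#' @export
coverage_fractions <- function(per_base_depths, thresholds = c(20, 30)) {
  if (length(per_base_depths) == 0L) abort("empty depth vector")
  tibble(
    threshold = thresholds,
    fraction = vapply(thresholds, function(t) mean(per_base_depths >= t), numeric(1))
  )
}

#' Read-level summary metrics
#'
#' @param total_reads,duplicate_reads,on_target_reads Read counts for one
#'   sample; duplicates and on-target reads cannot exceed the total.
#' @return One-row tibble: `total_reads, duplicate_fraction,
#'   on_target_fraction`.
#' @export
read_summary_metrics <- function(total_reads, duplicate_reads, on_target_reads) {
  if (total_reads <= 0) abort("total_reads must be positive")
  if (duplicate_reads > total_reads) abort("duplicate reads exceed total reads")
  if (on_target_reads > total_reads) abort("on-target reads exceed total reads")
  if (duplicate_reads < 0 || on_target_reads < 0) abort("read counts must be non-negative")
  tibble(
    total_reads = total_reads,
    duplicate_fraction = duplicate_reads / total_reads,
    on_target_fraction = on_target_reads / total_reads
  )
}

#' Per-sample QC metrics from a per-base depth track
#'
#' @param per_base_depths Numeric vector of per-base depths for one
#'   sample's targets.
#' @param sample_id Sample label.
#' @param thresholds Coverage thresholds (default 20x and 30x).
#' @return One-row tibble with mean depth, fold-80 penalty and the
#'   coverage fractions (`pct_ge_<t>x` columns).
#' @export
qc_sample_metrics <- function(per_base_depths, sample_id = NA_character_,
                              thresholds = c(20, 30)) {
  fr <- coverage_fractions(per_base_depths, thresholds)
  out <- tibble(
    sample_id = sample_id,
    mean_depth = mean(per_base_depths),
    fold80 = fold80_base_penalty(per_base_depths)
  )
  for (i in seq_len(nrow(fr))) {
    out[[sprintf("pct_ge_%dx", as.integer(fr$threshold[i]))]] <- fr$fraction[i]
  }
  out
}

#' Flag exons commonly uncovered across a batch
#'
#' An exon base counts as covered when its depth reaches `min_depth`
#' (default 20x, the panel's recurring confirmation threshold). An exon is
#' flagged as commonly uncovered when its covered fraction is strictly
#' below `cover_frac_max` (default 50%) in at least `sample_frac_min`
#' (default 95%) of samples — such exons need a systematic fallback assay
#' rather than per-case Sanger filling.
#'
#' @param exons Tibble of exon intervals (`chrom, start, end, label`),
#'   1-based inclusive.
#' @param depth_tracks Named list (one element per sample) of per-base
#'   depth tibbles with `chrom, pos, depth` (1-based positions), or of
#'   functions mapping `(chrom, positions)` to depths.
#' @param min_depth Depth floor defining "covered" (default 20).
#' @param cover_frac_max Coverage fraction below which an exon counts as
#'   uncovered in one sample (strict `<`, default 0.5).
#' @param sample_frac_min Minimum proportion of samples (`>=`, default
#'   0.95) for the common-uncovered flag.
#' @return Tibble: one row per exon with `label, chrom, start, end,
#'   n_samples_below, fraction_samples_below, flagged` plus a
#'   `covered_fraction` list-column of per-sample values.
#' @export
find_common_uncovered_exons <- function(exons, depth_tracks, min_depth = 20,
                                        cover_frac_max = 0.5,
                                        sample_frac_min = 0.95) {
  if (length(depth_tracks) == 0L) abort("at least one sample depth track required")
  n_samples <- length(depth_tracks)
  purrr::pmap_dfr(
    list(exons$chrom, exons$start, exons$end,
         if ("label" %in% names(exons)) exons$label else rep(NA_character_, nrow(exons))),
    function(chrom, start, end, label) {
      pos <- seq.int(start, end)
      covered <- vapply(depth_tracks, function(track) {
        d <- track_depths(track, chrom, pos)
        if (anyNA(d)) {
          abort(sprintf("exon %s (%s:%d-%d) outside depth track bounds",
                        label %||% "?", chrom, start, end))
        }
        mean(d >= min_depth)
      }, numeric(1))
      n_below <- sum(covered < cover_frac_max)
      tibble(
        label = label, chrom = chrom, start = start, end = end,
        n_samples_below = n_below,
        fraction_samples_below = n_below / n_samples,
        flagged = (n_below / n_samples) >= sample_frac_min,
        covered_fraction = list(unname(covered))
      )
    }
  )
}

track_depths <- function(track, chrom, pos) {
  if (is.function(track)) return(track(chrom, pos))
  assert_cols(track, c("chrom", "pos", "depth"), "depth track")
  sel <- track[norm_chrom(track$chrom) == norm_chrom(chrom), , drop = FALSE]
  sel$depth[match(pos, sel$pos)]
}

#' Read a run-length encoded per-base depth track
#'
#' Four-column BED-like input (`chrom, start0, end0, depth`; 0-based
#' half-open, constant depth per line, mosdepth-style) expanded to one row
#' per base.
#'
#' @param path Path to the 4-column TSV.
#' @return Tibble with `chrom, pos, depth` (1-based positions).
#' @export
read_perbase_depths <- function(path) {
  raw <- readr::read_tsv(path, col_names = c("chrom", "start0", "end0", "depth"),
                         show_col_types = FALSE, progress = FALSE)
  if (any(raw$end0 <= raw$start0)) abort("depth track has end <= start")
  purrr::pmap_dfr(raw, function(chrom, start0, end0, depth) {
    tibble(chrom = chrom, pos = seq.int(start0 + 1L, end0), depth = depth)
  })
}
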