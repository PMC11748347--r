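#' Parameters of the gene-dose / z-score CNV caller
#'
#' A target is called deleted when both its gene dose (ratio of the
#' sample's normalised depth to the reference-batch mean) and its z-score
#' cross their thresholds; duplication is symmetric. Requiring both
#' criteria suppresses calls on noisy, low-information targets.
#'
#' @param z_min Minimum |z| for a call (default 2.5).
#' @param dose_del_max Maximum dose for a deletion call (default 0.7; a
#'   clean heterozygous deletion sits near 0.5).
#' @param dose_dup_min Minimum dose for a duplication call (default 1.3;
#'   a clean single-copy gain sits near 1.5).
#' @param min_targets Minimum consecutive called targets per reported
#'   event (default 1, so single-exon events are reportable).
#' @param max_ref_cv Mask targets whose reference coefficient of variation
#'   exceeds this (default 0.3).
#' @param min_ref_depth Mask targets whose reference mean relative depth
#'   falls below this (default 0.1).
#' @param sd_floor Lower bound on the reference standard deviation used in
#'   the z denominator (default 0.05 relative-depth units), preventing
#'   infinite z on degenerate references.
#' @return A `cnv_params` list.
#' @export
cnv_params <- function(z_min = 2.5, dose_del_max = 0.7, dose_dup_min = 1.3,
                       min_targets = 1L, max_ref_cv = 0.3, min_ref_depth = 0.1,
                       sd_floor = 0.05) {
  stopifnot(dose_del_max < 1, dose_dup_min > 1, z_min > 0,
            min_targets >= 1, max_ref_cv > 0, min_ref_depth >= 0, sd_floor >= 0)
  structure(list(z_min = z_min, dose_del_max = dose_del_max,
                 dose_dup_min = dose_dup_min, min_targets = as.integer(min_targets),
                 max_ref_cv = max_ref_cv, min_ref_depth = min_ref_depth,
                 sd_floor = sd_floor),
            class = "cnv_params")
}

#' Normalise a coverage matrix to relative depths
#'
#' Divides each sample's column by that sample's median target depth,
#' removing library-size effects; after normalisation every sample has
#' median relative depth 1.
#'
#' @param m Coverage tibble (`chrom, start, end, gene` + one numeric
#'   column per sample).
#' @return Coverage tibble of relative depths.
#' @export
normalize_matrix <- function(m) {
  scols <- coverage_sample_cols(m)
  if (length(scols) < 2L) abort("normalisation needs at least 2 samples")
  out <- m
  for (sc in scols) {
    med <- stats::median(m[[sc]])
    if (!is.finite(med) || med <= 0) {
      abort(sprintf("sample '%s' has median depth 0; cannot normalise", sc))
    }
    out[[sc]] <- m[[sc]] / med
  }
  out
}

#' Per-target reference statistics for one test sample
#'
#' The reference set is all other samples of the batch. Targets are masked
#' (excluded from calling) when the reference mean relative depth is below
#' `min_ref_depth` or the reference coefficient of variation exceeds
#' `max_ref_cv` — such targets cannot support a reliable dose estimate.
#'
#' @param m Normalised coverage tibble (see [normalize_matrix()]).
#' @param test_sample Sample column to hold out.
#' @param params A [cnv_params()].
#' @return Tibble with `chrom, start, end, gene, ref_mean, ref_sd, masked`.
#' @export
reference_stats <- function(m, test_sample, params = cnv_params()) {
  scols <- coverage_sample_cols(m)
  if (!test_sample %in% scols) abort(sprintf("sample '%s' not in matrix", test_sample))
  ref <- setdiff(scols, test_sample)
  if (length(ref) < 3L) abort("need at least 3 reference samples")
  x <- as.matrix(m[ref])
  ref_mean <- rowMeans(x)
  ref_sd <- apply(x, 1L, stats::sd)
  cv <- ifelse(ref_mean > 0, ref_sd / ref_mean, Inf)
  tibble(
    chrom = m$chrom, start = m$start, end = m$end, gene = m$gene,
    ref_mean = ref_mean, ref_sd = ref_sd,
    masked = ref_mean < params$min_ref_depth | cv > params$max_ref_cv
  )
}

#' Per-target dose and z-score for one sample
#'
#' Dose is the sample's relative depth over the reference mean (about 0.5
#' for a heterozygous deletion, 1.5 for a single-copy duplication); the
#' z-score standardises the deviation by the reference standard deviation
#' (floored at `params$sd_floor`).
#'
#' @param m Normalised coverage tibble.
#' @param test_sample Sample column under test.
#' @param stats Output of [reference_stats()] for the same sample.
#' @param params A [cnv_params()].
#' @return Target-call tibble: `chrom, start, end, gene, sample_id,
#'   rel_depth, dose, z, state` (state `MASKED` or `NEUTRAL` at this
#'   stage).
#' @export
compute_dose_z <- function(m, test_sample, stats, params = cnv_params()) {
  rel <- m[[test_sample]]
  denom <- pmax(stats$ref_sd, params$sd_floor)
  tibble(
    chrom = m$chrom, start = m$start, end = m$end, gene = m$gene,
    sample_id = test_sample,
    rel_depth = rel,
    dose = ifelse(stats$ref_mean > 0, rel / stats$ref_mean, NA_real_),
    z = (rel - stats$ref_mean) / denom,
    state = ifelse(stats$masked, "MASKED", "NEUTRAL")
  )
}

#' Apply the dose/z calling thresholds
#'
#' A target is `DEL` when `dose <= dose_del_max` and `z <= -z_min`, `DUP`
#' when `dose >= dose_dup_min` and `z >= z_min`, otherwise `NEUTRAL`;
#' masked targets are never called.
#'
#' @param calls Target-call tibble from [compute_dose_z()].
#' @param params A [cnv_params()].
#' @return The tibble with `state` filled in.
#' @export
call_targets <- function(calls, params = cnv_params()) {
  st <- calls$state
  callable <- st != "MASKED" & !is.na(calls$dose)
  st[callable & calls$dose <= params$dose_del_max & calls$z <= -params$z_min] <- "DEL"
  st[callable & calls$dose >= params$dose_dup_min & calls$z >= params$z_min] <- "DUP"
  calls$state <- st
  calls
}

#' Merge called targets into gene-level CNV events
#'
#' Maximal runs of consecutively called targets of the same type within
#' one gene become one event; a neutral or masked target breaks the run.
#' Events spanning fewer than `min_targets` targets are dropped.
#'
#' @param calls Target-call tibble (ordered by genomic position) from
#'   [call_targets()].
#' @param params A [cnv_params()].
#' @return Event tibble: `sample_id, gene, chrom, start, end, n_targets,
#'   mean_dose, extreme_z, type`.
#' @export
segment_events <- function(calls, params = cnv_params()) {
  empty <- tibble(sample_id = character(), gene = character(), chrom = character(),
                  start = integer(), end = integer(), n_targets = integer(),
                  mean_dose = numeric(), extreme_z = numeric(), type = character())
  called <- calls$state %in% c("DEL", "DUP")
  if (!any(called)) return(empty)
  grp <- cumsum(
    c(TRUE, calls$gene[-1] != calls$gene[-nrow(calls)] |
        calls$state[-1] != calls$state[-nrow(calls)])
  )
  keep <- which(called)
  ev <- tibble(
    grp = grp[keep],
    sample_id = calls$sample_id[keep],
    gene = calls$gene[keep], chrom = calls$chrom[keep],
    start = calls$start[keep], end = calls$end[keep],
    dose = calls$dose[keep], z = calls$z[keep], type = calls$state[keep]
  ) |>
    group_by(.data$grp) |>
    summarise(
      sample_id = .data$sample_id[1], gene = .data$gene[1], chrom = .data$chrom[1],
      start = min(.data$start), end = max(.data$end), n_targets = n(),
      mean_dose = mean(.data$dose),
      extreme_z = .data$z[which.max(abs(.data$z))],
      type = .data$type[1], .groups = "drop"
    ) |>
    dplyr::select(-"grp") |>
    dplyr::filter(.data$n_targets >= params$min_targets)
  as_tibble(ev)
}

#' Call CNVs for one or all samples of a batch
#'
#' Convenience pipeline: [normalize_matrix()] then, per test sample,
#' [reference_stats()], [compute_dose_z()], [call_targets()] and
#' [segment_events()].
#'
#' @param m Raw coverage tibble.
#' @param samples Sample columns to test (default: all).
#' @param params A [cnv_params()].
#' @return A `cnv_result` object: list with `events` (all samples bound),
#'   `target_calls` and `params`.
#' @export
call_cnvs <- function(m, samples = NULL, params = cnv_params()) {
  norm <- normalize_matrix(m)
  samples <- samples %||% coverage_sample_cols(m)
  per_sample <- purrr::map(samples, function(s) {
    st <- reference_stats(norm, s, params)
    tc <- call_targets(compute_dose_z(norm, s, st, params), params)
    list(calls = tc, events = segment_events(tc, params))
  })
  structure(
    list(events = dplyr::bind_rows(purrr::map(per_sample, "events")),
         target_calls = dplyr::bind_rows(purrr::map(per_sample, "calls")),
         params = params),
    class = "cnv_result"
  )
}

#' @export
print.cnv_result <- function(x, ...) {
  cat(sprintf("<cnv_result> %d event(s) over %d target call(s)\n",
              nrow(x$events), nrow(x$target_calls)))
  if (nrow(x$events)) print(x$events)
  invisible(x)
}

#' Comparative-Ct (2^-ddCt) fold change
#'
#' Confirms candidate CNVs from qPCR cycle thresholds. Per sample,
#' replicate Cts are averaged per assay; the within-sample delta Ct is
#' `mean Ct(target assay) - mean Ct(reference assay)`; the delta-delta Ct
#' subtracts the mean delta Ct of the calibrator (negative control)
#' samples; the fold change is `2^(-ddCt)`. A heterozygous deletion is
#' expected near fold 0.5, a duplication near 1.5-2.
#'
#' @param ct Ct tibble from [read_ct_table()] (or equivalently shaped).
#' @return Tibble with one row per (non-calibrator sample, target assay):
#'   `sample_id, assay_id, delta_ct_test, delta_ct_calibrator, ddct,
#'   fold_change`.
#' @export
ddct_fold_change <- function(ct) {
  assert_cols(ct, c("sample_id", "assay_id", "role", "calibrator", "ct"), "Ct table")
  if (!any(ct$calibrator)) abort("no calibrator sample in Ct table")

  per_assay <- ct |>
    group_by(.data$sample_id, .data$assay_id, .data$role, .data$calibrator) |>
    summarise(ct = mean(.data$ct), .groups = "drop")

  refs <- dplyr::filter(per_assay, .data$role == "REFERENCE") |>
    group_by(.data$sample_id) |>
    summarise(ref_ct = mean(.data$ct), .groups = "drop")
  targets <- dplyr::filter(per_assay, .data$role == "TARGET")
  missing_ref <- setdiff(unique(targets$sample_id), refs$sample_id)
  if (length(missing_ref) > 0) {
    abort(sprintf("sample(s) missing a reference assay: %s",
                  paste(missing_ref, collapse = ", ")))
  }
  dct <- dplyr::left_join(targets, refs, by = "sample_id") |>
    mutate(delta_ct = .data$ct - .data$ref_ct)

  calib <- dct |>
    dplyr::filter(.data$calibrator) |>
    group_by(.data$assay_id) |>
    summarise(delta_ct_calibrator = mean(.data$delta_ct), .groups = "drop")
  if (nrow(calib) == 0L) abort("calibrator samples lack target-assay measurements")

  dct |>
    dplyr::filter(!.data$calibrator) |>
    dplyr::left_join(calib, by = "assay_id") |>
    mutate(
      ddct = .data$delta_ct - .data$delta_ct_calibrator,
      fold_change = 2^(-.data$ddct)
    ) |>
    dplyr::transmute(
      sample_id = .data$sample_id, assay_id = .data$assay_id,
      delta_ct_test = .data$delta_ct,
      delta_ct_calibrator = .data$delta_ct_calibrator,
      ddct = .data$ddct, fold_change = .data$fold_change
    )
}
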