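#' Summarise diagnostic outcomes across a cohort
#'
#' Computes the cohort diagnostic yield: the positive yield is the
#' percentage of diagnostic cases with a full genetic diagnosis; the
#' combined yield adds cases with uncertain (VUS-supported) findings that
#' may convert to positives on reclassification. Percentages are rounded
#' half-up to one decimal.
#'
#' @param outcomes Tibble with one row per diagnostic case: `sample_id`,
#'   `label` (`POSITIVE/UNCERTAIN/PARTIAL/UNSOLVED`) and optionally
#'   `category`; or a list of `case_outcome` objects with a parallel
#'   `cases` list of [sample_case()].
#' @return A `cohort_summary`: list with `overall` (one-row tibble of
#'   counts, `positive_yield` and `combined_yield`) and `by_category`
#'   (same columns per clinical category, when categories are present).
#' @export
summarize_cohort <- function(outcomes) {
  if (is.list(outcomes) && !is.data.frame(outcomes)) {
    outcomes <- purrr::map_dfr(outcomes, function(o) {
      tibble(sample_id = NA_character_, label = o$label, category = NA_character_)
    })
  }
  assert_cols(outcomes, "label", "outcomes")
  if (nrow(outcomes) == 0L) abort("cannot summarise an empty cohort")
  bad <- setdiff(unique(outcomes$label),
                 c("POSITIVE", "UNCERTAIN", "PARTIAL", "UNSOLVED"))
  if (length(bad) > 0) {
    abort(sprintf("non-diagnostic outcome label(s) in cohort: %s",
                  paste(bad, collapse = ", ")))
  }
  summarise_block <- function(df) {
    n <- nrow(df)
    counts <- table(factor(df$label, levels = c("POSITIVE", "UNCERTAIN",
                                                "PARTIAL", "UNSOLVED")))
    tibble(
      n_cases = n,
      n_positive = unname(counts["POSITIVE"]),
      n_uncertain = unname(counts["UNCERTAIN"]),
      n_partial = unname(counts["PARTIAL"]),
      n_unsolved = unname(counts["UNSOLVED"]),
      positive_yield = round_half_up(100 * counts[["POSITIVE"]] / n, 1),
      combined_yield = round_half_up(
        100 * (counts[["POSITIVE"]] + counts[["UNCERTAIN"]]) / n, 1),
      pct_positive = round_half_up(100 * counts[["POSITIVE"]] / n, 1),
      pct_uncertain = round_half_up(100 * counts[["UNCERTAIN"]] / n, 1),
      pct_partial = round_half_up(100 * counts[["PARTIAL"]] / n, 1),
      pct_unsolved = round_half_up(100 * counts[["UNSOLVED"]] / n, 1)
    )
  }
  by_category <- NULL
  if ("category" %in% names(outcomes) && any(!is.na(outcomes$category))) {
    by_category <- outcomes |>
      dplyr::filter(!is.na(.data$category)) |>
      group_by(category = .data$category) |>
      dplyr::group_modify(~ summarise_block(.x)) |>
      ungroup()
  }
  structure(list(overall = summarise_block(outcomes), by_category = by_category),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  o <- x$overall
  cat(sprintf(
    "<cohort_summary> %d case(s): positive yield %.1f%%, combined (positive + uncertain) %.1f%%\n",
    o$n_cases, o$positive_yield, o$combined_yield))
  print(o)
  if (!is.null(x$by_category)) print(x$by_category)
  invisible(x)
}

#' Diagnostic rate of a reanalysis campaign
#'
#' Percentage of reanalysed (previously negative or inconclusive) cases
#' solved by the reanalysis, rounded half-up to the nearest integer.
#'
#' @param n_solved Cases solved by reanalysis.
#' @param n_reanalyzed Cases reanalysed (> 0, and at least `n_solved`).
#' @return Integer percentage.
#' @export
reanalysis_rate <- function(n_solved, n_reanalyzed) {
  if (n_reanalyzed <= 0) abort("n_reanalyzed must be positive")
  if (n_solved > n_reanalyzed) abort("n_solved cannot exceed n_reanalyzed")
  as.integer(round_half_up(100 * n_solved / n_reanalyzed, 0))
}

#' Aggregate filtering funnels across cases
#'
#' Per cascade stage, the mean/min/max variant count across cases, plus
#' the percentage reduction attributable to the virtual-panel stage (the
#' drop from raw to on-panel counts).
#'
#' @param reports List of `funnel_report` tibbles (all sharing the stage
#'   vocabulary) or a single report.
#' @return List with `stages` (tibble: `stage, mean, min, max`) and
#'   `panel_reduction_pct` (mean percent reduction at the panel stage).
#' @export
funnel_table <- function(reports) {
  if (inherits(reports, "funnel_report")) reports <- list(reports)
  if (length(reports) == 0L) abort("no funnel reports supplied")
  ref_stages <- reports[[1]]$stage
  purrr::walk(reports, function(r) {
    if (!identical(r$stage, ref_stages)) abort("funnel reports have mismatching stages")
  })
  counts <- vapply(reports, function(r) r$count, numeric(length(ref_stages)))
  counts <- matrix(counts, nrow = length(ref_stages))
  reductions <- vapply(reports, function(r) {
    raw <- r$count[r$stage == "raw"]; pan <- r$count[r$stage == "panel"]
    if (raw == 0) 0 else 100 * (raw - pan) / raw
  }, numeric(1))
  list(
    stages = tibble(
      stage = ref_stages,
      mean = rowMeans(counts),
      min = apply(counts, 1L, min),
      max = apply(counts, 1L, max)
    ),
    panel_reduction_pct = round_half_up(mean(reductions), 1)
  )
}

#' Render a per-case report document
#'
#' Fills a plain-text template with the case metadata, the candidate
#' table (HGVS strings passed through verbatim), CNV events, the outcome
#' label and a confirmation section listing every candidate flagged
#' `NEEDS_CONFIRMATION`. Unsolved cases render the negative-report
#' template. Output is deterministic: identical inputs give byte-identical
#' documents.
#'
#' @param case A [sample_case()].
#' @param candidates Ranked candidate tibble.
#' @param outcome A `case_outcome`.
#' @param events Optional CNV event tibble.
#' @param template Path to a template file with `{{FIELD}}` placeholders
#'   (`SAMPLE_ID`, `CATEGORY`, `OUTCOME`, `CANDIDATE_TABLE`,
#'   `CNV_TABLE`, `CONFIRMATION_SECTION`); defaults to the templates
#'   shipped with the package (`report_positive.txt` /
#'   `report_negative.txt`).
#' @return Character scalar, the rendered document.
#' @export
render_case_report <- function(case, candidates, outcome, events = NULL,
                               template = NULL) {
  if (is.null(template)) {
    name <- if (outcome$label == "UNSOLVED") "report_negative.txt" else "report_positive.txt"
    template <- system.file("templates", name, package = "raredx")
  }
  if (!nzchar(template) || !file.exists(template)) {
    abort(sprintf("report template not found: '%s'", template))
  }
  txt <- paste(readr::read_lines(template, progress = FALSE), collapse = "\n")

  cand_tab <- if (nrow(candidates) == 0L) "(no candidate variants)" else {
    hdr <- "rank\tgene\thgvs\tzygosity\tclass\tflags"
    rows <- sprintf("%d\t%s\t%s\t%s\t%s\t%s",
                    candidates$rank, candidates$gene,
                    ifelse(is.na(candidates$hgvs), variant_key(candidates), candidates$hgvs),
                    candidates$zygosity, candidates$clin_class, candidates$flags)
    paste(c(hdr, rows), collapse = "\n")
  }
  cnv_tab <- if (is.null(events) || nrow(events) == 0L) "(no CNV events)" else {
    paste(c("gene\ttype\tn_targets\tmean_dose",
            sprintf("%s\t%s\t%d\t%.3f", events$gene, events$type,
                    events$n_targets, events$mean_dose)),
          collapse = "\n")
  }
  needs <- candidates[has_flag(candidates$flags, "NEEDS_CONFIRMATION"), , drop = FALSE]
  confirm <- if (nrow(needs) == 0L) "(none)" else {
    paste(sprintf("- %s %s (depth %d): orthogonal confirmation required",
                  needs$gene,
                  ifelse(is.na(needs$hgvs), variant_key(needs), needs$hgvs),
                  needs$depth),
          collapse = "\n")
  }
  fill <- c(
    SAMPLE_ID = case$sample_id,
    CATEGORY = if (is.na(case$category)) "unspecified" else case$category,
    OUTCOME = outcome$label,
    CANDIDATE_TABLE = cand_tab,
    CNV_TABLE = cnv_tab,
    CONFIRMATION_SECTION = confirm
  )
  for (k in names(fill)) {
    txt <- gsub(paste0("{{", k, "}}"), fill[[k]], txt, fixed = TRUE)
  }
  txt
}

#' Write the candidate table of a case as TSV
#'
#' @param result A `case_prioritization`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(result, path) {
  cand <- result$candidates
  out <- tibble(
    rank = cand$rank, chrom = cand$chrom, pos = cand$pos, ref = cand$ref,
    alt = cand$alt, gene = cand$gene, zygosity = cand$zygosity,
    clin_class = cand$clin_class,
    max_maf = max_maf(cand), vaf = cand$vaf, depth = cand$depth,
    pairing = cand$pairing, flags = cand$flags
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a funnel report as TSV
#'
#' @param funnel A `funnel_report` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_funnel <- function(funnel, path) {
  readr::write_tsv(as_tibble(funnel), path, progress = FALSE)
  invisible(path)
}

#' Write a case outcome as JSON
#'
#' @param outcome A `case_outcome`.
#' @param case A [sample_case()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_outcome_json <- function(outcome, case, path) {
  payload <- list(
    sample_id = case$sample_id,
    mode = case$mode,
    label = outcome$label,
    supporting = if (nrow(outcome$supporting)) {
      tibble(
        key = variant_key(outcome$supporting),
        gene = outcome$supporting$gene,
        zygosity = outcome$supporting$zygosity,
        clin_class = outcome$supporting$clin_class
      )
    } else list()
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
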