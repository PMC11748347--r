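#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a case prioritization result
#'
#' @param x A `case_prioritization`.
#' @param ... Unused.
#' @return The ranked candidate tibble with a `sample_id` column.
#' @exportS3Method generics::tidy
tidy.case_prioritization <- function(x, ...) {
  out <- x$candidates
  out$sample_id <- x$case$sample_id
  relocate(out, "sample_id")
}

#' One-row summary of a case prioritization
#'
#' @param x A `case_prioritization`.
#' @param ... Unused.
#' @return One-row tibble: sample, per-stage funnel counts and the number
#'   of candidates flagged for confirmation.
#' @exportS3Method generics::glance
glance.case_prioritization <- function(x, ...) {
  counts <- setNames(as.list(x$funnel$count), paste0("n_", x$funnel$stage))
  dplyr::bind_cols(
    tibble(sample_id = x$case$sample_id),
    as_tibble(counts),
    tibble(n_needs_confirmation =
             sum(has_flag(x$candidates$flags, "NEEDS_CONFIRMATION")))
  )
}

#' Tidy a CNV calling result
#'
#' @param x A `cnv_result`.
#' @param ... Unused.
#' @return The event tibble.
#' @exportS3Method generics::tidy
tidy.cnv_result <- function(x, ...) x$events

#' One-row summary of a CNV calling result
#'
#' @param x A `cnv_result`.
#' @param ... Unused.
#' @return One-row tibble with event/target/mask tallies.
#' @exportS3Method generics::glance
glance.cnv_result <- function(x, ...) {
  tibble(
    n_samples = length(unique(x$target_calls$sample_id)),
    n_targets = nrow(dplyr::distinct(x$target_calls, .data$chrom, .data$start)),
    n_masked = sum(x$target_calls$state == "MASKED"),
    n_del_events = sum(x$events$type == "DEL"),
    n_dup_events = sum(x$events$type == "DUP")
  )
}

#' Tidy a pseudocontrol validation report
#'
#' @param x A `pseudocontrol_report`.
#' @param ... Unused.
#' @return The per-spike case tibble.
#' @exportS3Method generics::tidy
tidy.pseudocontrol_report <- function(x, ...) x$cases

#' One-row summary of a pseudocontrol validation report
#'
#' @param x A `pseudocontrol_report`.
#' @param ... Unused.
#' @return One-row tibble with spike counts and the recovery percentage.
#' @exportS3Method generics::glance
glance.pseudocontrol_report <- function(x, ...) {
  tibble(n_spiked = x$n_spiked, n_recovered = x$n_recovered,
         recovery_pct = x$recovery_pct)
}

#' Tidy a cohort summary
#'
#' @param x A `cohort_summary`.
#' @param ... Unused.
#' @return Per-category rows when available, else the overall row.
#' @exportS3Method generics::tidy
tidy.cohort_summary <- function(x, ...) {
  if (!is.null(x$by_category)) x$by_category else x$overall
}

#' @rdname tidy.cohort_summary
#' @exportS3Method generics::glance
glance.cohort_summary <- function(x, ...) x$overall

#' Plot a filtering funnel
#'
#' Bar chart of variant counts per cascade stage.
#'
#' @param object A `funnel_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.funnel_report <- function(object, ...) {
  df <- as_tibble(object)
  df$stage <- factor(df$stage, levels = df$stage)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), vjust = -0.4, size = 3) +
    ggplot2::labs(x = "filtering stage", y = "variants retained",
                  title = "Variant filtering funnel") +
    ggplot2::theme_minimal()
}

#' Plot per-target dose and z-scores of a CNV result
#'
#' Dose along the target index, coloured by call state, one facet per
#' sample; the deletion/duplication dose thresholds are drawn as dashed
#' lines.
#'
#' @param object A `cnv_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.cnv_result <- function(object, ...) {
  df <- object$target_calls
  df$index <- stats::ave(seq_len(nrow(df)), df$sample_id, FUN = seq_along)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$dose,
                                   colour = .data$state)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = c(object$params$dose_del_max,
                                       object$params$dose_dup_min),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(~sample_id) +
    ggplot2::labs(x = "target index", y = "gene dose",
                  title = "Per-target gene dose") +
    ggplot2::theme_minimal()
}

#' Plot cohort outcome composition
#'
#' Stacked outcome percentages, per category when available.
#'
#' @param object A `cohort_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.cohort_summary <- function(object, ...) {
  df <- if (!is.null(object$by_category)) object$by_category else
    dplyr::mutate(object$overall, category = "All")
  long <- tidyr::pivot_longer(
    dplyr::select(df, "category", dplyr::starts_with("pct_")),
    -"category", names_to = "outcome", values_to = "pct",
    names_prefix = "pct_"
  )
  long$outcome <- factor(long$outcome,
                         levels = c("positive", "uncertain", "partial", "unsolved"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$category, y = .data$pct,
                                     fill = .data$outcome)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of cases", title = "Diagnostic outcomes") +
    ggplot2::theme_minimal()
}
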