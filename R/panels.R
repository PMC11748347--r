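#' Load a library of virtual gene panels
#'
#' A virtual panel is a phenotype-specific gene list applied in silico to a
#' larger sequenced capture; each gene carries its disease inheritance
#' mode(s) and optional exception flags that relax downstream filters
#' (genes with variants previously reported pathogenic, hypomorphic
#' alleles, or incomplete penetrance / variable expressivity).
#'
#' The TSV layout is one row per (panel, gene):
#' `panel_id, panel_name, category, subcategory, gene, modes,
#' exception_flags` with `modes` / `exception_flags` semicolon-separated.
#' A JSON mirror (array of objects with the same fields) is accepted on a
#' `.json` extension. A gene listed twice within one panel is collapsed by
#' uniting its modes and flags, with a warning.
#'
#' @param path Path to a panel TSV or JSON file.
#' @return A `panel_library` tibble: one row per (panel, gene) with
#'   normalised semicolon-joined `modes` and `exception_flags`.
#' @export
load_panels <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- as_tibble(jsonlite::fromJSON(path))
  } else {
    raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
  assert_cols(raw, c("panel_id", "panel_name", "gene", "modes"), "panel file")
  if (!"category" %in% names(raw)) raw$category <- NA_character_
  if (!"subcategory" %in% names(raw)) raw$subcategory <- NA_character_
  if (!"exception_flags" %in% names(raw)) raw$exception_flags <- ""
  raw$exception_flags <- ifelse(is.na(raw$exception_flags), "", raw$exception_flags)

  modes_list <- split_tokens(toupper(raw$modes))
  purrr::iwalk(modes_list, function(m, i) {
    bad <- setdiff(m, mode_levels)
    if (length(bad) > 0) {
      abort(sprintf("unknown inheritance mode '%s' at panel row %d", bad[1], i))
    }
    if (length(m) == 0L) abort(sprintf("empty modes at panel row %d", i))
  })
  flags_list <- split_tokens(toupper(raw$exception_flags))
  purrr::iwalk(flags_list, function(f, i) {
    bad <- setdiff(f, exception_levels)
    if (length(bad) > 0) {
      abort(sprintf("unknown exception flag '%s' at panel row %d", bad[1], i))
    }
  })
  raw$modes <- join_tokens(modes_list)
  raw$exception_flags <- join_tokens(flags_list)
  raw$gene <- toupper(raw$gene)

  dup <- dplyr::count(raw, .data$panel_id, .data$gene) |> dplyr::filter(n > 1)
  if (nrow(dup) > 0) {
    warn(sprintf("%d duplicated (panel, gene) row(s) collapsed by uniting modes/flags",
                 nrow(dup)))
  }
  lib <- raw |>
    group_by(.data$panel_id, .data$panel_name, .data$category, .data$subcategory,
             .data$gene) |>
    summarise(
      modes = join_tokens(list(unlist(split_tokens(.data$modes)))),
      exception_flags = join_tokens(list(unlist(split_tokens(.data$exception_flags)))),
      .groups = "drop"
    ) |>
    arrange(match(.data$panel_id, unique(raw$panel_id)),
            match(.data$gene, unique(raw$gene)))
  structure(lib, class = c("panel_library", class(lib)))
}

#' Extract one panel from a library
#'
#' @param library A `panel_library` tibble from [load_panels()].
#' @param id Panel identifier.
#' @return A `virtual_panel` tibble (`gene, modes, exception_flags`) with
#'   `panel_id`, `panel_name` and `version` attributes.
#' @export
get_panel <- function(library, id) {
  rows <- dplyr::filter(library, .data$panel_id == id)
  if (nrow(rows) == 0L) abort(sprintf("unknown panel id '%s'", id))
  new_virtual_panel(
    dplyr::select(rows, "gene", "modes", "exception_flags"),
    id = id, name = rows$panel_name[1], version = "1"
  )
}

new_virtual_panel <- function(entries, id, name = id, version = "1") {
  if (anyDuplicated(entries$gene)) abort("gene symbols must be unique within a panel")
  p <- as_tibble(entries)
  attr(p, "panel_id") <- id
  attr(p, "panel_name") <- name
  attr(p, "version") <- version
  class(p) <- c("virtual_panel", class(tibble()))
  p
}

#' @export
print.virtual_panel <- function(x, ...) {
  cat(sprintf("<virtual_panel> %s (%s, v%s): %d gene(s)\n",
              attr(x, "panel_id"), attr(x, "panel_name"), attr(x, "version"), nrow(x)))
  NextMethod()
}

#' Merge several panels into one
#'
#' Supports ordering multiple panels for a single patient: gene sets are
#' united and, for genes shared between panels, inheritance modes and
#' exception flags are united too. The merged panel id is the sorted
#' `+`-joined concatenation of the input ids.
#'
#' @param library A `panel_library`.
#' @param ids Character vector of panel ids (all must exist).
#' @return A `virtual_panel`.
#' @export
merge_panels <- function(library, ids) {
  if (length(ids) == 0L) abort("at least one panel id is required")
  panels <- purrr::map(ids, function(id) get_panel(library, id))
  if (length(panels) == 1L) return(panels[[1]])
  entries <- dplyr::bind_rows(panels) |>
    group_by(.data$gene) |>
    summarise(
      modes = join_tokens(list(unlist(split_tokens(.data$modes)))),
      exception_flags = join_tokens(list(unlist(split_tokens(.data$exception_flags)))),
      .groups = "drop"
    ) |>
    arrange(.data$gene)
  merged_id <- paste(sort(ids), collapse = "+")
  new_virtual_panel(entries, id = merged_id, name = merged_id, version = "1")
}

#' Add custom genes to a panel
#'
#' Clinicians may extend a pre-defined panel with additional genes for a
#' single study. New genes are appended; genes already present have their
#' modes/flags united. The result's version gains a `+custom` suffix.
#'
#' @param panel A `virtual_panel`.
#' @param extra Tibble with `gene, modes, exception_flags` (semicolon
#'   separated, flags optional).
#' @return A `virtual_panel`.
#' @export
customize_panel <- function(panel, extra) {
  if (is.null(extra) || nrow(extra) == 0L) return(panel)
  assert_cols(extra, c("gene", "modes"), "extra genes")
  if (!"exception_flags" %in% names(extra)) extra$exception_flags <- ""
  extra$gene <- toupper(extra$gene)
  extra$modes <- join_tokens(split_tokens(toupper(extra$modes)))
  extra$exception_flags <- join_tokens(split_tokens(toupper(ifelse(
    is.na(extra$exception_flags), "", extra$exception_flags))))
  combined <- dplyr::bind_rows(
    tibble(gene = panel$gene, modes = panel$modes,
           exception_flags = panel$exception_flags, .ord = seq_len(nrow(panel))),
    tibble(gene = extra$gene, modes = extra$modes,
           exception_flags = extra$exception_flags,
           .ord = nrow(panel) + seq_len(nrow(extra)))
  ) |>
    group_by(.data$gene) |>
    summarise(
      modes = join_tokens(list(unlist(split_tokens(.data$modes)))),
      exception_flags = join_tokens(list(unlist(split_tokens(.data$exception_flags)))),
      .ord = min(.data$.ord), .groups = "drop"
    ) |>
    arrange(.data$.ord) |>
    dplyr::select(-".ord")
  new_virtual_panel(combined, id = attr(panel, "panel_id"),
                    name = attr(panel, "panel_name"),
                    version = paste0(attr(panel, "version"), "+custom"))
}

#' Restrict variants to a virtual panel
#'
#' The first and strongest filter of the prioritization cascade: only
#' variants in panel genes survive. Matching is by exact gene symbol,
#' case-insensitive; input order is preserved; retained variants gain
#' `panel_id`, `panel_modes` and `panel_exceptions` columns carrying the
#' gene's inheritance modes and exception flags.
#'
#' @param variants Variant tibble (needs a `gene` column).
#' @param panel A `virtual_panel`.
#' @return The on-panel subset of `variants`.
#' @export
apply_panel <- function(variants, panel) {
  assert_cols(variants, "gene", "variants")
  idx <- match(toupper(variants$gene), panel$gene)
  keep <- !is.na(idx)
  out <- variants[keep, , drop = FALSE]
  out$panel_id <- attr(panel, "panel_id") %||% NA_character_
  out$panel_modes <- panel$modes[idx[keep]]
  out$panel_exceptions <- panel$exception_flags[idx[keep]]
  as_tibble(out)
}
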