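#' Describe one sequenced case
#'
#' @param sample_id Sample identifier.
#' @param sex `"MALE"`, `"FEMALE"` or `"UNKNOWN"`.
#' @param category Clinical category label (free text).
#' @param panels Character vector of panel ids ordered for this case;
#'   required for diagnostic studies.
#' @param mode `"DIAGNOSTIC"` or `"CARRIER"`.
#' @return A `sample_case` list.
#' @export
sample_case <- function(sample_id, sex = "UNKNOWN", category = NA_character_,
                        panels = character(), mode = "DIAGNOSTIC") {
  mode <- match.arg(mode, c("DIAGNOSTIC", "CARRIER"))
  sex <- match.arg(sex, c("MALE", "FEMALE", "UNKNOWN"))
  if (mode == "DIAGNOSTIC" && length(panels) == 0L) {
    abort("diagnostic cases require at least one panel id")
  }
  structure(list(sample_id = sample_id, sex = sex, category = category,
                 panels = panels, mode = mode),
            class = "sample_case")
}

clin_rank <- function(clin_class, cip_has_plp) {
  r <- c(P = 1, LP = 2, CIP = 3, VUS = 4, NONE = 5, LB = 6, B = 7)[clin_class]
  unname(ifelse(clin_class == "CIP" & !(cip_has_plp %in% TRUE), r + 1.5, r))
}

deleterious_votes <- function(variants) {
  scols <- score_cols(variants)
  if (length(scols) == 0L) return(rep(0L, nrow(variants)))
  vocab <- c("deleterious", "damaging", "probably_damaging", "possibly_damaging",
             "pathogenic", "d")
  m <- as.matrix(variants[scols])
  apply(m, 1L, function(r) sum(tolower(trimws(as.character(r))) %in% vocab, na.rm = TRUE))
}

#' Order candidates deterministically
#'
#' Total order: clinical class (P > LP > CIP-with-P/LP > VUS > unclassified),
#' then smaller worst-case population frequency (absent frequency sorts as
#' rarest), then more deleterious in-silico predictor votes, then
#' chromosome/position lexicographically. A `rank` column (1..n) is
#' assigned. The ordering itself is a package convention: the filter
#' cascade defines what survives, not how survivors are listed.
#'
#' @param candidates Candidate variant tibble.
#' @return The same tibble, ordered, with a `rank` column.
#' @export
rank_candidates <- function(candidates) {
  if (nrow(candidates) == 0L) {
    candidates$rank <- integer()
    return(candidates)
  }
  ord <- order(
    clin_rank(candidates$clin_class, candidates$cip_has_plp),
    dplyr::coalesce(max_maf(candidates), 0),
    -deleterious_votes(candidates),
    norm_chrom(candidates$chrom),
    candidates$pos,
    candidates$ref,
    candidates$alt
  )
  out <- candidates[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out
}

funnel_stages <- c("raw", "panel", "frequency", "classification", "zygosity", "final")

new_funnel_report <- function(counts) {
  stopifnot(length(counts) == length(funnel_stages))
  structure(tibble(stage = funnel_stages, count = as.integer(counts)),
            class = c("funnel_report", class(tibble())))
}

#' Run the full prioritization cascade for one case
#'
#' Applies, in order: virtual-panel restriction (panels merged when the
#' case orders several), population-frequency filter, clinical
#' classification filter, inheritance-aware zygosity filter,
#' compound-heterozygote detection/phasing, and deterministic ranking.
#' Heterozygous variants retained solely as compound-het material are
#' dropped when trio phasing shows all their pairings in cis. Surviving
#' candidates with sequencing depth below `cfg$min_confirm_depth` (default
#' 20 reads) are flagged `NEEDS_CONFIRMATION` for orthogonal validation;
#' atypical allele fractions are flagged `VAF_OUTLIER`.
#'
#' @param case A [sample_case()].
#' @param variants Variant tibble for the case sample.
#' @param library A `panel_library`.
#' @param pedigree Optional `pedigree` (phasing and segregation input).
#' @param cfg A [filter_config()].
#' @return A `case_prioritization` object: list with `candidates` (ranked
#'   tibble with `pairing`/`pair_phase` columns), `funnel` (stage counts),
#'   `pairs` (compound-het pair table) and `case`.
#' @export
prioritize_case <- function(case, variants, library, pedigree = NULL,
                            cfg = filter_config()) {
  stopifnot(inherits(case, "sample_case"))
  panel <- merge_panels(library, case$panels)
  n_raw <- nrow(variants)

  v_panel <- apply_panel(variants, panel)
  v_freq <- filter_frequency(v_panel, cfg)
  v_class <- filter_classification(v_freq, cfg)
  v_zyg <- check_zygosity_consistency(v_class, sex = case$sex, cfg = cfg)

  pairs <- detect_compound_het(v_zyg, pedigree, case$sample_id)
  final <- resolve_comphet(v_zyg, pairs, sex = case$sex)
  final <- flag_vaf_outliers(final, cfg)
  final$flags <- add_flag(final$flags, "NEEDS_CONFIRMATION",
                          !is.na(final$depth) & final$depth < cfg$min_confirm_depth)
  final <- rank_candidates(final)

  funnel <- new_funnel_report(c(n_raw, nrow(v_panel), nrow(v_freq),
                                nrow(v_class), nrow(v_zyg), nrow(final)))
  structure(list(candidates = final, funnel = funnel,
                 pairs = pairs, case = case, config = cfg),
            class = "case_prioritization")
}

# Attach pairing info and drop hets whose only justification was a
# compound-het pairing now shown to be cis.
resolve_comphet <- function(v, pairs, sex = "UNKNOWN") {
  if (nrow(v) == 0L) {
    v$pairing <- character(); v$pair_phase <- character()
    return(v)
  }
  v$pairing <- NA_character_
  v$pair_phase <- NA_character_
  keys <- variant_key(v)
  usable <- pairs[pairs$phase != "CIS", , drop = FALSE]
  for (i in seq_len(nrow(v))) {
    mine <- usable[usable$var1 == keys[i] | usable$var2 == keys[i], , drop = FALSE]
    if (nrow(mine) == 0L) next
    # prefer a trans-confirmed pairing, then the partner of highest class
    mine <- mine[order(mine$phase != "TRANS"), , drop = FALSE]
    partner <- ifelse(mine$var1 == keys[i], mine$var2, mine$var1)
    pr <- clin_rank(v$clin_class[match(partner, keys)],
                    v$cip_has_plp[match(partner, keys)])
    best <- order(mine$phase != "TRANS", pr, partner)[1]
    v$pairing[i] <- partner[best]
    v$pair_phase[i] <- mine$phase[best]
  }
  v$flags <- add_flag(v$flags, "PHASE_UNKNOWN",
                      !is.na(v$pair_phase) & v$pair_phase == "UNKNOWN")

  # drop variants that depended on a (now cis) pairing
  need_pair <- vapply(seq_len(nrow(v)), function(i) {
    if (v$zygosity[i] != "HET") return(FALSE)
    if (is_plp(v$clin_class[i])) return(FALSE)
    if (has_exception(v$panel_exceptions[i])) return(FALSE)
    modes <- split_tokens(v$panel_modes[i])[[1]]
    if (any(modes %in% c("AD", "XLD"))) return(FALSE)
    if ("XLR" %in% modes && identical(sex, "MALE")) return(TRUE)
    TRUE
  }, logical(1))
  v[!need_pair | !is.na(v$pairing), , drop = FALSE]
}

#' Classify the genetic outcome of a case
#'
#' Assigns exactly one diagnostic label:
#' * `POSITIVE` — a genotype-complete pathogenic / likely pathogenic (P/LP)
#'   configuration exists: one P/LP variant under a dominant mode; a P/LP
#'   homozygote, or a compound-het pair with both halves P/LP (trans or
#'   unphased), under a recessive mode; hemizygous P/LP for X-linked
#'   recessive males.
#' * `UNCERTAIN` — a genotype-complete configuration exists but involves at
#'   least one variant of uncertain significance (or conflicting
#'   interpretation); phenotype compatibility is proxied by panel
#'   membership.
#' * `PARTIAL` — only a monoallelic P/LP heterozygote in an autosomal (or
#'   X-linked) recessive gene.
#' * `UNSOLVED` — none of the above.
#' * `CARRIER_FINDINGS` — carrier-mode cases with P/LP heterozygotes in
#'   recessive genes.
#'
#' @param candidates Ranked candidate tibble (segregation-inconsistent
#'   candidates already removed), or a `case_prioritization` object.
#' @param case A [sample_case()]; ignored when a `case_prioritization` is
#'   given.
#' @return A `case_outcome` list: `label` and `supporting` (candidate rows
#'   underpinning the label).
#' @export
classify_outcome <- function(candidates, case = NULL) {
  if (inherits(candidates, "case_prioritization")) {
    case <- candidates$case
    candidates <- candidates$candidates
  }
  stopifnot(inherits(case, "sample_case"))
  v <- candidates
  if (nrow(v) > 0) assert_cols(v, c("panel_modes", "clin_class", "zygosity"), "candidates")
  if (!"pairing" %in% names(v)) v$pairing <- rep(NA_character_, nrow(v))
  keys <- if (nrow(v)) variant_key(v) else character()
  modes <- split_tokens(if (nrow(v)) v$panel_modes else character())

  uncertainish <- function(cls, cip) cls == "VUS" | (cls == "CIP" & cip %in% TRUE)
  supportive <- function(cls, cip) is_plp(cls) | uncertainish(cls, cip)

  if (case$mode == "CARRIER") {
    idx <- which(v$zygosity == "HET" & is_plp(v$clin_class) &
                   vapply(modes, function(m) any(m %in% c("AR", "XLR")), logical(1)))
    label <- if (length(idx)) "CARRIER_FINDINGS" else "UNSOLVED"
    return(new_case_outcome(label, v[idx, , drop = FALSE]))
  }

  male <- identical(case$sex, "MALE")
  complete_plp <- integer(); complete_vus <- integer(); partial <- integer()

  for (i in seq_len(nrow(v))) {
    cls <- v$clin_class[i]; cip <- v$cip_has_plp[i]; z <- v$zygosity[i]
    if (!supportive(cls, cip)) next
    m <- modes[[i]]
    complete <- FALSE; involves_vus <- uncertainish(cls, cip)
    if (any(m == "AD") && z %in% c("HET", "HOM")) complete <- TRUE
    if (any(m == "XLD") && z %in% c("HET", "HOM", "HEM")) complete <- TRUE
    if (any(m == "AR") && z == "HOM") complete <- TRUE
    if (any(m == "XLR") && ((z == "HEM") || (z == "HOM" && !male))) complete <- TRUE
    if (any(m %in% c("AR", "XLR")) && z == "HET" && !is.na(v$pairing[i])) {
      j <- match(v$pairing[i], keys)
      if (!is.na(j) && supportive(v$clin_class[j], v$cip_has_plp[j])) {
        complete <- TRUE
        involves_vus <- involves_vus || uncertainish(v$clin_class[j], v$cip_has_plp[j])
      }
    }
    if (complete && !involves_vus && is_plp(cls)) complete_plp <- c(complete_plp, i)
    else if (complete) complete_vus <- c(complete_vus, i)
    if (!complete && z == "HET" && is_plp(cls) && any(m %in% c("AR", "XLR"))) {
      partial <- c(partial, i)
    }
  }

  if (length(complete_plp)) {
    sup <- with_partners(v, keys, complete_plp)
    return(new_case_outcome("POSITIVE", sup))
  }
  if (length(complete_vus)) {
    return(new_case_outcome("UNCERTAIN", with_partners(v, keys, complete_vus)))
  }
  if (length(partial)) {
    return(new_case_outcome("PARTIAL", v[partial, , drop = FALSE]))
  }
  new_case_outcome("UNSOLVED", v[0, , drop = FALSE])
}

with_partners <- function(v, keys, idx) {
  partners <- stats::na.omit(match(v$pairing[idx], keys))
  v[sort(unique(c(idx, partners))), , drop = FALSE]
}

new_case_outcome <- function(label, supporting) {
  structure(list(label = label, supporting = as_tibble(supporting)),
            class = "case_outcome")
}

#' @export
print.case_outcome <- function(x, ...) {
  cat(sprintf("<case_outcome> %s (%d supporting variant(s))\n",
              x$label, nrow(x$supporting)))
  invisible(x)
}

#' @export
print.case_prioritization <- function(x, ...) {
  cat(sprintf("<case_prioritization> sample %s: %d candidate(s)\n",
              x$case$sample_id, nrow(x$candidates)))
  print(x$funnel)
  invisible(x)
}
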