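#' Filter configuration for the prioritization cascade
#'
#' Thresholds for the sequential variant filters. Frequency ceilings are
#' per inheritance mode (dominant modes demand rarer variants than
#' recessive ones); the VAF band flags (never drops) variants whose allele
#' fraction is atypical for the called zygosity; candidates below
#' `min_confirm_depth` survive but are flagged for orthogonal (Sanger)
#' confirmation.
#'
#' @param maf_max Named numeric: maximum population allele frequency per
#'   mode (`AD`, `AR`, `XLD`, `XLR`), all in \[0,1\].
#' @param het_vaf_range Length-2 numeric: expected VAF band for
#'   heterozygous calls.
#' @param hom_vaf_min Minimum expected VAF for homozygous calls.
#' @param min_confirm_depth Depth (reads) below which a surviving candidate
#'   is flagged `NEEDS_CONFIRMATION`.
#' @param drop_classes Clinical classes removed outright.
#' @param keep_cip_only_with_plp Keep conflicting-interpretation (CIP)
#'   variants only when at least one submitter called them P/LP (the CIP
#'   dagger rule).
#' @return A `filter_config` list.
#' @export
filter_config <- function(maf_max = c(AD = 0.001, AR = 0.01, XLD = 0.001, XLR = 0.01),
                          het_vaf_range = c(0.3, 0.7),
                          hom_vaf_min = 0.8,
                          min_confirm_depth = 20L,
                          drop_classes = c("B", "LB"),
                          keep_cip_only_with_plp = TRUE) {
  stopifnot(
    all(mode_levels %in% names(maf_max)),
    all(maf_max >= 0 & maf_max <= 1),
    length(het_vaf_range) == 2L,
    het_vaf_range[1] >= 0, het_vaf_range[1] < het_vaf_range[2], het_vaf_range[2] <= 1,
    hom_vaf_min >= 0, hom_vaf_min <= 1,
    min_confirm_depth >= 0
  )
  structure(
    list(maf_max = maf_max, het_vaf_range = het_vaf_range,
         hom_vaf_min = hom_vaf_min, min_confirm_depth = as.integer(min_confirm_depth),
         drop_classes = drop_classes, keep_cip_only_with_plp = keep_cip_only_with_plp),
    class = "filter_config"
  )
}

# Largest frequency ceiling among a gene's panel modes; a variant passing
# under any one mode passes the stage.
mode_maf_ceiling <- function(panel_modes, maf_max) {
  vapply(split_tokens(panel_modes), function(m) {
    if (length(m) == 0L) return(max(maf_max))
    max(maf_max[m])
  }, numeric(1))
}

has_exception <- function(panel_exceptions) {
  lengths(split_tokens(panel_exceptions)) > 0L
}

#' Population-frequency filter
#'
#' Retains a variant when its worst (largest) population allele frequency
#' does not exceed the most permissive ceiling among its gene's inheritance
#' modes. Two escape hatches: genes carrying any exception flag (reported
#' pathogenic / hypomorphic / incomplete penetrance) bypass the ceiling,
#' and variants absent from every frequency source are kept but flagged
#' `NO_FREQUENCY_DATA` — a missing database record must not hide a
#' candidate.
#'
#' @param variants Panel-filtered variant tibble (needs `panel_modes`,
#'   `panel_exceptions`).
#' @param cfg A [filter_config()].
#' @return Filtered variant tibble.
#' @export
filter_frequency <- function(variants, cfg = filter_config()) {
  if (nrow(variants) == 0L) return(variants)
  assert_cols(variants, c("panel_modes", "panel_exceptions", "flags"), "variants")
  mm <- max_maf(variants)
  ceiling_ <- mode_maf_ceiling(variants$panel_modes, cfg$maf_max)
  no_data <- is.na(mm)
  keep <- no_data | (mm <= ceiling_) | has_exception(variants$panel_exceptions)
  out <- variants[keep, , drop = FALSE]
  out$flags <- add_flag(out$flags, "NO_FREQUENCY_DATA", no_data[keep])
  out
}

#' Clinical-classification filter
#'
#' Removes benign / likely benign variants. Variants with conflicting
#' interpretations of pathogenicity (CIP) are kept only when at least one
#' submitter classified them pathogenic or likely pathogenic; pathogenic,
#' likely pathogenic, uncertain and unclassified variants pass.
#'
#' @inheritParams filter_frequency
#' @return Filtered variant tibble.
#' @export
filter_classification <- function(variants, cfg = filter_config()) {
  if (nrow(variants) == 0L) return(variants)
  cls <- variants$clin_class
  keep <- !(cls %in% cfg$drop_classes)
  if (cfg$keep_cip_only_with_plp) {
    keep <- keep & (cls != "CIP" | variants$cip_has_plp %in% TRUE)
  }
  variants[keep, , drop = FALSE]
}

# A variant's class counts as likely causative for outcome logic.
is_plp <- function(clin_class) clin_class %in% c("P", "LP")

#' Inheritance-aware zygosity filter
#'
#' Drops variants whose genotype cannot produce disease under any
#' inheritance mode of their gene:
#' * `AD`: heterozygous or homozygous calls pass.
#' * `AR`: homozygous calls pass; a heterozygous call passes when the gene
#'   holds at least two surviving heterozygous variants (potential compound
#'   heterozygote) or when the variant itself is P/LP (kept and flagged
#'   `MONOALLELIC`, supporting a partial diagnosis).
#' * `XLR`: hemizygous males and homozygous females pass; female
#'   heterozygotes follow the AR compound-het/monoallelic rules.
#' * `XLD`: any non-reference genotype passes.
#'
#' Genes with exception flags bypass removal entirely. A hemizygous call in
#' a female sample is inconsistent data: the variant is kept but flagged
#' `SEX_GENOTYPE_CONFLICT` with a warning. VAF values outside the expected
#' band for the called zygosity add a `VAF_OUTLIER` flag (flag, not drop).
#'
#' @inheritParams filter_frequency
#' @param sex Sample sex, `"MALE"`, `"FEMALE"` or `"UNKNOWN"`.
#' @return Filtered variant tibble.
#' @export
check_zygosity_consistency <- function(variants, sex = "UNKNOWN", cfg = filter_config()) {
  if (nrow(variants) == 0L) return(variants)
  assert_cols(variants, c("panel_modes", "panel_exceptions", "zygosity", "gene"),
              "variants")
  v <- variants

  hem_female <- v$zygosity == "HEM" & rep(identical(sex, "FEMALE"), nrow(v))
  if (any(hem_female)) {
    warn(sprintf("%d hemizygous call(s) in a female sample; flagged", sum(hem_female)))
    v$flags <- add_flag(v$flags, "SEX_GENOTYPE_CONFLICT", hem_female)
  }

  het_n <- stats::ave(rep(1L, nrow(v)),
                      toupper(v$gene), v$zygosity == "HET",
                      FUN = sum)
  n_het_in_gene <- ifelse(v$zygosity == "HET", het_n, 0L)

  modes <- split_tokens(v$panel_modes)
  keep <- logical(nrow(v))
  mono <- logical(nrow(v))
  for (i in seq_len(nrow(v))) {
    z <- v$zygosity[i]
    plp <- is_plp(v$clin_class[i])
    ok <- FALSE; mono_i <- FALSE
    for (m in modes[[i]]) {
      if (m == "AD" && z %in% c("HET", "HOM")) ok <- TRUE
      if (m == "XLD" && z %in% c("HET", "HOM", "HEM")) ok <- TRUE
      if (m == "AR") {
        if (z == "HOM") ok <- TRUE
        else if (z == "HET" && n_het_in_gene[i] >= 2L) ok <- TRUE
        else if (z == "HET" && plp) { ok <- TRUE; mono_i <- TRUE }
      }
      if (m == "XLR") {
        male <- identical(sex, "MALE")
        if (z == "HEM" && (male || sex == "UNKNOWN")) ok <- TRUE
        if (z == "HOM" && !male) ok <- TRUE
        if (z == "HET" && !male) {
          if (n_het_in_gene[i] >= 2L) ok <- TRUE
          else if (plp) { ok <- TRUE; mono_i <- TRUE }
        }
      }
    }
    keep[i] <- ok
    mono[i] <- mono_i && !ok_without_mono(modes[[i]], z, n_het_in_gene[i], sex)
  }
  bypass <- has_exception(v$panel_exceptions)
  v$flags <- add_flag(v$flags, "MONOALLELIC", keep & mono)
  out <- v[keep | bypass, , drop = FALSE]
  out
}

# TRUE when the genotype already passes some mode without invoking the
# lone-P/LP monoallelic allowance (so the MONOALLELIC flag is not set).
ok_without_mono <- function(modes, z, n_het, sex) {
  for (m in modes) {
    if (m == "AD" && z %in% c("HET", "HOM")) return(TRUE)
    if (m == "XLD" && z %in% c("HET", "HOM", "HEM")) return(TRUE)
    if (m == "AR" && (z == "HOM" || (z == "HET" && n_het >= 2L))) return(TRUE)
    if (m == "XLR") {
      male <- identical(sex, "MALE")
      if (z == "HEM" && (male || sex == "UNKNOWN")) return(TRUE)
      if (z == "HOM" && !male) return(TRUE)
      if (z == "HET" && !male && n_het >= 2L) return(TRUE)
    }
  }
  FALSE
}

# VAF band check: flag, never drop.
flag_vaf_outliers <- function(variants, cfg = filter_config()) {
  if (nrow(variants) == 0L) return(variants)
  vaf <- variants$vaf
  out_of_band <- !is.na(vaf) & (
    (variants$zygosity == "HET" &
       (vaf < cfg$het_vaf_range[1] | vaf > cfg$het_vaf_range[2])) |
    (variants$zygosity %in% c("HOM", "HEM") & vaf < cfg$hom_vaf_min)
  )
  variants$flags <- add_flag(variants$flags, "VAF_OUTLIER", out_of_band)
  variants
}
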