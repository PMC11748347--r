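#' Propose and phase compound-heterozygote pairs
#'
#' Enumerates all unordered pairs of heterozygous variants within each
#' gene. When parental genotypes are available in the pedigree the pair is
#' phased: a pair is `TRANS` (confirmed compound heterozygote) when its
#' two alleles demonstrably come from different parents, `CIS` (removed
#' from candidacy) when one parent carries both alleles and the other
#' carries neither, and `UNKNOWN` otherwise (pair kept, flagged
#' `PHASE_UNKNOWN` — singleton cases dominate diagnostics).
#'
#' @param variants Variant tibble; only heterozygous rows are considered.
#' @param pedigree Optional `pedigree` with `genotypes` for the proband's
#'   parents.
#' @param proband Sample id of the index case within the pedigree.
#' @return Tibble of pairs: `gene, var1, var2, phase` with
#'   `var1 < var2` lexicographically (keys from [variant_key()]).
#' @export
detect_compound_het <- function(variants, pedigree = NULL, proband = NULL) {
  hets <- variants[variants$zygosity == "HET", , drop = FALSE]
  empty <- tibble(gene = character(), var1 = character(), var2 = character(),
                  phase = character())
  if (nrow(hets) < 2L) return(empty)
  hets$key <- variant_key(hets)
  pairs <- hets |>
    dplyr::distinct(.data$gene, .data$key) |>
    dplyr::group_by(gene_u = toupper(.data$gene)) |>
    dplyr::reframe(gene = .data$gene[1], pair = list_pairs(sort(.data$key))) |>
    tidyr::unnest_wider("pair")
  if (nrow(pairs) == 0L) return(empty)
  pairs <- dplyr::select(pairs, "gene", "var1", "var2")
  pairs$phase <- purrr::map2_chr(pairs$var1, pairs$var2, function(a, b) {
    phase_pair(a, b, pedigree, proband)
  })
  pairs
}

list_pairs <- function(keys) {
  if (length(keys) < 2L) return(list())
  idx <- utils::combn(length(keys), 2L)
  purrr::map(seq_len(ncol(idx)), function(j) {
    list(var1 = keys[idx[1, j]], var2 = keys[idx[2, j]])
  })
}

# Parental carrier status for one variant key: TRUE / FALSE / NA (untyped).
parent_carries <- function(pedigree, parent_id, key) {
  if (is.na(parent_id)) return(NA)
  g <- pedigree$genotypes
  rows <- g[g$sample_id == parent_id & g$var_id == key, , drop = FALSE]
  if (nrow(rows) == 0L) return(NA)
  any(rows$zygosity %in% c("HET", "HOM", "HEM"))
}

phase_pair <- function(key1, key2, pedigree, proband) {
  if (is.null(pedigree) || is.null(proband)) return("UNKNOWN")
  mem <- pedigree$members
  row <- mem[mem$sample_id == proband, , drop = FALSE]
  if (nrow(row) == 0L) return("UNKNOWN")
  f <- row$father_id[1]; m <- row$mother_id[1]
  f1 <- parent_carries(pedigree, f, key1); f2 <- parent_carries(pedigree, f, key2)
  m1 <- parent_carries(pedigree, m, key1); m2 <- parent_carries(pedigree, m, key2)
  if (anyNA(c(f1, f2, m1, m2))) return("UNKNOWN")
  # alleles demonstrably from different parents
  if ((f1 & !f2 & m2 & !m1) || (f2 & !f1 & m1 & !m2)) return("TRANS")
  # one parent transmits both, the other neither
  if ((f1 & f2 & !m1 & !m2) || (m1 & m2 & !f1 & !f2)) return("CIS")
  "UNKNOWN"
}

#' Check a candidate genotype against the family
#'
#' Segregation analysis discards candidates whose full causal genotype is
#' carried by an unaffected relative. Under the full-penetrance assumption
#' a dominant-acting candidate is inconsistent as soon as an unaffected
#' relative carries it; a recessive candidate is inconsistent only when an
#' unaffected relative carries the complete biallelic genotype (homozygous,
#' or both halves of a compound-het pair). Genes flagged
#' `INCOMPLETE_PENETRANCE` are exempt from the dominant rule. With no
#' genotyped relatives the test is `UNINFORMATIVE`.
#'
#' @param candidate One-row candidate tibble (needs `zygosity`,
#'   `panel_modes`, `panel_exceptions`, `pairing` and the variant key
#'   columns).
#' @param pedigree A `pedigree` with relative genotypes.
#' @param proband Index-case sample id.
#' @return `"CONSISTENT"`, `"INCONSISTENT"` or `"UNINFORMATIVE"`.
#' @export
check_segregation <- function(candidate, pedigree, proband) {
  stopifnot(nrow(candidate) == 1L)
  g <- pedigree$genotypes
  relatives <- setdiff(unique(g$sample_id), proband)
  if (length(relatives) == 0L) return("UNINFORMATIVE")
  key <- variant_key(candidate)
  modes <- split_tokens(candidate$panel_modes)[[1]]
  exceptions <- split_tokens(candidate$panel_exceptions)[[1]]
  mem <- pedigree$members
  unaffected <- mem$sample_id[!mem$affected & mem$sample_id %in% relatives]
  if (length(unaffected) == 0L) return("CONSISTENT")
  informative <- FALSE

  carries <- function(id, k, zyg = c("HET", "HOM", "HEM")) {
    rows <- g[g$sample_id == id & g$var_id == k, , drop = FALSE]
    if (nrow(rows) == 0L) return(NA)
    any(rows$zygosity %in% zyg)
  }

  dominant <- any(modes %in% c("AD", "XLD")) &&
    !"INCOMPLETE_PENETRANCE" %in% exceptions
  recessive <- any(modes %in% c("AR", "XLR"))
  pair_key <- if ("pairing" %in% names(candidate)) candidate$pairing[1] else NA_character_

  for (id in unaffected) {
    c1 <- carries(id, key)
    if (is.na(c1)) next
    informative <- TRUE
    if (dominant && c1) return("INCONSISTENT")
    if (recessive) {
      hom <- carries(id, key, c("HOM", "HEM"))
      if (isTRUE(hom) && candidate$zygosity[1] %in% c("HOM", "HEM")) return("INCONSISTENT")
      if (!is.na(pair_key) && nzchar(pair_key)) {
        c2 <- carries(id, pair_key)
        if (isTRUE(c1) && isTRUE(c2)) return("INCONSISTENT")
      }
    }
  }
  if (informative) "CONSISTENT" else "UNINFORMATIVE"
}
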