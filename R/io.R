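#' Read genotyped variants from a VCF with a sidecar annotation table
#'
#' Reads a VCF 4.2 file, decomposes genotyped records per ALT allele for one
#' sample, and joins clinical/population annotations from a tab-separated
#' sidecar keyed by `chrom,pos,ref,alt`. One row is emitted per ALT allele
#' carried by the sample (reference-only genotypes are skipped); a `1/2`
#' genotype therefore yields two heterozygous rows. Variants with no matching
#' annotation row are kept with `clin_class = "NONE"` and missing
#' frequencies; annotation rows matching no genotyped allele are counted and
#' reported via a message.
#'
#' @param vcf_path Path to a VCF 4.2 file (plain text or bgzipped).
#' @param ann_path Path to the annotation sidecar TSV (see
#'   [read_annotations()]), or `NULL` for no annotations.
#' @param sample_id Sample to extract; must be present in the VCF.
#' @return A variant tibble: `chrom, pos, ref, alt, gene, consequence,
#'   zygosity, vaf, depth, clin_class, cip_has_plp, hgvs, flags` plus any
#'   `maf_*` / `score_*` columns found in the sidecar.
#' @export
read_vcf_with_annotations <- function(vcf_path, ann_path = NULL, sample_id) {
  vcf <- tryCatch(
    vcfR::read.vcfR(vcf_path, verbose = FALSE),
    error = function(e) abort(sprintf("failed to parse VCF '%s': %s",
                                      vcf_path, conditionMessage(e)))
  )
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record VCFs drop to a vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  samples <- colnames(vcf@gt)[-1]
  if (!sample_id %in% samples) {
    abort(sprintf("sample '%s' not found in VCF (samples: %s)",
                  sample_id, paste(samples, collapse = ", ")))
  }
  if (nrow(fix) == 0L) return(annotate_variants(empty_variant_tbl(), ann_path))

  gt <- vcfR::extract.gt(vcf, element = "GT")[, sample_id]
  dp <- extract_fmt_num(vcf, "DP", sample_id)
  ad <- vcfR::extract.gt(vcf, element = "AD")[, sample_id]

  rows <- purrr::pmap(
    list(fix$CHROM, as.integer(fix$POS), fix$REF, fix$ALT, gt, dp, ad),
    decompose_record
  )
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) return(annotate_variants(empty_variant_tbl(), ann_path))
  annotate_variants(out, ann_path)
}

# One VCF record -> zero or more per-ALT rows for one sample.
decompose_record <- function(chrom, pos, ref, alt_field, gt, dp, ad) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(NULL)
  alts <- strsplit(alt_field, ",", fixed = TRUE)[[1]]
  alleles <- strsplit(gt, "[/|]")[[1]]
  alleles <- suppressWarnings(as.integer(alleles))
  alleles <- alleles[!is.na(alleles)]
  if (length(alleles) == 0L || all(alleles == 0L)) return(NULL)
  ploidy <- length(alleles)
  ads <- if (!is.na(ad)) suppressWarnings(as.numeric(strsplit(ad, ",", fixed = TRUE)[[1]])) else NULL
  alt_idx <- sort(unique(alleles[alleles > 0L]))
  purrr::map_dfr(alt_idx, function(i) {
    if (i > length(alts)) abort(sprintf("GT allele %d exceeds ALT count at %s:%d", i, chrom, pos))
    count <- sum(alleles == i)
    zyg <- if (ploidy == 1L) "HEM" else if (count >= 2L) "HOM" else "HET"
    vaf <- if (!is.null(ads) && length(ads) > i && sum(ads, na.rm = TRUE) > 0) {
      ads[i + 1L] / sum(ads, na.rm = TRUE)
    } else NA_real_
    tibble(
      chrom = chrom, pos = pos, ref = ref, alt = alts[i],
      zygosity = zyg, vaf = vaf,
      depth = if (is.na(dp)) NA_integer_ else as.integer(dp)
    )
  })
}

extract_fmt_num <- function(vcf, element, sample_id) {
  m <- tryCatch(vcfR::extract.gt(vcf, element = element, as.numeric = TRUE),
                error = function(e) NULL)
  if (is.null(m) || !sample_id %in% colnames(m)) {
    return(rep(NA_real_, nrow(vcf@fix)))
  }
  m[, sample_id]
}

empty_variant_tbl <- function() {
  tibble(
    chrom = character(), pos = integer(), ref = character(), alt = character(),
    zygosity = character(), vaf = numeric(), depth = integer()
  )
}

#' Read a variant annotation sidecar table
#'
#' Expected header: `chrom, pos, ref, alt, gene, consequence, clin_class,
#' cip_has_plp, hgvs` plus any number of `maf_<source>` (numeric, values in
#' \[0,1\]) and `score_<predictor>` (free-text label) columns.
#'
#' @param path Path to a TSV file.
#' @return Annotation tibble with a normalised `clin_class`.
#' @export
read_annotations <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_cols(ann, c("chrom", "pos", "ref", "alt", "gene"), "annotation table")
  if (!"clin_class" %in% names(ann)) ann$clin_class <- "NONE"
  ann$clin_class <- toupper(ifelse(is.na(ann$clin_class), "NONE", ann$clin_class))
  bad <- setdiff(unique(ann$clin_class), clin_levels)
  if (length(bad) > 0) {
    abort(sprintf("unknown clin_class value(s): %s", paste(bad, collapse = ", ")))
  }
  if (!"cip_has_plp" %in% names(ann)) ann$cip_has_plp <- FALSE
  ann$cip_has_plp <- as.logical(ann$cip_has_plp) %in% TRUE
  if (!"hgvs" %in% names(ann)) ann$hgvs <- NA_character_
  if (!"consequence" %in% names(ann)) ann$consequence <- NA_character_
  for (mc in maf_cols(ann)) {
    v <- ann[[mc]]
    if (any(!is.na(v) & (v < 0 | v > 1))) {
      abort(sprintf("column '%s' has allele frequencies outside [0,1]", mc))
    }
  }
  as_tibble(ann)
}

# Join sidecar annotations onto decomposed genotype rows.
annotate_variants <- function(gt_tbl, ann_path) {
  base <- gt_tbl
  base$key <- variant_key(base)
  if (is.null(ann_path)) {
    ann <- NULL
  } else {
    ann <- read_annotations(ann_path)
    ann$key <- variant_key(ann)
    n_unmatched <- sum(!ann$key %in% base$key)
    if (n_unmatched > 0) {
      inform(sprintf("%d annotation row(s) matched no genotyped allele; ignored",
                     n_unmatched))
    }
    ann <- dplyr::select(ann, -"chrom", -"pos", -"ref", -"alt")
  }
  if (!is.null(ann)) {
    out <- dplyr::left_join(base, ann, by = "key")
  } else {
    out <- base
  }
  if (!"gene" %in% names(out)) out$gene <- NA_character_
  if (!"consequence" %in% names(out)) out$consequence <- NA_character_
  if (!"clin_class" %in% names(out)) out$clin_class <- NA_character_
  if (!"cip_has_plp" %in% names(out)) out$cip_has_plp <- FALSE
  if (!"hgvs" %in% names(out)) out$hgvs <- NA_character_
  out$clin_class <- ifelse(is.na(out$clin_class), "NONE", out$clin_class)
  out$cip_has_plp <- out$cip_has_plp %in% TRUE
  out$flags <- ""
  dplyr::select(out, -"key") |>
    relocate(any_of(variant_core_cols)) |>
    as_tibble()
}

#' Read target regions from a BED file
#'
#' BED coordinates (0-based, half-open) are converted to the package's
#' 1-based inclusive convention: `start = BED start + 1`, `end = BED end`.
#' Input order is preserved and overlapping intervals are not merged.
#'
#' @param path Path to a BED3+ file (4th column, when present, becomes the
#'   interval label).
#' @return Tibble with `chrom, start, end, label`.
#' @export
read_bed_targets <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")]
  if (length(lines) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  label = character()))
  }
  parts <- strsplit(lines, "\t| +")
  purrr::imap_dfr(parts, function(p, i) {
    if (length(p) < 3L) abort(sprintf("BED line %d has fewer than 3 fields", i))
    s0 <- suppressWarnings(as.integer(p[2])); e0 <- suppressWarnings(as.integer(p[3]))
    if (is.na(s0) || is.na(e0)) abort(sprintf("BED line %d has non-numeric coordinates", i))
    if (e0 <= s0) abort(sprintf("BED line %d: end (%d) must exceed start (%d)", i, e0, s0))
    tibble(chrom = p[1], start = s0 + 1L, end = e0,
           label = if (length(p) >= 4L) p[4] else NA_character_)
  })
}

#' Write target intervals as BED
#'
#' Inverse of [read_bed_targets()]: 1-based inclusive intervals become
#' 0-based half-open lines.
#'
#' @param targets Tibble with `chrom, start, end` and optional `label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed_targets <- function(targets, path) {
  assert_cols(targets, c("chrom", "start", "end"), "targets")
  lab <- if ("label" %in% names(targets)) targets$label else rep(NA, nrow(targets))
  lines <- ifelse(
    is.na(lab),
    sprintf("%s\t%d\t%d", targets$chrom, targets$start - 1L, targets$end),
    sprintf("%s\t%d\t%d\t%s", targets$chrom, targets$start - 1L, targets$end, lab)
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a 6-column PED pedigree file
#'
#' Columns: family, individual, father, mother, sex (1 = male, 2 = female,
#' other = unknown), phenotype (2 = affected, 1 = unaffected, other =
#' unknown). Unknown parents (`0`) are stored as `NA`. Parent identifiers
#' must reference individuals present in the file.
#'
#' @param path Path to a whitespace-delimited PED file.
#' @return A `pedigree` object: list with a `members` tibble
#'   (`sample_id, father_id, mother_id, sex, affected`) and an initially
#'   empty `genotypes` tibble (`sample_id, var_id, zygosity`); populate the
#'   latter with [set_pedigree_genotypes()].
#' @export
read_ped <- function(path) {
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 6L) abort("PED file must have 6 columns")
  members <- tibble(
    sample_id = as.character(raw[[2]]),
    father_id = ifelse(raw[[3]] %in% c("0", 0), NA_character_, as.character(raw[[3]])),
    mother_id = ifelse(raw[[4]] %in% c("0", 0), NA_character_, as.character(raw[[4]])),
    sex = unname(c("1" = "MALE", "2" = "FEMALE")[as.character(raw[[5]])]),
    affected = raw[[6]] %in% c(2, "2")
  )
  members$sex <- ifelse(is.na(members$sex), "UNKNOWN", members$sex)
  new_pedigree(members)
}

#' Construct a pedigree from a members table
#'
#' @param members Tibble with `sample_id, father_id, mother_id, sex,
#'   affected`.
#' @param genotypes Optional tibble with `sample_id, var_id, zygosity`
#'   (`var_id` as produced by [variant_key()]; `zygosity` in
#'   `HET/HOM/HEM/REF`).
#' @return A `pedigree` object.
#' @export
new_pedigree <- function(members, genotypes = NULL) {
  if (anyDuplicated(members$sample_id)) {
    dup <- members$sample_id[duplicated(members$sample_id)]
    abort(sprintf("duplicate sample id(s) in pedigree: %s", paste(unique(dup), collapse = ", ")))
  }
  for (col in c("father_id", "mother_id")) {
    dangling <- setdiff(stats::na.omit(members[[col]]), members$sample_id)
    if (length(dangling) > 0) {
      abort(sprintf("%s value(s) not present as members: %s",
                    col, paste(dangling, collapse = ", ")))
    }
  }
  check_no_ancestry_cycle(members)
  ped <- list(
    members = as_tibble(members),
    genotypes = genotypes %||%
      tibble(sample_id = character(), var_id = character(), zygosity = character())
  )
  structure(ped, class = "pedigree")
}

check_no_ancestry_cycle <- function(members) {
  parent_of <- setNames(
    purrr::map2(members$father_id, members$mother_id, ~ stats::na.omit(c(.x, .y))),
    members$sample_id
  )
  for (id in members$sample_id) {
    seen <- character()
    frontier <- parent_of[[id]]
    while (length(frontier) > 0) {
      if (id %in% frontier) abort(sprintf("member '%s' is its own ancestor", id))
      seen <- union(seen, frontier)
      frontier <- setdiff(unique(unlist(parent_of[frontier])), seen)
    }
  }
  invisible(members)
}

#' Attach per-member variant genotypes to a pedigree
#'
#' @param ped A `pedigree` object.
#' @param genotypes Tibble with `sample_id, var_id, zygosity`.
#' @return The pedigree with genotypes replaced.
#' @export
set_pedigree_genotypes <- function(ped, genotypes) {
  stopifnot(inherits(ped, "pedigree"))
  assert_cols(genotypes, c("sample_id", "var_id", "zygosity"), "genotypes")
  unknown <- setdiff(unique(genotypes$sample_id), ped$members$sample_id)
  if (length(unknown) > 0) {
    abort(sprintf("genotypes reference unknown member(s): %s", paste(unknown, collapse = ", ")))
  }
  ped$genotypes <- as_tibble(genotypes)
  ped
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("<pedigree> %d member(s), %d genotype record(s)\n",
              nrow(x$members), nrow(x$genotypes)))
  print(x$members)
  invisible(x)
}

#' Read a per-target depth table
#'
#' Expected TSV layout: `chrom, start, end, gene` (1-based inclusive
#' coordinates) followed by one numeric column per sample, rows in capture
#' order.
#'
#' @param path Path to the TSV.
#' @return A coverage tibble (targets x samples in wide form).
#' @export
read_depth_table <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  probs <- readr::problems(m)
  if (nrow(probs) > 0) {
    abort(sprintf("malformed depth table at line %d: %s", probs$row[1] + 1L, probs$expected[1]))
  }
  assert_cols(m, c("chrom", "start", "end", "gene"), "depth table")
  validate_coverage(m)
}

validate_coverage <- function(m) {
  scols <- coverage_sample_cols(m)
  if (length(scols) == 0L) abort("depth table has no sample columns")
  for (sc in scols) {
    if (!is.numeric(m[[sc]])) abort(sprintf("sample column '%s' is not numeric", sc))
    if (any(is.na(m[[sc]]))) abort(sprintf("sample column '%s' has missing depths", sc))
    if (any(m[[sc]] < 0)) abort(sprintf("sample column '%s' has negative depths", sc))
  }
  as_tibble(m)
}

coverage_sample_cols <- function(m) setdiff(names(m), c("chrom", "start", "end", "gene"))

#' Write a per-target depth table
#'
#' @param m Coverage tibble as returned by [read_depth_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth_table <- function(m, path) {
  readr::write_tsv(m, path, progress = FALSE)
  invisible(path)
}

#' Read a qPCR cycle-threshold table
#'
#' CSV with columns `sample_id, assay_id, role, calibrator, replicate, ct`;
#' `role` is `TARGET` (assay over the region under test) or `REFERENCE`
#' (normalising assay), `calibrator` marks the unaffected control samples
#' the comparative-Ct method normalises against.
#'
#' @param path Path to the CSV.
#' @return Validated Ct tibble.
#' @export
read_ct_table <- function(path) {
  ct <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  assert_cols(ct, c("sample_id", "assay_id", "role", "calibrator", "replicate", "ct"),
              "Ct table")
  ct$role <- toupper(ct$role)
  bad <- setdiff(unique(ct$role), c("TARGET", "REFERENCE"))
  if (length(bad) > 0) abort(sprintf("unknown Ct role(s): %s", paste(bad, collapse = ", ")))
  ct$calibrator <- as.logical(ct$calibrator) %in% TRUE
  if (!any(ct$calibrator)) abort("Ct table has no calibrator sample")
  as_tibble(ct)
}

#' Write a variant table as VCF 4.2 plus annotation sidecar
#'
#' Emits the two files the prioritization readers consume: a minimal VCF
#' (GT:DP FORMAT for a single sample) and the `chrom,pos,ref,alt,...`
#' annotation TSV. Used by the simulator and the command line `simulate`
#' subcommand.
#'
#' @param variants Variant tibble (one row per ALT allele).
#' @param sample_id Sample name written to the VCF header.
#' @param vcf_path,ann_path Output paths.
#' @return Invisibly, a list with both paths.
#' @export
write_variant_vcf <- function(variants, sample_id, vcf_path, ann_path) {
  v <- dplyr::arrange(variants, .data$chrom, .data$pos, .data$ref, .data$alt)
  gt <- c(HET = "0/1", HOM = "1/1", HEM = "1")[v$zygosity]
  dp <- ifelse(is.na(v$depth), ".", as.character(v$depth))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample_id)
  )
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:DP\t%s:%s",
                  v$chrom, v$pos, v$ref, v$alt, gt, dp)
  readr::write_lines(c(header, body), vcf_path)
  ann <- dplyr::select(v, any_of(c("chrom", "pos", "ref", "alt", "gene", "consequence",
                                   "clin_class", "cip_has_plp", "hgvs")),
                       dplyr::starts_with("maf_"), dplyr::starts_with("score_"))
  readr::write_tsv(ann, ann_path, progress = FALSE)
  invisible(list(vcf = vcf_path, annotations = ann_path))
}
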