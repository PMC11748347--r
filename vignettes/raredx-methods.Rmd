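---
title: "raredx: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{raredx: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raredx)
```

This vignette is the package's account of the science it implements: the
variant-prioritization cascade, the gene-dose CNV caller, the qPCR
confirmation arithmetic and the coverage QC — what each assumes, which
parameters matter, and where the design was genuinely open.

## The prioritization cascade

A diagnostic case is analysed against a *virtual panel*: a gene list with
per-gene inheritance modes (`AD`, `AR`, `XLD`, `XLR`) and optional
exception flags. The cascade applies, in order: panel restriction,
population-frequency ceiling, clinical-classification triage,
inheritance-aware zygosity logic, compound-het phasing, and ranking. The
first four filters are pure per-variant (or per-gene-context) predicates, so
their composition equals the intersection of their keep-sets and their order
only affects the funnel bookkeeping, not the survivors; the compound-het
step is the one non-local stage and is tested separately against
brute-force pair enumeration.

### Frequency ceilings

A variant passes when its **worst** (largest) allele frequency over all
annotated population sources is at most the most permissive ceiling among
its gene's modes:

| mode | default ceiling |
|------|-----------------|
| AD, XLD | 0.001 |
| AR, XLR | 0.01 |

These are fractions of alleles in a reference population. Dominant
pathologies require rarer alleles than recessive ones because carriers are
affected; both defaults are the values commonly used in dominant/recessive
rare-disease triage and are configurable in `filter_config()`. Two escape
hatches reflect clinical practice: genes flagged `KNOWN_PATHOGENIC`,
`HYPOMORPHIC` or `INCOMPLETE_PENETRANCE` bypass the ceiling (pathogenic
founder alleles and hypomorphs can be "too common"), and variants missing
from every frequency source are **kept** and flagged
`NO_FREQUENCY_DATA` — an absent database record must never hide a
candidate.

### Classification triage

ACMG/AMP classes `B` and `LB` are removed. Variants with conflicting
interpretations of pathogenicity (`CIP`) are kept only when at least one
submitter classified them P/LP; this keeps genuinely contested variants
reviewable while discarding conflicts among benign-leaning submissions.
`P`, `LP`, `VUS` and unclassified (`NONE`) variants pass — classification
here is an *input label* from upstream interpretation engines, not
something the package computes.

### Zygosity versus inheritance

For each gene the surviving genotypes must be able to produce disease under
at least one mode: dominant modes accept any non-reference genotype;
recessive modes require biallelic evidence — a homozygote, or at least two
heterozygous variants in the gene (candidate compound heterozygote). A lone
heterozygous **P/LP** variant in a recessive gene survives with a
`MONOALLELIC` flag: it cannot complete a diagnosis but supports a *partial*
one, and in carrier-mode studies it is the finding of interest. X-linked
logic keys on sample sex (hemizygous males, compound-het logic for females
only); a hemizygous call in a female sample is a data inconsistency and is
flagged `SEX_GENOTYPE_CONFLICT` rather than silently dropped.

Variant allele fraction is used as a *flag*, not a filter: heterozygous
calls outside [0.3, 0.7] and homozygous calls below 0.8 gain `VAF_OUTLIER`.
Dropping on VAF would silently discard mosaic and capture-biased sites;
flagging keeps the geneticist in the loop.

### Compound-het phasing

All unordered within-gene pairs of heterozygous survivors are proposed.
With parental genotypes, a pair is *trans* (confirmed) when each allele is
demonstrably carried by a different parent, *cis* (removed from candidacy)
when one parent carries both and the other neither, and unknown otherwise.
Unphased pairs are kept, flagged `PHASE_UNKNOWN`, and may support a
positive outcome: singleton cases dominate diagnostic practice, and
requiring trio phasing would misclassify most true compound heterozygotes
as unsolved. This leniency is deliberate and documented in the report
flags.

### Ranking and confirmation

The filters define *what* survives; the ordering is a package convention:
clinical class (P ▸ LP ▸ CIP-with-P/LP ▸ VUS ▸ unclassified), then smaller
worst-case frequency (absent frequency ranks as rarest), then more
deleterious in-silico predictor votes, then genomic position as a
deterministic tie-break. Survivors with sequencing depth below
`min_confirm_depth` (default 20 reads) are flagged `NEEDS_CONFIRMATION`;
the per-case report renders them in a dedicated confirmation section.

### Segregation and outcomes

`check_segregation()` discards candidates whose full causal genotype is
carried by an unaffected relative: any carrier relative contradicts a
dominant candidate (full-penetrance assumption, waived for genes flagged
`INCOMPLETE_PENETRANCE`), while recessive candidates are contradicted only
by an unaffected relative carrying the complete biallelic genotype. With no
genotyped relatives the result is `UNINFORMATIVE` — segregation is an
optional refinement, not a gate.

Outcome labels partition cases: `POSITIVE` needs a genotype-complete P/LP
configuration; `UNCERTAIN` a complete configuration involving at least one
VUS (or CIP-with-P/LP); `PARTIAL` exactly a monoallelic P/LP het in a
recessive gene; otherwise `UNSOLVED`. "VUS compatible with the phenotype"
is operationalised as *VUS in an on-panel gene* — the panel is the
phenotype proxy; free-text phenotype matching is out of scope. A
consequence worth knowing: `POSITIVE` can never rest on VUS-only support.

## The gene-dose CNV caller

Input is a batch matrix of mean depths, targets × samples. The model is
multiplicative: `depth(t, s) ≈ baseline(t) · size(s) · noise`, so each
sample column is first divided by its own **median** target depth. Median
(not mean, not on-target total) was chosen because a handful of CNV or
failed targets should not shift a sample's normaliser; the alternative
normalisers would be legitimate and the choice is isolated in
`normalize_matrix()`.

For a test sample, every other batch sample forms the reference: per-target
mean and standard deviation are computed with the test sample held out. No
outlier-sample pruning is applied beyond the per-target mask — the simplest
defensible baseline, explicitly designed for replacement. Targets with
reference mean relative depth < 0.1 or coefficient of variation > 0.3 are
**masked**: they cannot support a reliable dose estimate.

Calling requires **both** criteria (`cnv_params()` defaults):

* deletion: `dose ≤ 0.7` **and** `z ≤ −2.5`;
* duplication: `dose ≥ 1.3` **and** `z ≥ 2.5`;

with `z = (rel − mean) / max(sd, 0.05)`. The 0.05 relative-depth floor
prevents infinite z on degenerate (near-identical) references. The dose
thresholds sit roughly midway between the diploid expectation (1.0) and the
single-copy expectations (0.5 and 1.5); the conjunction suppresses calls on
targets whose dose excursion is large but within their own noise. These
cutoffs are explicit stand-ins calibrated on synthetic data — the
operating point they are designed for is per-target CV up to ~8–10% after
normalisation (a well-behaved capture batch). The arithmetic is worth
stating: a duplication threshold of 1.3 is a 3.7σ excursion at 8% CV but
only 2σ at 15% CV, so in noisier batches the defaults will both miss real
single-copy changes and admit false duplications; recalibrate
`cnv_params()` against known-CNV samples for such batches, as one would
against an MLPA-confirmed truth set.

Consecutively called targets of the same type within one gene merge into a
single event (a neutral or masked target breaks the run — no bridging);
`min_targets` (default 1) lets a laboratory demand multi-exon support.

### Comparative-Ct confirmation

`ddct_fold_change()` implements the pure 2^−ΔΔCt method: technical
replicates are averaged per assay (arithmetic mean, no efficiency
correction), ΔCt = Ct(target assay) − Ct(reference assay) within each
sample, ΔΔCt subtracts the mean ΔCt of the calibrator (negative control)
samples, and the fold change is 2^−ΔΔCt. The identities
`ΔΔCt = 0 → 1`, `+1 → 0.5`, `−1 → 2` and the reciprocal symmetry
`f(x)·f(−x) = 1` hold exactly and are asserted in the tests.

## Coverage QC

* **Fold-80 base penalty** = mean per-base depth / 20th percentile of
  per-base depth. The percentile uses linear interpolation between closest
  ranks (R quantile type 7) so the statistic is bit-reproducible; 1 means
  perfectly uniform coverage, and the value is undefined (`NA`, flagged)
  when ≥ 20% of bases have zero depth.
* **Coverage fractions**: share of bases at ≥ 20× and ≥ 30× (thresholds
  configurable).
* **Commonly uncovered exons**: an exon counts as poorly covered in a
  sample when < 50% of its bases reach 20×; it is flagged for the batch
  when that holds in ≥ 95% of samples (strict `<` on coverage, `≥` on the
  sample proportion — the 19/20 vs 18/20 boundary is tested). The 20×
  floor for "covered" is an interpretation, surfaced as the `min_depth`
  argument, since only the 50%/95% pair is fixed by the rule.

## Synthetic study conditions

The generators in `sim_config()` define the conditions everything is tested
under: an invented genome of 400 genes (1–10 exons each, one gene in 23 on
chrX), 300 background variants per case with a clinical-class mix dominated
by benign/VUS calls (P 1%, LP 2%, VUS 30%, CIP 5%, LB 20%, B 32%, NONE
10%), log-uniform allele frequencies on [10⁻⁶, 0.5] with 10% of variants
absent from all sources, sequencing depth Poisson around 200×, and coverage
matrices with lognormal multiplicative noise (σ = 0.08 by default, the CNV
caller's calibrated operating point). Lognormal noise was preferred over
negative binomial because planted CNV doses act exactly multiplicatively,
giving closed-form truth. Genes carrying planted genotypes hold only those
genotypes, so spike recovery (or an engineered miss) never depends on
incidental background in the same gene.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: linkage structure and founder haplotypes,
annotation errors and gene-symbol drift, mosaicism, segmental-duplication
cross-mapping, GC-dependent depth waves that correlate across targets, and
batch effects beyond a scalar library-size factor. The pseudocontrol
harness validates the *logic* of the cascade, not the upstream calling or
annotation.

Truth manifests are first-class outputs (TSV), so validation never
re-derives truth from generator internals. All generators are
byte-deterministic under a fixed seed; per-case sub-seeds are derived with
a fixed integer recurrence so independent draws stay independent.

## Numerical conventions and degenerate inputs

* Coordinates are 1-based inclusive internally (VCF convention); BED is
  converted at the boundary and round-trips exactly.
* Chromosome matching strips an optional `chr` prefix, then compares
  exactly; gene matching is case-insensitive symbol equality (no alias
  resolution — alias tables are an external database dependency).
* Multiallelic records are decomposed per ALT allele; indels are kept as
  written (normalisation is upstream's job).
* Percentages round half-up: yields to one decimal, reanalysis rates to
  integers. Base R's round-half-even would differ on exact .05 boundaries.
* Ties in ranking break on genomic position; re-running yields identical
  order.
* Empty inputs: empty panels, zero-row variant tables and zero-spike
  configurations flow through every stage and produce empty, correctly
  typed outputs; zero-depth samples, inconsistent read counts and dangling
  pedigree references abort with named errors.

## Problem sizes

The test suite and `scripts/acceptance.R` run at sizes chosen to exercise
the statistics while staying desk-scale: 1,000 seeded cases for funnel
monotonicity, 200 seeded matrices (20 targets × 8 samples) for CNV
sensitivity/false-positive rates, 30 pseudocontrol cases plus four
5-case engineered-violation batches, and brute-force comparisons up to 6
heterozygotes per gene. Cohort-yield arithmetic uses the published
worked-example counts (1497 and 564 + 1497 of 6267; 11 of 90) directly.

## Known limitations

CNV calls are reported separately from the SNV funnel (whether they should
enter it is a workflow policy, not a modelling question). The caller has no
breakpoint resolution and no allele-frequency-informed genotyping. The
outcome classifier trusts upstream ACMG labels; it performs no evidence
scoring. Panels carry no genomic coordinates — region-level operations use
the capture BED. EMQN-style sensitivity/precision scoring against a truth
VCF, HPO-driven panel suggestion and report/EHR integration are out of
scope.
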