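---
title: "Extended annotation and relevance scoring of coding variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extended annotation and relevance scoring of coding variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evanno)
```

## The problem

Whole-exome variant callers such as GATK's UnifiedGenotyper and MuTect
produce technically excellent but biologically opaque output: a VCF or a
call-stats table says nothing about which gene a variant hits, whether it
changes protein sequence, how rare it is, or whether the gene is plausibly
connected to the disease under study. `evanno` post-processes such call
sets into a ranked, filterable short-list. It was designed around the study
design of a related-sample comparison — e.g. a monozygotic twin pair in
which purified T-cells serve as controls and mononuclear cells as targets —
where no true matched normal exists and "germline" must be approximated as
the intersection of calls across related samples (the *pseudo-germline*
set).

The workflow is deliberately descriptive and integrative rather than
inferential: with one or a few exomes, there is no sampling distribution to
test against, and the aim is a transparent, reproducible prioritization
that a clinician-scientist can inspect channel by channel.

## Pipeline stages

1. **Gene annotation.** Variants are mapped to gene models loaded from a
   GenePred table. A variant maps to a gene when its position falls inside
   any transcript span `[tx_start, tx_end)`; UTRs and introns count,
   strand does not. Mapping is therefore a pure interval query, and the
   implementation (GenomicRanges overlap) is required by the test suite to
   be observationally identical to a brute-force scan over every
   transcript.
2. **Coding selection.** A mapped variant is *coding* when, for at least
   one transcript, it lies both inside the CDS interval and inside an
   exon. This two-stage narrowing (mapped, then coding) keeps intergenic
   and intragenic-noncoding variants available for inspection instead of
   silently discarding them.
3. **Pseudo-germline intersection.** `intersect_variants()` matches on the
   full variant key (chromosome, position, reference, alternate) and
   ignores sample labels and zygosity: two related samples share a
   germline allele even if one carries it heterozygously and the other
   homozygously.
4. **Pileup export.** Coding variants are written as 4-column
   chromosome/position/reference/alternate lines for upload to the Variant
   Effect Predictor. The explicit-allele form is lossless, unlike IUPAC
   consensus codes; zygosity is deliberately *not* encoded because it is
   rejoined later from the call set itself.
5. **Enrichment.** VEP's default tabular output (run with SIFT/PolyPhen
   *scores*, not categorical predictions) is parsed, aggregated per
   (variant, gene), and joined back to the calls together with the local
   per-gene evidence tables. Amino-acid substitutions are additionally
   classified by side-chain polarity change.
6. **Scoring and ranking.** Eight evidence channels are combined into a
   weighted additive score (next section).
7. **Reporting.** A threshold filter produces the result table; genes of
   retained variants are summarized as a mean-normalized tissue expression
   matrix and rendered as TSV and a static HTML report.

## The composite score

For an enriched variant with VEP annotation and gene evidence, the
components are:

| channel           | value                                                        | range   |
|-------------------|--------------------------------------------------------------|---------|
| rarity            | absent GMAF → 1; else `clamp((g_max − GMAF)/g_max, 0, 1)`    | [0, 1]  |
| sift_damage       | 1 if SIFT present and ≤ 0.05, else 0                         | {0, 1}  |
| polyphen_damage   | the PolyPhen-2 probability itself (0 when absent)            | [0, 1]  |
| literature        | `log10(1 + n)` over MeSH-scoped PubMed counts                | ≥ 0     |
| cosmic            | `min(entries/protein_length, cap)/cap`                       | [0, 1]  |
| disease           | 1 if any gene–disease association matches the disease focus  | {0, 1}  |
| function          | 1 if any process term matches the functional focus           | {0, 1}  |
| zygosity          | 1 for homozygous-alternate, 0.5 for heterozygous or unknown  | {0.5, 1}|

and the total is `Σ w_c · component_c` with unit weights by default.

Design notes on the individual channels:

* **Rarity.** An unreported GMAF is scored as maximally rare, never
  imputed as 0-frequency-common: absence from the population tables is
  itself the interesting signal for a putative driver. The ramp ceiling
  `g_max` defaults to 0.05 (5% minor allele frequency), a conventional
  rare-variant cut-off; it is a `focus_config()` parameter.
* **Literature.** The logarithm deliberately dampens heavily published
  biomarkers: 9 references score 1.0, 999 references score 3.0, so a
  famous gene cannot dominate on fame alone.
* **COSMIC burden.** Entry counts are normalized to protein length
  (entries per residue) so large genes do not win by target size, and
  capped at 1 entry/residue by default before rescaling to [0, 1].
* **SIFT vs PolyPhen.** SIFT enters as a binary call at its conventional
  0.05 damage threshold because SIFT values are tolerance probabilities
  with an established cut-off; PolyPhen-2 enters as its raw probability,
  which is already calibrated toward "probability of damage". Across
  transcripts of a gene the most damaging value is kept (minimum SIFT,
  maximum PolyPhen) — the conservative choice for prioritization.
* **Zygosity.** Unknown zygosity is scored like heterozygous (0.5) rather
  than penalized to 0: missing genotype metadata should not erase an
  otherwise strong variant.

The additive unit-weight form, the binary SIFT channel, the rarity ramp
and the COSMIC cap are this package's concrete instantiation of a
deliberately simple scoring scheme; every one of these constants is
exposed through `focus_config()` so alternatives are one configuration
away, and the weighted-sum invariant (`total == Σ w·c` to 1e-9) is
enforced by tests.

Variants overlapping several genes are scored once per gene; the maximum
total is the variant's ranking score and the winning gene is the one
reported. Ties are broken by (chromosome, position, alternate allele) with
a locale-independent radix sort, so rankings — and all TSV outputs — are
byte-stable across runs and input orderings.

## Filtering semantics

`result_table()` applies, conjunctively: a damage predicate (by default
*every present* predictor must pass — SIFT ≤ 0.05, PolyPhen ≥ 0.85 — with
at least one present; `damage_mode = "any"` switches to the disjunctive
reading), a GMAF ceiling (default 1, the documented no-op sentinel since
real frequencies are ≤ 0.5), minimum literature/COSMIC counts, a minimum
number of focus-matching disease associations, a census mode, and the
functional focus. Census modes partition cleanly: mode 1 is census genes,
mode 2 is interactors of census genes that are not census themselves, and
mode 3 is their union — a property asserted by tests. Tightening any
threshold can only shrink the result set (strictness monotonicity, also
under test).

Disease matching is case-insensitive substring matching of the focus
phrases against association names (so the phrase "Myelodysplas" matches
both "Myelodysplasia" and "Myelodysplastic syndrome"). Functional-term
matching additionally ignores non-alphanumeric characters, so a focus
entry like "B-cell" matches "B cell receptor signaling".

## The synthetic fixture universe

Because the real workflow depends on external resources (UCSC gene
models, VEP, COSMIC, population frequencies, literature and expression
databases), the package ships a deterministic generator,
`simulate_universe()`, that emits a mutually consistent offline universe:
gene models, two control and two target VCFs sharing a planted germline
set, a MuTect-style call-stats file for the target-only somatic variants,
a VEP-style annotation file covering exactly the coding variants, the
seven evidence tables, and a manifest recording every planted variant's
true class and coding status. The manifest is a complete oracle: the test
suite checks that each pipeline stage reproduces the manifest-predicted
set exactly.

Generator conventions, chosen once as plausible for an exome-scale
miniature and not tuned thereafter:

* Genes of 3–12 kb with 2–4 exons and 1–2 transcripts are laid
  end-to-end with 2–8 kb gaps on two chromosomes; positions are sampled
  without replacement so variant keys are unique by construction.
* Planted *drivers* carry the canonical high-relevance profile: no
  reported GMAF, SIFT ≤ 0.05, PolyPhen ≥ 0.9, a census gene with ≈ 1
  COSMIC entry per residue, disease and process terms matching the focus,
  and elevated expression in hematopoietic tissues.
* *Background* variants carry common frequencies (GMAF 0.06–0.4, above
  the rarity ramp), tolerated predictor scores (SIFT 0.2–0.9, PolyPhen
  ≤ 0.4), sparse literature (0–20 references) and unrelated disease and
  process terms.
* Germline zygosity is 80% het / 20% hom-alt and identical across the
  related samples; somatic calls are heterozygous with tumor allele
  fractions of 0.2–0.6.

`simulate_worked_example()` fixes a 20-variant somatic scenario with 3
drivers under the shipped hematological focus (`leukemia_focus()`); the
end-to-end pipeline ranks the drivers 1–3 and the default thresholds
retain exactly them.

What the generator does *not* emulate — and what passing tests therefore
do not demonstrate about real data: mutational signatures and
transition/transversion bias, homopolymer and alignment artifacts,
multi-gene overlap (synthetic genes never overlap, though the scorer
handles overlap and is unit-tested on it), population structure in allele
frequencies, and any correlation structure between evidence channels.
Recovery of planted drivers shows the plumbing and the score behave as
specified under the declared profiles, not that the score separates true
drivers in real exomes.

## Numerical and degenerate-input choices

* All internal genomic arithmetic is 0-based half-open (the GenePred
  convention); conversion to 1-based happens only at I/O boundaries.
* Gene-model rows violating coordinate invariants are rejected with line
  numbers (warning + attribute) rather than aborting the load;
  structurally malformed rows abort with the line named.
* Multiallelic VCF records are split per alternate allele and re-checked
  for SNV-ness. An alternate allele with zero copies in the sample's
  genotype is treated as not called in that sample and dropped; a missing
  genotype yields zygosity `unknown`.
* VEP transcript-row aggregation must be permutation-invariant (tested by
  shuffling rows), so the amino-acid change is taken as the
  lexicographically smallest `ref/alt` pair among rows that carry one —
  a deterministic tie-break that does not depend on file order.
* A gene with an all-zero expression profile is excluded from the heatmap
  with a warning (mean-normalization is undefined) and listed with the
  profile-less genes instead of being zero-filled.
* Weighted totals are validated to 1e-9; heatmap rows to mean 1 within
  1e-9.

## Problem sizes used in the test suite

The oracle-equivalence tests run 20 seeded universes of roughly 1,000 to
9,600 variants against 50–500 transcripts, with extra variants planted on
both sides of every transcript, CDS and exon boundary of the first 20
transcripts; driver-recovery runs the 20-variant worked example plus a
1,000-variant somatic set with 10 planted drivers. These sizes exercise
the same code paths as a full exome (which differs only in constant
factors) while keeping the suite quick to run anywhere.

## Known limitations

* SNVs only: indels, MNVs and structural variants are out of scope, as is
  re-running VEP itself — the package consumes VEP's tabular output.
* Evidence is whatever the local tables say; there is no live PubMed,
  COSMIC or DisGeNET querying, no query expansion on MeSH terms, and no
  versioning of the underlying databases.
* The score is a descriptive prioritization device, not a calibrated
  probability; weights are not trained against labeled data.
* Census mode 2 ("interactors") depends entirely on the supplied
  interaction pairs; directionality and evidence quality of interactions
  are not modeled.
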