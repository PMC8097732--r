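---
title: "Profiling tRNA 3'-end maturation and fragmentation with trfcat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling tRNA 3'-end maturation and fragmentation with trfcat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trfcat)
```

## The biological problem

In *Bacillus subtilis*, tRNA-Cys is encoded by a single-copy gene at the
distal end of the *rrnD* ribosomal operon. The gene is 71 nt long and does
**not** encode the universal 3'-terminal CCA: that trinucleotide is added
post-transcriptionally by the CCA-adding enzyme, and is required for
aminoacylation. A small-RNA sequencing library from spores or outgrowing
cells therefore contains a zoo of tRNA-Cys-related molecules: unprocessed
precursors still carrying genomically encoded leader/trailer nucleotides,
immature species that end exactly at the encoded 3' base, mature CCA-bearing
tRNA, CC-ended repair intermediates, tRNA-derived fragments (tRFs) with or
without their own CC/CCA ends, and species carrying incorrect
post-transcriptional tails (CCACCA, CCA plus poly(A), and similar).

`trfcat` classifies each read mapping to such a locus into one of nine
categories and profiles how the category composition changes across
timepoints and conditions (e.g. dormant spores at T0 versus outgrowth at
30/60/90 min, with and without 1.2 M NaCl):

| Category | Definition |
|----------|------------|
| I    | precursor: any genomically encoded 5' leader or 3' trailer base |
| II   | full-length (positions 1–71), no tail |
| III  | full-length + `CCA` (mature) |
| IV   | full-length + `CC` |
| V    | 3'-tRF (start ≥ 2, end = 71) + `CCA` |
| VI   | 3'-tRF + `CC` |
| VII  | 5'-tRF (end < 71 from position 1) or internal fragment |
| VIII | full-length with any other tail |
| IX   | 3'-tRF with any other tail |

The central analytical difficulty is the **tail-versus-trailer ambiguity**:
a read ending in `...CCA` may carry a post-transcriptional CCA (mature) or,
if the downstream genomic sequence happens to begin with C, a genomically
encoded trailer (precursor). The classifier resolves this against the
reference window, not by read length.

## Pipeline model

The pipeline is `read -> trim -> filter -> map -> annotate -> classify ->
profile`:

1. **Reference window** (`load_locus()`, `build_window()`): the gene plus up
   to `flank` nt (default 50) of genomic context on each side, oriented in
   gene sense (minus-strand loci are reverse-complemented). Flanks are what
   make genomic leaders/trailers detectable. BED input is half-open 0-based;
   all internal gene coordinates are 1-based with position 1 the first
   encoded base and 71 the last (CCA is never genomic).
2. **Read preprocessing** (`read_sequences()`, `trim_adapter()`,
   `filter_reads()`): FASTQ/FASTA in (gzip supported); the longest read
   suffix matching an adapter prefix within a 10% substitution rate and at
   least 3 nt of overlap is removed; reads containing non-ACGT characters
   are dropped entirely, as are reads shorter than 15 nt. No quality-score
   trimming is performed. All thresholds are configurable; the defaults are
   the package's own choices for a small-RNA protocol whose exact trimmer
   settings are not public.
3. **Mapping** (`map_reads()`): Smith–Waterman local alignment of each read,
   in both orientations, against the window only — reads were preselected
   for this locus, and multi-mapping elsewhere in the genome is out of
   scope. Alignments must pass four filters: length fraction ≥ 0.8 (aligned
   read bases / read length), similarity fraction ≥ 0.8 (identical columns /
   all alignment columns, gap columns included), at most 2 mismatching
   columns, and at most 3 gap *events* (an indel run of any length counts
   once). Antisense survivors are reported but excluded from
   classification.
4. **End annotation** (`annotate_ends()`): the alignment's column mapping —
   not the read length — defines the covered gene interval. Read bases
   before/after it form the 5'/3' extensions. Bases *aligned* within a
   flank count as genomic; soft-clipped bases extend the genomic run only
   by contiguous exact match against the flank. The residual after the
   genomic prefix of the 3' extension is the post-transcriptional tail.
5. **Classification** (`classify_reads()`): the rules in the table above,
   applied in precedence order I → full-length → 3'-tRF → VII. Tail
   vocabulary is matched verbatim (`CCA`, `CC`, empty, anything else); no
   error-tolerant tail matching is attempted, so a sequencing error inside
   a CCA tail lands in VIII/IX — a known inflation source for the
   incorrect-tail categories at high error rates.
6. **Profiling** (`count_categories()`, `category_percentages()`,
   `aggregate_replicates()`, `report_timecourse()`): exact integer counts
   per sample partition the mapped total; percentages divide by the
   classified total (UNCLASSIFIED flank-only reads are excluded from the
   denominator by default, because published category percentages span only
   the nine categories — set `include_unclassified = TRUE` to change this);
   replicate aggregation reports means and SEM (sample SD with the n−1
   denominator over √n; a single replicate reports `NA`, not 0). Pooled
   percentages sum counts before dividing, which equals the count-weighted
   mean of per-replicate percentages.

## Design choices where the design was genuinely open

* **Alignment scoring.** No public scoring scheme exists for the original
  (commercial) mapper, so the package defaults to match +2, mismatch −3,
  gap open −5, gap extend −2, with a gap of length L costing
  `open + (L−1)·extend`. All four values are configurable
  (`scoring_scheme()`); the *filters* — not the scores — do the work of
  deciding which reads count, and those are pinned by tests.
* **Filter definitions.** "Length fraction" is aligned read bases over full
  read length; "similarity fraction" is identical columns over all
  alignment columns including gaps; the indel budget counts gap events, the
  mismatch budget substituted columns. These are the closest public
  interpretations of the original tool's definitions and are pinned by
  tests.
* **Tie-breaking.** Among equal-scoring local alignments the aligner
  deterministically prefers the smallest window end coordinate, then the
  smallest read coordinate, and traces back preferring aligned columns over
  gaps (fewest gap events). Determinism, not a particular co-optimal
  choice, is the requirement: category assignment depends only on covered
  interval and extensions, which co-optimal alignments share in all
  non-pathological cases.
* **Genomic-versus-tail rule.** The genomic trailer is the maximal
  contiguous run (aligned flank bases, then exact-matching clipped bases)
  adjacent to the gene; any genomic base at either end makes the read a
  precursor (category I), taking precedence over every other label. When
  the first downstream flank base is C the call is intrinsically ambiguous;
  such reads are flagged per read (`ambiguous_flank_c`) rather than
  silently decided.
* **Unplaced corner cases.** 3'-fragments ending exactly at position 71
  with no tail are assigned VII with flag `three_trf_no_tail`; tails on
  reads ending before position 71 stay in VII with flag `tail_before_71`;
  single-C tails go to VIII/IX with flag `single_c_tail`. The flags keep
  these decisions auditable instead of baked in.
* **No inferential testing.** With two replicates per timepoint the package
  reports means ± SEM and draws trend plots; it deliberately implements no
  hypothesis test.
* **Outgrowth averages.** Printed outgrowth summaries can be read as
  averages over samples, over times, or over conditions; the time-course
  table emits per-(condition, time) means so any of the three aggregations
  can be formed.

## The synthetic-data generator

Because the package must be testable without downloading the original
sequencing runs, `generate_reference()` and `simulate_sample()` produce a
fully labelled synthetic study:

* a random 71-nt gene inside ≥ 50-nt flanks, where the first ten
  downstream-flank bases are drawn from `{G, T}` only. This guarantees the
  flank cannot begin with C, contains no `CCA` near the junction, and —
  because every tail in the repertoire is built from C and A — cannot
  profitably absorb any tail into the alignment. Tail/trailer
  disambiguation is then *exact*, which is what makes 100% truth-recovery
  assertions meaningful.
* reads drawn from a configurable category mixture. The default mixture is
  the published dormant-spore composition (I 1.01%, II 0.34%, III 22.85%,
  IV 9.47%, V+VI 23.19% split evenly, VII 30.46%, VIII+IX 12.16% split
  7.0/5.27), normalised to sum to one; the published splits for V/VI and
  VIII/IX are not printed separately, so the even and 7.0/5.27 splits are
  testing defaults, not claims about the study.
* precursor leaders/trailers of length `1 + Geometric(0.3)` truncated at
  the flank — short extensions dominate, as expected for partially
  processed transcripts; fragment boundaries uniform over the valid ranges
  with a 15-nt minimum so simulated fragments survive the read filter;
  incorrect tails drawn from `CCAC`, `CCACA`, `CCACCA`, `CCA` + 1–6 A's
  (poly(A) appended after CCA), `C`, `CA`; iid substitution errors at a
  configurable per-base rate; constant quality strings.
* `simulate_study()` emits the full 14-sample layout (two T0 replicates,
  two conditions × three outgrowth timepoints × two replicates) with
  per-sample depths taken from the published per-run accounting
  (243–1,141 mapped reads per run, 9,163 in total).

What the generator does **not** emulate: realistic base-quality profiles,
PCR duplication, ligation bias, and modification-induced reverse-
transcriptase fall-off (named but unquantified in the source study). A
passing truth-recovery test therefore demonstrates the correctness of the
classification logic under the stated read model, not end-to-end accuracy
on real libraries, where modification-induced truncations will inflate
fragment categories.

Two intrinsic effects, verified by the test suite, are worth knowing:

* **Long-tailed fragments are lost by design.** A category IX read with a
  short body and a long incorrect tail (e.g. 17 nt of gene + `CCAAAAA`)
  has less than 80% of its length alignable and fails the length-fraction
  filter, exactly as it would in the original pipeline. At the default
  mixture this affects ~0.3–0.7% of reads; truth recovery is measured over
  reads that reach the classifier.
* **Error-induced reroutes are asymmetric.** At a 1% substitution rate,
  mature CCA reads misclassify through exactly four routes: a hit in the
  first two gene positions trims the alignment start (→ V), a hit near the
  3' gene end trims the end (→ VII), a hit inside the tail corrupts it
  (→ VIII), and a tail base mutated to coincide with the first downstream
  flank base produces a single-base apparent trailer (→ I). A tail cannot
  shorten by substitution, so IV is unreachable from III.

## Numerical and reproducibility choices

* Every stochastic entry point takes a mandatory integer seed;
  simulation restores the caller's RNG state afterwards. Identical seeds
  give byte-identical FASTQ corpora and TSV outputs.
* Percentages are computed in double precision and tested to sum to 100
  within 1e−9 of the classified total.
* Alignment scores are exact sums of the (integer-valued by default)
  scoring parameters; the aligner was validated against exhaustive
  enumeration of all local alignment paths on sequences up to 8 nt.
* Problem sizes used by the test suite and acceptance script: 10,000-read
  corpora for truth recovery and proportion recovery (3-multinomial-SE
  bands), 20 × 10,000 draws for the chi-square goodness-of-fit property,
  200 random pairs for the alignment oracle, and 14 × 25–40-read studies
  for end-to-end determinism checks — sizes chosen so sampling noise is
  far below the tested tolerances while a full run stays in the
  single-minute range.

## Known limitations

* Single-locus design: reads multimapping to other tRNA isoacceptors or
  rRNA are out of scope; users must pre-extract locus-mapped reads or rely
  on the window's local alignment to reject them via the filters.
* The exact read accounting of the original commercial mapper is not
  reproducible from its publication; this package's filters are a
  documented, tested interpretation, so per-run mapped-read counts on the
  original raw data are expected to approximate, not equal, the published
  table.
* Adapter sequences for the original libraries are not public; trimming
  real runs requires supplying them in the configuration.
* No aminoacylation state, ribonucleoside modification, or
  differential-abundance inference.
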