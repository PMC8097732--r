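# trfcat

Classification and profiling of tRNA 3'-end maturation states and
tRNA-derived fragments (tRFs) from small RNA-seq reads mapping to a
single-copy tRNA locus.

## The problem

In *Bacillus subtilis* the single-copy tRNA-Cys gene (71 nt, at the distal
end of the *rrnD* operon) does not encode the 3'-terminal CCA required for
aminoacylation — CCA is added post-transcriptionally. A small-RNA library
from dormant spores or outgrowing cells therefore contains a mixture of
tRNA-Cys-related species at different processing stages. `trfcat` assigns
every locus-mapped read to one of nine categories:

| Category | Species |
|----------|---------|
| I    | precursor (genomically encoded 5' leader and/or 3' trailer) |
| II   | immature full-length tRNA (71 nt, no CCA) |
| III  | mature full-length tRNA + `CCA` |
| IV   | full-length tRNA + `CC` |
| V    | 3'-tRF + `CCA` |
| VI   | 3'-tRF + `CC` |
| VII  | 5'-tRF or internal fragment |
| VIII | full-length tRNA with an incorrect tail (`CCACCA`, `CCA(A)n`, ...) |
| IX   | 3'-tRF with an incorrect tail |

and aggregates per-sample counts into percentages, replicate means ± SEM
and condition × timepoint trend tables/plots.

The crux is separating a post-transcriptional tail from a genomically
encoded trailer. For a read aligned to the locus window with covered gene
interval `[s, e]` (1-based, `e ≤ 71`), 5'/3' extension strings, and a
genomic prefix of the 3' extension of length `g` (maximal contiguous match
against the downstream flank, aligned bases first, then exact-matching
soft-clipped bases), the label is decided in precedence order:

1. any genomic extension (`g ≥ 1` either side) → **I**
2. `s = 1, e = 71`: tail `""` → **II**, `CCA` → **III**, `CC` → **IV**, else → **VIII**
3. `s ≥ 2, e = 71`, tail ≠ `""`: `CCA` → **V**, `CC` → **VI**, else → **IX**
4. everything else → **VII** (with `n = 71 − e` recorded)

Mapping uses full Smith–Waterman local alignment (affine gaps,
compiled code) against the gene ± flank window with the mapping filters:
length fraction ≥ 0.8, similarity fraction ≥ 0.8, ≤ 2 mismatches, ≤ 3
indel events per read.

A seeded simulator generates fully labelled synthetic corpora (all nine
categories, configurable proportions, leader/trailer lengths, tail
repertoire, substitution errors) over constraint-checked synthetic
references, so the whole pipeline is testable without any downloads.

## Worked example

```r
library(trfcat)
library(dplyr)

window <- generate_reference(seed = 1)                    # synthetic locus
mix    <- category_mixture(dormant_proportions(),          # published T0 mixture
                           n_reads = 2000, error_rate = 0)
reads  <- simulate_sample(window, mix, seed = 2, sample_id = "T0")

per_read <- classify_sample(reads[c("read_id", "seq", "qual")], window,
                            sample_id = "T0")
pipeline_log(per_read)
#> # A tibble: 1 × 8
#>   sample_id input dropped  kept mapped antisense unmapped classified
#>   <chr>     <int>   <int> <int>  <int>     <int>    <int>      <int>
#> 1 T0         2000       0  2000   1990         0       10       1990

profile <- count_categories(per_read)
category_percentages(profile) %>% filter(count > 0)
#> # A tibble: 9 × 4
#>   sample_id category count percent
#>   <chr>     <fct>    <int>   <dbl>
#> 1 T0        I           21   1.06
#> 2 T0        II           8   0.402
#> 3 T0        III        441  22.2
#> 4 T0        IV         198   9.95
#> 5 T0        V          198   9.95
#> 6 T0        VI         238  12.0
#> 7 T0        VII        627  31.5
#> 8 T0        VIII       149   7.49
#> 9 T0        IX         110   5.53
```

Reading the output: of 2,000 simulated reads, 1,990 map to the locus (the
10 others are short-bodied long-tailed fragments rejected by the 0.8
length-fraction filter). The recovered percentages track the configured
dormant-spore mixture — 22.2% mature CCA-ended tRNA (III), 31.5%
5'-tRF/internal fragments (VII), ~1% precursors (I) — within multinomial
sampling noise at n ≈ 2,000. Category membership of every single mapped
read equals its generating label at `error_rate = 0`.

A full multi-sample study (14 samples, two conditions × four timepoints)
runs through `simulate_study()` + `run_pipeline()` (or the wrapper script
`inst/scripts/trfcat.R` with subcommands `simulate`, `profile`,
`classify`, `report`), producing per-read TSVs, per-sample profiles,
replicate means ± SEM, trend plots and a conservation-checked run log.

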