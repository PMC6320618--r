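# rangetable

A tidy, fluent grammar for transforming tables of genomic ranges in R.

Genomic interval data — gene and exon annotations, ChIP-seq coverage
islands, variant calls, read alignments — all share one tabular shape: one
range per row with fixed `seqnames`/`start`/`end`/`strand` columns plus
arbitrary metadata columns. `rangetable` implements an endomorphic algebra
over that shape, so analyses read as pipelines of small verbs rather than
index bookkeeping. It is aimed at genomicists who already think in dplyr
verbs and want the same style for range-specific operations.

The algebra covers:

* **column verbs** — `filter()`, `mutate()`, `select()`, `arrange()`,
  `group_by()` / `summarise()` (methods on the dplyr generics), evaluated
  in the context of the table (any column plus the derived `width`);
* **anchored arithmetic** — `anchor_start/end/center/5p/3p()` fix a point,
  then `mutate(width = ...)` or `stretch()` resize around it;
  `shift_*()` and `flank_*()` take a direction suffix
  (`left`/`right`/`upstream`/`downstream`, strand-resolved);
* **set operations** — parallel (row-wise) `%intersect%`, `%union%`,
  `span()`, `between()`, `%setdiff%`, and merging (base-set-wise)
  `intersect_ranges()`, `union_ranges()`, `setdiff_ranges()`,
  `complement_ranges()`, `reduce_ranges()`, `disjoin_ranges()`,
  `compute_coverage()`;
* **joins by overlap or proximity** — `join_overlap_inner()`,
  `join_overlap_intersect()`, `join_overlap_left()`, `join_nearest()`,
  `join_precede()`, `join_follow()`, `filter_by_overlaps()`,
  `group_by_overlaps()`, `tile_genome()`;
* **exact I/O** — BED, bedGraph, GFF3 and chrom.sizes, with all coordinate
  convention changes (0-based half-open vs the internal 1-based inclusive)
  confined to the I/O layer;
* **fixtures and oracles** — seeded simulators (`simulate_ranges()`,
  `simulate_coverage_track()`, `simulate_variants()`) and naive brute-force
  oracles (`oracle_hits()`, `oracle_base_set()`, `oracle_coverage()`) used
  by the test suite as independent ground truth;
* **a CLI** — `cli_main()` (launcher in `inst/cli/rangetable`) exposes the
  verb catalog over files with a safe mini expression grammar.

Coordinates are 1-based inclusive with `width = end - start + 1`;
`end = start - 1` encodes a legal width-0 range. An attached
`genome_info()` (per-sequence lengths and build tag) makes every operation
bounds-checked: arithmetic that would leave the genome raises an error
naming the offending row instead of silently clipping.

## Worked example

```r
library(rangetable)

gi <- genome_info(c(chr1 = 1000L), build = "toy1")
peaks <- range_table("chr1", c(120, 300, 310, 700), c(180, 350, 360, 720),
                     strand = c("+", "+", "-", "*"), score = c(5, 12, 9, 3),
                     genome_info = gi)

peaks %>% filter(score > 4) %>% reduce_ranges(peak = max(score))
#> RangeTable with 2 range(s) and 1 metadata column(s)
#>   seqnames start end strand width peak
#> 1     chr1   120 180      *    61    5
#> 2     chr1   300 360      *    61   12
#> genome: 1 sequence(s) [toy1]
```

The two ranges scoring above 4 on `[300,350]` and `[310,360]` overlap, so
`reduce_ranges()` merges them into one island `[300,360]` whose `peak`
column records the island maximum (12); the isolated `[120,180]` range
stays its own island with peak 5.

Promoter-style regions — 50 bases upstream of each feature's 5' end —
compose from anchoring, resizing and flanking; note row 3 flanks to the
*right* because the feature is on the minus strand:

```r
peaks %>% anchor_5p() %>% mutate(width = 20) %>% flank_upstream(50)
#> RangeTable with 4 range(s) and 1 metadata column(s)
#>   seqnames start end strand width score
#> 1     chr1    70 119      +    50     5
#> 2     chr1   250 299      +    50    12
#> 3     chr1   361 410      -    50     9
#> 4     chr1   650 699      *    50     3
#> genome: 1 sequence(s) [toy1]
```

Per-base depth as constant runs (the in-memory form of a bedGraph file,
zero runs included — note the depth-2 run where the two middle peaks
overlap):

```r
compute_coverage(peaks)
#>   seqnames start  end strand score
#> 1     chr1     1  119      *     0
#> 2     chr1   120  180      *     1
#> ...
#> 5     chr1   310  350      *     2
#> ...
#> 9     chr1   721 1000      *     0
```

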