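---
title: "A tidy grammar of genomic range transformation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A tidy grammar of genomic range transformation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rangetable)
```

## The data model

Most genomic interval data — feature annotations, read alignments, coverage
tracks, variant calls — share one shape: a table with one range per row,
fixed columns naming the sequence (`seqnames`), the coordinates (`start`,
`end`), the `strand`, and arbitrary further columns carrying measurements or
annotations. `rangetable` takes that shape seriously: the `RangeTable` is a
plain data.frame specialization with those four fixed columns, an optional
per-genome bookkeeping record (`genome_info()`: sequence lengths plus a
build tag), and the invariants

* `start >= 1`, coordinates 1-based and inclusive;
* `width = end - start + 1`, always derived, never stored;
* `end = start - 1` is legal and encodes a width-0 (insertion-point) range;
* with a genome attached, every range lies within its sequence.

Keeping width derived means the three coordinate dimensions can never
disagree, and keeping width-0 ranges legal means the gap between adjacent
ranges (`between()`), and degenerate intersections of abutting ranges, are
representable without a special empty marker.

Every verb in the grammar except `summarise()` is *endomorphic*: a valid
`RangeTable` in, a valid `RangeTable` out, genome included, so pipelines
compose with `%>%` indefinitely. `summarise()` deliberately returns a plain
data.frame — an aggregated row summarizes many features and no longer has
single-feature range semantics.

External formats differ in convention: BED and bedGraph are 0-based
half-open, GFF3 is 1-based inclusive. All conversion happens in the I/O
layer and nowhere else, so `read_bed()` on `chr1 0 10` yields `[1, 10]` and
`chr1 5 5` yields a width-0 range at start 6.

## Column verbs and expressions

`filter()`, `mutate()`, `select()`, `arrange()`, `group_by()` and
`summarise()` are methods on the dplyr generics. Expressions are ordinary R
code evaluated with the table's columns in scope, plus the derived `width`
and the helpers `n()`, `n_distinct()`, `first()`, `last()` and `desc()`;
symbols not matching a column fall through to the calling environment.
Evaluation is pure — the input table is never modified — and no verb except
`arrange()` ever reorders rows, so outputs are deterministic and goldens are
bit-reproducible.

Two design points are worth stating because the design was genuinely open:

* **Group emission order.** Nothing forces an order on `summarise()`
  output; we emit groups in first-appearance order of the key values, which
  preserves the (genome-sorted) order of typical inputs and is documented
  behavior, not an accident of a hash table.
* **Missing values.** Each column type's native `NA` is the missing
  sentinel. Left joins pad unmatched rows with `NA`, expressions propagate
  it, and aggregations treat it as R does (so `sum()`/`mean()` behave
  conventionally unless the expression handles `NA` itself).

`select()` refuses to touch the four coordinate columns: removing them
would break the endomorphism, so they are simply always retained.

## Anchored arithmetic

`start`, `end` and `width` are mutually dependent, so "set the width" is
ambiguous until a fixed point is chosen. Anchoring (`anchor_start()`,
`anchor_end()`, `anchor_center()`, `anchor_5p()`, `anchor_3p()`) records
that fixed point without touching coordinates; a subsequent
`mutate(width = ...)` or `stretch()` consumes it:

```{r}
rng <- range_table("chr1", 100, 101)
mutate(anchor_center(rng), width = 4)
```

Numerical choices here are deliberate and tested:

* **Center parity.** When a width change is odd, exact symmetry is
  impossible; the extra base goes to the *end* side. Deterministic,
  documented, and checked in a 15-case anchor-by-strand enumeration derived
  by hand before the implementation existed.
* **Strand resolution.** `5p`/`3p` anchors, `shift_upstream()`/
  `_downstream()` and `flank_upstream()`/`_downstream()` resolve per row by
  strand; unstranded rows are treated as plus strand everywhere, the least
  surprising total convention.
* **Bounds.** Arithmetic that would cross coordinate 1 or the sequence end
  raises an integrity error naming the offending row rather than silently
  clipping — coordinate bookkeeping exists precisely to protect downstream
  overlap computations. `stretch()` on a width-0 range is allowed and grows
  the range around its insertion point.

## Parallel versus merging set operations

The parallel operators (`%intersect%`, `%union%`, `span()`, `between()`,
`%setdiff%`) combine row *i* with row *i* and insist on rectangular,
single-range results: a gapped `%union%` and a two-piece `%setdiff%` are
errors by design (the merging forms cover those cases), while abutting
pairs intersect in a width-0 range. `between()` of an *overlapping* pair
has no gap to return; we clamp to a width-0 range at `min(ends) + 1` rather
than error, keeping the operator total.

The merging operators treat each table as a set of covered bases per
sequence. `reduce_ranges()` merges overlapping *and abutting* runs (gap 0
counts as touching); `disjoin_ranges()` splits covered bases at every
boundary into maximal pieces of constant membership; `compute_coverage()`
returns maximal constant-depth runs including explicit zero runs;
`complement_ranges()` (the unary member) needs a genome and returns every
uncovered base. Merged rows are unstranded and metadata-free — aggregation
expressions on `reduce_ranges()`/`disjoin_ranges()` are the sanctioned way
to carry information through a merge — and output order is fixed: genome
sequence order (first appearance if no genome), then start, then end.
Strand-restricted variants (`reduce_ranges_directed()` etc.) run the same
operation within strand classes.

Width-0 rows cover no bases, so the base-set operations and `disjoin`
ignore them; consistently, two ranges overlap when `max(starts) <=
min(ends)`, the arithmetic reading under which a width-0 range matches
ranges straddling its insertion point.

## Overlap and proximity joins

`find_overlap_hits(x, y)` produces the (query, subject) index pairs sharing
at least one base on the same sequence, sorted and unique. Flags compose:
`within` requires containment of the query, `directed` requires equal
strand — and under directed matching unstranded rows match only unstranded
rows, while by default strand is ignored entirely. Mere adjacency is *not*
overlap; an explicit `maxgap` relaxes that. Three merge modes consume hits:
inner (x's coordinates, both metadata sets, one row per hit), intersect
(pairwise intersections as coordinates), and left (all x rows, `NA` padding
for misses). Colliding metadata names get `.x`/`.y` suffixes on both sides,
a fixed, deterministic schema.

`find_nearest_hits()` returns at most one subject per query — minimal gap,
overlap counting as gap 0, ties to the lowest subject index (the
deterministic choice golden tests need). `precede`/`follow` are defined
purely by coordinate order (subject strictly after the query's end /
strictly before its start); a strand-aware variant is just a strand filter
composed with them.

The matcher itself prunes candidates against per-sequence sorted subject
starts; its only contract is exact agreement with the quadratic
nested-loop oracle, which the suite checks on over a hundred seeded random
instances, alongside an independent cross-check against a reference
interval library on one fixture.

## Synthetic data: what it does and does not show

All tests run on seeded synthetic data from the fixtures module, which is
first-class, exported code:

* `simulate_ranges()` places `n` ranges uniformly (sequences weighted by
  length, widths uniform on `[1, 50]` by default) on a two-chromosome toy
  genome of 10 and 8 kb, strands 45/45/10 percent plus/minus/unstranded,
  with optional uniform scores, categorical ids, or REF/ALT single-base
  variants drawn uniformly from the 12 ordered pairs.
* `simulate_coverage_track()` emulates a normalized ChIP-seq coverage
  signal as ~200 constant-score integer runs tiling a 100 kb chromosome,
  background scores uniform below the peak height, with one planted
  maximal run (default height 30, width 1500) whose position is recorded
  for recovery tests.
* `simulate_variants()` plants exact per-chromosome transition and
  transversion counts, plus indel and mitochondrial rows as filter fodder,
  so downstream Ti/Tv ratios are known by construction.

The oracles (`oracle_hits()`, `oracle_base_set()`, `oracle_coverage()`)
are intentionally naive — nested loops and per-base arrays sharing no code
with the engine — so agreement is evidence rather than tautology.

Passing on these fixtures shows the algebra is implemented correctly; it
does not show robustness to what real data adds — scale (millions of
rows), pathological annotation (overlapping transcripts sharing exons,
circular chromosomes, which are out of scope), sequencing noise, or
missing-data patterns beyond simple `NA`s. Problem sizes in the suite
(up to 150x150-range join instances on a 100 kb genome, 100 seeded
instances per oracle sweep, a 500-read windowed-statistics fixture) were
chosen as the smallest sizes that still exercise every code path several
times over.

## The three replicated workflows

The acceptance suite and `scripts/acceptance.R` replay three standard
epigenomics/QC pipelines end to end on the synthetic fixtures:

1. **Peak finding** — read a bedGraph coverage track, `filter(score > 8)`,
   `reduce_ranges(peak = max(score))` into islands, locate the global
   maximum, take a 5000-nt window around it via `anchor_center()`, and
   inner-join the islands against the window. The planted peak run and the
   per-base-oracle island set must be recovered exactly.
2. **Windowed statistics** — `tile_genome(gi, 10000)`,
   `group_by_overlaps()`, `summarise(n(), mean(score))`, checked against a
   nested-loop per-tile computation.
3. **Variant QC** — filter indels and `chrM`, flag transitions, and
   `group_by(seqnames) %>% summarise()` the Ti/Tv ratio, which must equal
   the planted per-chromosome ratios exactly.

## Known limitations

* BAM and BigWig are not parsed; the reader family is designed so such
  adapters slot in (path + optional overlap filter), and bedGraph/BED
  stand in for coverage tracks at desk scale.
* GFF3 attribute values are written verbatim (no percent-encoding) and
  attribute order is normalized, so GFF3 round-trips are semantic, not
  byte-exact.
* `read_bed(..., overlap_filter =)` honors the only-matching-records
  contract by filtering parsed records before returning; it does not skip
  I/O for non-matching regions.
* No laziness or out-of-core support: tables are in-memory data.frames,
  appropriate for the annotation-scale data the grammar targets.
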