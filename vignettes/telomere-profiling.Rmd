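---
title: "Profiling telomere content and variant repeats from aligned reads"
author: "telomereprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling telomere content and variant repeats from aligned reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telomereprofiler)
```

## The problem

Human telomeres are arrays of the hexamer `TTAGGG` (t-type), interspersed
with variant repeats (TVRs) such as c-type `TCAGGG`, g-type `TGAGGG` and
j-type `TTGGGG`. Standard aligners cannot place most telomeric reads
uniquely, so telomere biology is invisible in conventional variant-calling
workflows. Two read-level quantities are nonetheless recoverable from an
ordinary BAM file:

* **telomere content** — how much of the library derives from telomeric
  DNA, a proxy (not an estimator) for telomere length; and
* **telomere-repeat composition** — the spectrum of `NNNGGG` hexamers and,
  specifically, *singleton* TVRs (`(TTAGGG)₃-NNNGGG-(TTAGGG)₃`), which are
  enriched in tumors using the recombination-based ALT maintenance
  mechanism.

This package recomputes both from coordinate-sorted BAM input, for single
samples or matched tumor/control pairs.

## The procedure and its assumptions

### Extraction

A read is *telomeric* when it carries at least
$n = \lfloor 0.06 \cdot \ell \rfloor$ repeat hits, where $\ell$ is the
read's own length ($n = 6$ at $\ell = 100$; clamped to $n \ge 1$ so short
reads are never trivially telomeric). Hits are counted by a
**non-overlapping, left-to-right greedy scan** over the search set — the
configured patterns plus their reverse complements, since reads are scanned
as stored and unmapped reads have no meaningful strand. Greedy
non-overlapping counting reflects that telomeric repeats tile: a 12-mer of
t-type counts as 2 repeats, not as 7 overlapping match offsets.

In the default *non-consecutive* mode, hits from all patterns are summed
regardless of spacing. In *consecutive* mode the statistic is the length of
the longest run of **adjacent** hits; a run may mix patterns of the search
set, reading the consecutive criterion as applying to the patterns jointly
(the alternative — per-pattern runs — is strictly narrower and can be
recovered by passing a single pattern).

### Classification

Extracted reads are partitioned by alignment evidence against a
chromosome-band annotation; the **first and last band** of each chromosome
are "terminal". Precedence is fixed:

1. a read mapped with mapping quality ≥ 8 is placed by its own position —
   terminal band → *subtelomeric*, interior band → *intrachromosomal*,
   no band → *intratelomeric*;
2. otherwise the mate is consulted — a mapped mate on a terminal band makes
   the read *junction spanning*; anything else is *intratelomeric*.

Design choices in step 1/2 where the contract was genuinely open:

* High-quality alignments to contigs absent from the band file (decoys,
  unplaced scaffolds) become intratelomeric rather than being dropped;
  dropping them would silently shrink the partition invariant
  (categories must sum to the extracted total).
* Mate rescue does not check the mate's mapping quality: per-record
  alignment fields do not carry it, and requiring it would need a second
  file pass for a marginal gain.
* A confidently placed subtelomeric read with an unmapped mate stays
  subtelomeric; its own position is the stronger evidence.

### Telomere content

$$\mathrm{TRPM} = \frac{\text{intratelomeric reads}}
{\#\{\text{background reads with } 48\% \le \mathrm{GC} \le 52\%\}} \times 10^6$$

GC matching corrects for library GC bias: the canonical repeat is 50% GC,
so the denominator counts reads of comparable composition. Both window
bounds are inclusive; GC percent is computed per read as
round-half-up of $100(G{+}C)/(A{+}C{+}G{+}T)$ with ambiguous bases excluded
from both numerator and denominator (an all-N read falls in no bin but
still counts toward the total).

**Extracted telomeric reads are excluded from the GC denominator.** This is
a deliberate design decision: telomeric reads themselves sit at ~50% GC, so
including them makes the normalizer self-referential — a sample with a
large telomere compartment would inflate its own denominator and compress
its TRPM. Excluding them makes the denominator a pure background-depth
estimate and gives planted fixtures their closed-form TRPM exactly. At
realistic telomere fractions (~10⁻⁴ of a genome library) the two readings
differ negligibly.

If the window is empty the estimate is flagged `undefined` (`NA`), never an
infinity. This matters for bisulfite libraries, where cytosine conversion
empties the 48–52% window; content estimation from such data relies on the
sense strand only and lives on a different numeric scale.

With a matched control, `log2_tc_ratio()` reports
$\log_2(\mathrm{TRPM}_T / \mathrm{TRPM}_C)$, `NA` when either side is
undefined or zero.

### TVR and singleton quantification

On intratelomeric reads only:

* **arbitrary context** — the greedy scan counts any hexamer ending `GGG`
  (sense) or starting `CCC` (antisense, reported as its forward-strand
  reverse complement). The canonical `TTAGGG` is tallied alongside the
  variants so composition fractions sum to one; ALT-oriented outputs simply
  filter it out. Counts are normalized per intratelomeric read.
* **singletons** — every 42-bp window is tested for
  `(TTAGGG)₃-NNNGGG-(TTAGGG)₃` with a non-canonical centre, in either
  orientation; longer canonical flanks still qualify (substring match),
  and overlapping windows may share flanks. Counts are normalized per
  total sample read, because the singleton rate is interpreted against the
  whole library.
* **contexts** — for a configurable TVR list (default: ten common
  variants; the canonical reference enumerates "the ten most common"
  without listing them, so the default here is a curated, explicitly
  replaceable choice), the 18-bp flanks on both sides of each occurrence
  are recorded in telomere-forward orientation; occurrences closer than
  18 bp to a read end are dropped.

**Base quality.** A hexamer (or a singleton's central hexamer) is counted
only when all six bases have Phred quality ≥ 20, suppressing sequencing
errors that would otherwise masquerade as rare TVRs. Two interpretation
points: the filter applies to the singleton's centre only — applying it to
all 42 positions would conflate flank sequencing errors with variant
detection — and a motif hit that fails the filter still advances the scan
frame by six bases, keeping tiled repeats in register (under the
alternative advance-by-one reading a single bad base could shift the frame
of every downstream repeat).

## Parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `threshold_coefficient` | 0.06 | repeats/bp | 6 repeats per 100-bp read; robust for WGS and WES |
| `threshold_override` | unset | repeats | fixed threshold replacing the formula |
| `patterns` | t, c, g, j hexamers | — | the canonical repeat plus the three most prominent TVR types |
| `include_reverse_complement` | TRUE | — | reads are scanned as stored |
| `consecutive` | FALSE | — | scattered hits count by default |
| `mapping_quality_threshold` | 8 | Phred | below this an alignment is treated as unplaced |
| GC window | 48–52 | % | GC content comparable to the canonical repeat |
| `min_base_quality` | 20 | Phred | per-base floor for TVR/singleton counting |
| `flank` | 18 | bp | three repeat units of context per side |

## The synthetic-data generator

`fixture_spec()` / `emit_fixture()` state a small but complete world: 100-bp
reads; a telomere compartment built as an in-frame tiling of hexamers with
configurable variant frequencies (default 5% g-type, 2% c-type, 10%
singleton rate — modest telomerase-like composition); subtelomeric,
intrachromosomal and junction-pair reads placed on a two-chromosome,
three-band-per-chromosome annotation; and background reads with an *exact*
per-read GC count at the target percent (default 50%), rejection-sampled to
stay below the extraction threshold.

Because every tiled hexamer ends in `GGG`, no out-of-frame telomeric motif
can arise inside a planted read, so the tiling itself is the ground truth:
hexamer counts are the slot tabulation, singleton counts are the slots with
a variant centre and three canonical neighbours on both sides, and the
GC-matched denominator is known in closed form without re-scanning the
emitted file. Truth is therefore derived combinatorially, independent of
the scanners it tests.

What the generator does **not** emulate: sequencing errors and indels,
realistic quality profiles, coverage fluctuations, soft-clipped alignments,
bisulfite conversion, and real subtelomeric sequence divergence. A green
end-to-end test establishes that the bookkeeping — extraction, partition,
normalization, tallies — is exact on clean input; it does not establish
robustness to noisy alignments, which on real data is governed by the
quality thresholds above.

## Numerical and degenerate-input choices

* Round-half-up for GC percent (R's `round()` rounds half to even, which
  would misplace exact .5 bins).
* Thresholds clamp to ≥ 1; `compute_repeat_threshold()` rejects
  non-positive read lengths.
* Zero denominators (GC window, total reads, intratelomeric count) yield
  flagged `NA`s, never `Inf`; per-hexamer log2 ratios are `NA` when a
  hexamer is absent from one side.
* Empty inputs are valid: an empty BAM gives an all-zero result with a
  warning; an empty category writes a header-only BAM.
* Band files are sorted by start position per chromosome before terminal
  flags are assigned; overlapping bands are an error, not a warning.
* Coordinates are 1-based leftmost internally (the R convention used by
  the alignment reader); band intervals stay 0-based half-open as in the
  UCSC dialect, converted inside `locate_band()`.
* Strand symmetry of the greedy hexamer scan is exact on hexamer tilings
  (its actual domain — intratelomeric reads), but not on arbitrary
  sequences: a G-run such as `AGGGGGG` resolves to `AGGGGG` scanned
  forward but `GGGGGG` from the reverse strand. The windowed singleton
  scan is strand-symmetric on any input. Tests assert exactly these
  scopes.
* Secondary and supplementary alignments are excluded everywhere so each
  template contributes once; duplicate-flagged reads are counted by
  default with an opt-out, since duplicate marking conventions vary across
  pipelines.

## Known limitations

* TRPM is a content measure, not a base-pair length estimate; converting
  to length would require coverage and ploidy modelling that is explicitly
  out of scope.
* Junction detection relies on mate rescue only; split-read or soft-clip
  aware detection is not attempted.
* CRAM input and streaming from object stores are unsupported.
* The default TVR context list is a placeholder for "the ten most common
  TVRs" and should be set explicitly in studies where the context tables
  matter.
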