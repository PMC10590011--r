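---
title: "Finding transcription factor high accumulation (HOT) zones"
author: "hotzones package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding transcription factor high accumulation (HOT) zones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages({
  library(hotzones)
  library(GenomicRanges)
})
```

## The problem

Transcription factors (TFs) bind DNA mainly at regulatory elements.
ChIP-seq experiments for many TFs reveal that while most binding regions
are occupied by one or a few factors, some DNA stretches accumulate
bindings of unusually many distinct TFs — the *high occupancy target*
(HOT) zones. Locating them reproducibly matters because they coincide with
open chromatin, promoters and CpG islands, and have been linked to both
housekeeping transcription and disease-associated regulation.

This package implements a parametric, fully deterministic procedure for
HOT zone identification from a table of TF binding regions (chromosome,
start, end, strand, TF name; 1-based inclusive coordinates, the native
GenomicRanges convention). The inputs are typically ChIP-seq narrow peaks;
no aligned reads or peak calling are involved.

## Accumulation vectors

Everything starts from a per-base *accumulation vector* per chromosome,
represented exactly as a run-length-encoded integer vector (`Rle`). For a
base $b$ and a symmetric moving window of semi-width $w$ (neighborhood
$[\max(1, b-w),\, b+w]$), three quantification strategies are offered:

* **TF accumulation** — the number of distinct TFs with at least one
  binding region intersecting the window:
  $\mathrm{TF}_{acc}(b) = \#\{t : \exists\, r \in t,\ r \cap [b-w, b+w]
  \neq \emptyset\}$;
* **region accumulation** — the number of input binding regions (for new
  or already counted TFs alike) intersecting the window;
* **base accumulation** — the total number of bases of input regions
  falling inside the window, summed over regions with multiplicity:
  $\mathrm{GB}_{acc}(b) = \sum_r |r \cap [b-w, b+w]|$.

At $w = 0$ the three coincide at every base unless two regions of the same
TF overlap; there, region and base accumulation exceed TF accumulation.
For any base and window the ordering
$\mathrm{TF}_{acc} \le \mathrm{BR}_{acc} \le \mathrm{GB}_{acc}$ holds, TF
accumulation is bounded by the TF inventory size, and all three are
non-decreasing in $w$.

The window mitigates the sparsity that uni-read filtering imposes on
ChIP-seq peaks: each base inherits signal from its neighborhood, smoothing
local discontinuities. A semi-width of 1000 bases is the suggested default
— wide enough to smooth, narrow enough not to aggregate unrelated loci —
and is exposed as the `w` parameter (in bases, default 1000 in the CLI and
in `find_hot_zones()`). Very large `w` merges distant signals and should
be avoided.

### The worked example

The built-in ten-region, three-TF dataset (`fig3_regions()`) illustrates
the differences compactly. Its two Z regions overlap exactly in
[4250, 4500]:

```{r}
rs <- fig3_regions()
track_value(accumulation_track(rs, "tf", w = 0), "chr1", c(4250, 4500))
track_value(accumulation_track(rs, "region", w = 0), "chr1", c(4250, 4500))
```

With `w = 0`, TF accumulation there is 2 (TFs Y and Z) while region and
base accumulation are 3 (three regions, three region-bases per base). With
`w = 1000`, at base 3250 the window [2250, 4250] additionally intercepts
the start of the Z region at [4250, 6000]: region accumulation rises to 4,
but TF accumulation saturates at 3 — Z is already counted:

```{r}
track_value(accumulation_track(rs, "region", w = 1000), "chr1", 3250)
track_value(accumulation_track(rs, "tf", w = 1000), "chr1", 3250)
```

### Numerical realization

Tracks are computed without ever materializing a per-base array:

* TF and region tracks are coverage vectors of the $\pm w$-expanded
  intervals — per-TF merged expansions for TF accumulation (so a TF counts
  once per base), raw expansions for region accumulation;
* the base track is an exact centred running sum (`IRanges::runsum`,
  width $2w+1$) over the multiplicity coverage, zero-padded on both sides
  so the left clamp at position 1 and the open right end come out exactly.

All values are integers; computation switches to doubles only if
$(2w+1) \times \max(\mathrm{coverage})$ could overflow a 32-bit integer.
The window is clamped at position 1 on the left; no chromosome length is
assumed, so the non-zero support simply ends at `max(end) + w`.
Chromosomes are processed independently — a window never spans two of
them. A literal per-base transcription of the three definitions
(`naive_accumulation()`) ships with the package and the test suite
verifies the engine against it base-by-base on randomized inputs.

## From tracks to zones

Two search methods turn accumulation into candidate (*dense*) zones:

* **binding region method** — input regions sharing at least one base are
  transitively merged (book-ended regions stay separate: adjacency is not
  overlap); each merged zone's *accumulation index* is the number of
  distinct TFs binding at least one of its bases. The index therefore
  dominates the per-base TF accumulation anywhere inside the zone, and
  zones may contain bases of accumulation as low as 1. The moving window
  plays no role: zones are the original regions without neighborhood.
* **overlap method** — the track is cut into maximal runs of contiguous
  bases sharing one non-zero accumulation value; the run value is the
  index. Zones are finer, tile the non-zero support exactly, and every
  base of a selected zone meets the threshold.

At an equal threshold the overlap method's HOT bases (TF accumulation,
$w=0$) are always contained in the binding-region HOT zones — the overlap
method trades sensitivity for precision.

## Thresholding

HOT zones are dense zones whose index is **at least** a threshold
(inclusive comparison; ties at the threshold are never split). Two
data-driven procedures are provided, plus an absolute escape hatch:

* **top k percentage** — sort zones by index, take the top
  $\lceil k/100 \cdot N \rceil$ zones and use the minimum index among
  them. Ceiling (rather than floor) is used so the selection is non-empty
  for any valid $k$; because re-selection is by index, the result is
  deterministic and order-independent under ties. More `k`, more zones.
* **over k standard deviations** — $\lceil \mu + k\sigma \rceil$ of the
  per-base accumulation over all (and only) bases with non-zero
  accumulation. More `k`, fewer zones. The sample ($n-1$) standard
  deviation is used, a conventional estimator choice; with a single
  qualifying base $\sigma$ is taken as 0 so the procedure stays defined
  and degenerates to $\lceil \mu \rceil$, consistent with the
  constant-track limit.

For the binding-region method combined with the k-std procedure the base
statistics are taken from the TF accumulation track at the analysis `w`:
the zone indexes are distinct-TF counts, so the threshold must live on the
same scale. This pairing was a genuinely open design point; the TF track
is the only one commensurate with the indexes.

By default zones and base statistics are pooled genome-wide into one
threshold; `per_chromosome = TRUE` repeats the whole search on each
chromosome separately. The full pipeline is one call:

```{r}
res <- find_hot_zones(rs, method = "overlap", acc_type = "tf", w = 0,
                      spec = threshold_spec("absolute", 2))
res
zone_length_stats(res$hot)[c("n", "mean", "median")]
```

## Evaluation helpers

`overlap_summary()` reports, for a zone set against an annotation set
(promoters, CpG islands, ...), how many zones hit at least one feature and
vice versa — "overlap" always means at least one shared base, the same
convention as the merging rule. `method_concordance()` is the
one-directional fraction, used e.g. to quantify the agreement of the two
search methods. `conserved_exclusive()` partitions each sample's zones
into those overlapping at least one zone of *every* other sample
(conserved), none (exclusive), or some (other) — the typical cross-cell-
line comparison. No minimum-overlap-fraction option and no enrichment
testing are in scope.

## Synthetic data

`random_regions()` draws uniformly positioned, uniformly sized regions on
one chromosome, guarantees every TF label is used, and can force a chosen
fraction of regions to overlap an earlier one (`overlap_rate`, default
0.3 — overlaps are what make the accumulation types diverge, so tests need
them at a controlled rate). Defaults (50 regions, 4 TFs, 10 kb span,
lengths 20–200 bases) give peak densities where all three strategies and
both methods produce non-trivial structure at desk scale. The generator is
seeded and leaves the session RNG untouched.

What it deliberately does **not** emulate: realistic peak length and
inter-peak distance distributions, chromosome-specific density, signal
strength columns, or read-level noise. Passing tests therefore demonstrate
algorithmic correctness (engine = literal definition, invariants, method
containment), not biological recall on real ChIP-seq collections.

## Problem sizes and validation scale

The test suite validates the engine against the naive per-base oracle on
randomized instances up to 100 regions over ~10 kb spans for
$w \in \{0, 1, 7, 250, 1000\}$, and runs both full pipelines on a
5-TF, 5000-region, 2 Mb dataset as a scaled-down analog of a bulk
multi-TF analysis; these sizes exercise every code path (clamping, window
overhang, per-TF merging, pooled thresholds) while keeping the whole suite
fast. Genome-scale collections (millions of peaks) reduce to the same Rle
operations and are limited by memory on the number of runs, not by any
per-base array.

## Known limitations

* Strand is read and preserved but ignored in all computations; the
  methodology is strand-agnostic.
* narrowPeak files carry no TF column, so a TF name must be supplied
  explicitly per file — there is no filename guessing.
* Chromosome names are opaque labels; no assembly registry, so windows are
  unclamped on the right (positions beyond the last region are simply
  zero).
* The two thresholding procedures assume integer accumulation indexes;
  fractional-occupancy scores are out of scope, as are WARM/COLD zone
  classifications and association (Fisher) testing against annotations.
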