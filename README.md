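# hotzones

Identification of transcription factor high accumulation (HOT) DNA zones
from ChIP-seq-derived binding regions.

## What it does

Genomic regions bound by unusually many distinct transcription factors
(TFs) — *high occupancy target* (HOT) zones — mark open, highly regulated
chromatin (promoters, CpG islands) and are of direct interest in gene
regulation and disease studies. Given a table of TF binding regions
(chromosome, start, end, strand, TF; 1-based inclusive coordinates),
`hotzones`:

1. computes an exact per-base **accumulation vector** per chromosome
   (run-length encoded), under one of three strategies evaluated on the
   symmetric moving window `[max(1, b−w), b+w]` of semi-width `w`:
   - `tf` — distinct TFs with a region intersecting the window,
     `TF_acc(b) = #{t : ∃ r∈t, r ∩ [b−w, b+w] ≠ ∅}`;
   - `region` — regions intersecting the window,
     `BR_acc(b) = #{r : r ∩ [b−w, b+w] ≠ ∅}`;
   - `base` — region bases inside the window, `GB_acc(b) = Σ_r |r ∩
     [b−w, b+w]|`;
2. extracts **dense zones** by either the *binding region* method
   (transitively merge regions sharing ≥ 1 base; index = distinct TFs
   bound inside) or the *overlap* method (maximal runs of constant
   non-zero accumulation; index = the run value);
3. selects **HOT zones** as dense zones with index ≥ a data-driven
   threshold: *top k percentage* (minimum index of the top ⌈k/100·N⌉
   zones) or *over k standard deviations* (⌈mean + k·sd⌉ of the non-zero
   per-base accumulation), with zone length statistics
   (min/max/mean/median/sd) reported alongside.

Region and zone sets are plain `GRanges`, tracks are integer `RleList`s,
so everything interoperates with the usual Bioconductor toolchain.
Annotation-overlap summaries, cross-method concordance and
conserved/exclusive partitions across samples are included, as are a
seeded synthetic-data generator and a brute-force per-base oracle.

## Worked example

The built-in ten-region, three-TF dataset has two same-TF (Z) regions
overlapping exactly in [4250, 4500]:

```r
library(hotzones)
rs <- fig3_regions()

track_value(accumulation_track(rs, "tf",     w = 0), "chr1", 4300)
#> [1] 2          # TFs Y and Z bind there; Z's two regions count once
track_value(accumulation_track(rs, "region", w = 0), "chr1", 4300)
#> [1] 3          # three regions (Y, Z, Z) cover the base
track_value(accumulation_track(rs, "region", w = 1000), "chr1", 3250)
#> [1] 4          # window [2250, 4250] also intercepts the region at 4250
track_value(accumulation_track(rs, "tf",     w = 1000), "chr1", 3250)
#> [1] 3          # saturates at the number of distinct TFs

res <- find_hot_zones(rs, method = "overlap", acc_type = "tf", w = 0,
                      spec = threshold_spec("absolute", 2))
res
#> HOT zone search (overlap method, tf accumulation, w = 0)
#>   input regions: 10
#>   dense zones:   14
#>   threshold:     2 (absolute, k = 2)
#>   HOT zones:     6
```

Every HOT zone is a maximal run whose every base is bound by at least two
distinct TFs; the doubly-Z-bound range [4250, 4500] sits inside the
selected [4000, 5000] run. The same pipeline is scriptable:

```sh
Rscript inst/cli/hotzones.R simulate --fig3 --out regions.tsv
Rscript inst/cli/hotzones.R hotfind --input regions.tsv --method overlap \
    --acc-type tf --w 0 --threshold absolute --k 2 --out-prefix out
```

which writes `out.dense.bed`, `out.hot.bed` (BED6, score = accumulation
index), `out.report.json` (zone counts, covered bases, average lengths,
resolved threshold) and a provenance record. Subcommands: `accumulate`,
`hotfind`, `simulate`, `compare`.

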