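#' Built-in ten-region, three-TF example dataset
#'
#' A small fixed dataset of 10 binding regions of three TFs (X, Y, Z) on one
#' chromosome, designed so that the only same-TF overlap is between the two
#' Z regions, which share exactly the range \[4250, 4500\]. On that range,
#' with `w = 0`, TF accumulation is 2 (TFs Y and Z) while region and base
#' accumulation are 3; with `w = 1000`, region accumulation at base 3250 is
#' 4 (the window \[2250, 4250\] intercepts the starting base of the region
#' at \[4250, 6000\]) whereas TF accumulation there is 3, the maximum
#' possible with three TFs. This makes the dataset a compact worked example
#' of how the accumulation strategies and the moving window differ.
#'
#' @return a region set of 10 regions, 3 TFs, chromosome `"chr1"`.
#' @export
fig3_regions <- function() {
  region_set(
    chrom = rep("chr1", 10),
    start = c(100, 300, 500, 2300, 2800, 4000, 4250, 6500, 6800, 7200),
    end   = c(600, 900, 1100, 2600, 4500, 5000, 6000, 7000, 7400, 7800),
    tf    = c("X", "Y", "Z", "X", "Z", "Y", "Z", "X", "Y", "Z")
  )
}

#' Generate a random synthetic region set
#'
#' Draws `n_regions` binding regions on one chromosome, with lengths uniform
#' in `length_range` and starts uniform over `[1, span]`. TF labels
#' (`TF1 ... TFn`) are assigned so that every TF is used at least once and
#' the rest are drawn uniformly. With `overlap_rate > 0`, that fraction of
#' regions is instead anchored near a previously placed region so its
#' interval overlaps it, letting tests exercise same-TF and cross-TF
#' overlaps at a controlled rate. The RNG state of the session is left
#' untouched; the same seed always yields an identical region set.
#'
#' @param n_regions number of regions (`>= n_tfs`).
#' @param n_tfs number of distinct TFs (`>= 1`).
#' @param span genomic extent in bases over which starts are drawn.
#' @param length_range integer `c(min, max)` uniform bounds on region
#'   length, `min >= 1`.
#' @param overlap_rate fraction in `[0, 1]` of regions forced to overlap an
#'   earlier region.
#' @param seed RNG seed (required: the seed is part of the dataset's
#'   identity).
#' @param chrom chromosome name.
#' @return a region set.
#' @export
random_regions <- function(n_regions = 50, n_tfs = 4, span = 10000,
                           length_range = c(20, 200), overlap_rate = 0.3,
                           seed, chrom = "chr1") {
  if (missing(seed)) hz_stop_usage("'seed' is required")
  if (n_tfs < 1 || n_regions < n_tfs) {
    hz_stop_usage("need n_regions >= n_tfs >= 1")
  }
  if (length_range[1] < 1 || length_range[2] < length_range[1]) {
    hz_stop_usage("invalid length_range")
  }
  if (overlap_rate < 0 || overlap_rate > 1) {
    hz_stop_usage("overlap_rate must be in [0, 1]")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  tfs <- paste0("TF", seq_len(n_tfs))
  labels <- c(tfs, sample(tfs, n_regions - n_tfs, replace = TRUE))
  labels <- sample(labels)   # shuffle so the guaranteed copies are anywhere
  len <- sample(seq(length_range[1], length_range[2]), n_regions,
                replace = TRUE)
  start <- sample.int(span, n_regions, replace = TRUE)
  if (overlap_rate > 0 && n_regions > 1) {
    n_overlap <- floor(overlap_rate * n_regions)
    if (n_overlap > 0) {
      anchored <- sample(seq(2, n_regions), min(n_overlap, n_regions - 1))
      for (i in anchored) {
        j <- sample.int(i - 1, 1)
        # start inside region j so the two intervals share at least one base
        start[i] <- start[j] + sample.int(len[j], 1) - 1L
      }
    }
  }
  region_set(rep(chrom, n_regions), start, start + len - 1L, tf = labels)
}

#' Brute-force per-base accumulation oracle
#'
#' Literal evaluation of the three accumulation definitions by looping over
#' the input regions for each queried base: the number of distinct TFs with
#' a region intersecting the window `[max(1, b - w), b + w]` (`"tf"`), the
#' number of regions intersecting it (`"region"`), or the summed sizes of
#' the region/window intersections (`"base"`). Independent of the run-length
#' machinery of [accumulation_track()]; intended as ground truth in
#' validation, not for genome-scale use.
#'
#' @param regions a region set.
#' @param acc_type `"tf"`, `"region"` or `"base"`.
#' @param w moving-window semi-width.
#' @param b vector of 1-based positions to evaluate.
#' @param chrom chromosome to evaluate on (default: the region set's first).
#' @return integer vector of accumulation values, one per element of `b`.
#' @export
naive_accumulation <- function(regions, acc_type = c("tf", "region", "base"),
                               w = 0L, b, chrom = NULL) {
  acc_type <- match.arg(acc_type)
  w <- check_w(w)
  stopifnot(all(b >= 1))
  if (is.null(chrom)) chrom <- as.character(seqnames(regions))[1]
  gr <- regions[as.character(seqnames(regions)) == chrom]
  lo <- pmax(1, b - w)
  hi <- b + w
  acc <- numeric(length(b))
  if (acc_type == "tf") {
    for (t in unique(mcols(gr)$tf)) {
      rt <- gr[mcols(gr)$tf == t]
      bound <- rep(FALSE, length(b))
      for (i in seq_along(rt)) {
        bound <- bound | (start(rt)[i] <= hi & end(rt)[i] >= lo)
      }
      acc <- acc + bound
    }
  } else if (acc_type == "region") {
    for (i in seq_along(gr)) {
      acc <- acc + (start(gr)[i] <= hi & end(gr)[i] >= lo)
    }
  } else {
    for (i in seq_along(gr)) {
      acc <- acc + pmax(0, pmin(end(gr)[i], hi) - pmax(start(gr)[i], lo) + 1)
    }
  }
  as.integer(acc)
}
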