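# Brute-force reference implementations used as independent ground truth.
# They work per base on materialized vectors (via the package's literal
# naive_accumulation oracle or plain R loops) and never touch the Rle /
# coverage machinery under test.

# full naive accumulation vector over positions 1..L of one chromosome
naive_track_vector <- function(rs, acc_type, w, chrom = NULL) {
  if (is.null(chrom)) chrom <- as.character(GenomicRanges::seqnames(rs))[1]
  gr <- rs[as.character(GenomicRanges::seqnames(rs)) == chrom]
  L <- max(GenomicRanges::end(gr)) + w
  naive_accumulation(rs, acc_type, w, b = seq_len(L), chrom = chrom)
}

# maximal non-zero constant runs of a per-base vector, by base R rle()
runs_from_vector <- function(v, chrom = "chr1") {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values > 0
  data.frame(chrom = chrom, start = starts[keep], end = ends[keep],
             value = r$values[keep])
}

# brute-force binding-region zones: per-base union occupancy -> runs; the
# index of each zone is counted by scanning the regions it contains
brute_binding_zones <- function(rs, chrom = NULL) {
  if (is.null(chrom)) chrom <- as.character(GenomicRanges::seqnames(rs))[1]
  gr <- rs[as.character(GenomicRanges::seqnames(rs)) == chrom]
  L <- max(GenomicRanges::end(gr))
  occupied <- logical(L)
  for (i in seq_along(gr)) {
    occupied[GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]] <- TRUE
  }
  runs <- runs_from_vector(as.integer(occupied), chrom)
  runs$value <- vapply(seq_len(nrow(runs)), function(z) {
    inside <- GenomicRanges::start(gr) <= runs$end[z] &
      GenomicRanges::end(gr) >= runs$start[z]
    length(unique(S4Vectors::mcols(gr)$tf[inside]))
  }, integer(1))
  runs
}

# quadratic all-pairs interval overlap check (1-based inclusive)
brute_any_overlap <- function(s1, e1, s2, e2) {
  vapply(seq_along(s1), function(i) any(s1[i] <= e2 & e1[i] >= s2),
         logical(1))
}

zones_df <- function(z) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(z)),
             start = GenomicRanges::start(z), end = GenomicRanges::end(z),
             value = S4Vectors::mcols(z)$index)
}

# a seeded random instance plus the same instance with all same-TF overlaps
# removed (keeps, per TF, a maximal prefix of mutually disjoint regions)
drop_same_tf_overlaps <- function(rs) {
  keep <- logical(length(rs))
  for (t in unique(S4Vectors::mcols(rs)$tf)) {
    idx <- which(S4Vectors::mcols(rs)$tf == t)
    taken_s <- integer(0); taken_e <- integer(0)
    for (i in idx) {
      s <- GenomicRanges::start(rs)[i]; e <- GenomicRanges::end(rs)[i]
      if (!any(s <= taken_e & e >= taken_s)) {
        keep[i] <- TRUE
        taken_s <- c(taken_s, s); taken_e <- c(taken_e, e)
      }
    }
  }
  rs[keep]
}

expect_tracks_equal_oracle <- function(rs, acc_type, w, chrom = "chr1") {
  tr <- accumulation_track(rs, acc_type, w)
  v_engine <- track_value(tr, chrom,
                          seq_len(length(tr[[chrom]])))
  v_oracle <- naive_track_vector(rs, acc_type, w, chrom)
  expect_identical(v_engine, v_oracle,
                   label = sprintf("engine track (%s, w=%d)", acc_type, w))
}
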