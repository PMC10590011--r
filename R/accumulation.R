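#' Compute per-base accumulation tracks
#'
#' For every chromosome, builds the accumulation vector: an exact
#' run-length-encoded integer function of base position. The value at base
#' `b` depends on the symmetric moving window `[max(1, b - w), b + w]` of
#' semi-width `w` and the chosen quantification strategy:
#'
#' * `"tf"` — number of distinct TFs having at least one binding region that
#'   intersects the window (TF accumulation);
#' * `"region"` — number of input binding regions intersecting the window
#'   (binding region accumulation);
#' * `"base"` — total number of bases of input binding regions falling in
#'   the window, summed over all regions with multiplicity (genomic base
#'   accumulation).
#'
#' With `w = 0` the three strategies agree at every base unless two regions
#' of the same TF overlap, in which case region and base accumulation exceed
#' TF accumulation there. The window is clamped at position 1 on the left;
#' the right side is unbounded (no chromosome length is assumed, the input
#' regions define the extent: positions beyond `max(end) + w` are zero).
#'
#' Computation uses coverage of the `w`-expanded intervals (per-TF merged
#' for `"tf"`, raw for `"region"`) and an exact sliding-window running sum
#' of the multiplicity coverage for `"base"`; no per-base vector is ever
#' materialized.
#'
#' @param regions a region set (see [region_set()]).
#' @param acc_type `"tf"`, `"region"` or `"base"`.
#' @param w moving-window semi-width in bases, integer `>= 0`. `w = 0`
#'   evaluates each base in isolation.
#' @param chroms optional character vector restricting the analysis to these
#'   chromosomes.
#' @return an integer `RleList` (one run-length vector per chromosome,
#'   position 1 = base 1), with `metadata()` fields `acc_type` and `w`.
#' @examples
#' rs <- fig3_regions()
#' tr <- accumulation_track(rs, "tf", w = 0)
#' track_value(tr, "chr1", c(4250, 4375, 4500))  # 2 2 2
#' @export
accumulation_track <- function(regions, acc_type = c("tf", "region", "base"),
                               w = 0L, chroms = NULL) {
  acc_type <- match.arg(acc_type)
  w <- check_w(w)
  if (!is.null(chroms)) {
    regions <- regions[as.character(seqnames(regions)) %in% chroms]
    chrom_names <- sort(unique(chroms))
  } else {
    chrom_names <- GenomeInfoDb::seqlevels(regions)
  }
  tracks <- lapply(chrom_names, function(chr) {
    chrom_accumulation(regions[as.character(seqnames(regions)) == chr],
                       acc_type, w)
  })
  names(tracks) <- chrom_names
  out <- methods::as(tracks, "SimpleRleList")
  metadata(out) <- list(acc_type = acc_type, w = w)
  out
}

check_w <- function(w) {
  if (length(w) != 1 || is.na(w) || w < 0 || w != floor(w)) {
    hz_stop_usage("'w' must be a single integer >= 0")
  }
  as.integer(w)
}

# accumulation vector for the regions of a single chromosome
chrom_accumulation <- function(gr, acc_type, w) {
  if (length(gr) == 0) return(Rle(integer(0)))
  len <- max(end(gr)) + w
  if (acc_type == "base") {
    cov0 <- coverage(ranges(gr), width = max(end(gr)))
    if (w == 0L) return(cov0)
    # pad with w zeros on each conceptual side so the centred running sum of
    # width 2w + 1 realizes sum(cov0[b - w .. b + w]) with zeros off the ends
    padded <- c(Rle(0L, w), cov0, Rle(0L, 2L * w))
    k <- 2L * w + 1L
    if (as.double(k) * max(runValue(cov0)) > .Machine$integer.max) {
      runValue(padded) <- as.double(runValue(padded))
    }
    return(runsum(padded, k = k, endrule = "drop"))
  }
  ir <- IRanges(pmax(1L, start(gr) - w), end(gr) + w)
  if (acc_type == "tf") {
    # count each TF at most once per base: merge its expanded intervals first
    ir <- unlist(reduce(S4Vectors::split(ir, mcols(gr)$tf)), use.names = FALSE)
  }
  coverage(ir, width = len)
}

#' Read track values at given positions
#'
#' @param tracks an `RleList` from [accumulation_track()].
#' @param chrom chromosome name.
#' @param positions 1-based base positions; positions beyond the stored
#'   extent (where the track is implicitly zero) return 0.
#' @return integer vector of accumulation values.
#' @export
track_value <- function(tracks, chrom, positions) {
  if (!chrom %in% names(tracks)) return(rep(0L, length(positions)))
  x <- tracks[[chrom]]
  out <- rep(0L, length(positions))
  inside <- positions >= 1 & positions <= length(x)
  if (any(inside)) out[inside] <- as.integer(x[positions[inside]])
  out
}

#' Pooled statistics of non-zero accumulation values
#'
#' Considering all and only the bases with non-zero accumulation, pooled
#' across the supplied chromosome tracks (each base weighted once), returns
#' their count, mean, standard deviation (sample convention, n - 1; 0 when a
#' single base qualifies) and the maximum accumulation value. These are the
#' inputs of the over-k-standard-deviations thresholding procedure.
#'
#' @param tracks an `RleList` from [accumulation_track()].
#' @return a list with `n_nonzero_bases`, `mean`, `sd`, `max_value`
#'   (`mean`/`sd`/`max_value` are `NA` when no base has non-zero
#'   accumulation).
#' @export
accumulation_stats <- function(tracks) {
  vals <- lapply(tracks, function(x) {
    keep <- runValue(x) > 0
    list(v = as.double(runValue(x)[keep]), l = as.double(runLength(x)[keep]))
  })
  v <- unlist(lapply(vals, `[[`, "v"))
  l <- unlist(lapply(vals, `[[`, "l"))
  n <- sum(l)
  if (n == 0) {
    return(structure(list(n_nonzero_bases = 0, mean = NA_real_,
                          sd = NA_real_, max_value = NA_real_),
                     class = "accumulation_stats"))
  }
  m <- sum(v * l) / n
  s <- if (n > 1) sqrt((sum(v^2 * l) - n * m^2) / (n - 1)) else 0
  structure(list(n_nonzero_bases = n, mean = m, sd = max(s, 0),
                 max_value = max(v)),
            class = "accumulation_stats")
}

#' @export
print.accumulation_stats <- function(x, ...) {
  cat(sprintf(
    "accumulation over %d non-zero bases: mean %.4f, sd %.4f, max %g\n",
    x$n_nonzero_bases, x$mean, x$sd, x$max_value))
  invisible(x)
}

#' Maximal non-zero constant runs of a track collection
#'
#' @param tracks an `RleList` from [accumulation_track()].
#' @return a data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive) and `value`, one row per maximal run with value > 0.
#' @export
track_segments <- function(tracks) {
  per_chrom <- lapply(names(tracks), function(chr) {
    x <- tracks[[chr]]
    if (length(x) == 0) return(NULL)
    ends <- cumsum(as.double(runLength(x)))
    starts <- ends - as.double(runLength(x)) + 1
    keep <- runValue(x) > 0
    if (!any(keep)) return(NULL)
    data.frame(chrom = chr, start = starts[keep], end = ends[keep],
               value = as.double(runValue(x)[keep]))
  })
  out <- do.call(rbind, per_chrom)
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), start = double(0),
                      end = double(0), value = double(0))
  }
  rownames(out) <- NULL
  out
}

#' Export a track collection as bedGraph
#'
#' One line per maximal non-zero constant run, 0-based half-open
#' coordinates.
#'
#' @param tracks an `RleList` from [accumulation_track()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_bedgraph <- function(tracks, path) {
  seg <- track_segments(tracks)
  lines <- if (nrow(seg) == 0) character(0) else
    paste(seg$chrom, format(seg$start - 1, scientific = FALSE, trim = TRUE),
          format(seg$end, scientific = FALSE, trim = TRUE),
          format(seg$value, scientific = FALSE, trim = TRUE), sep = "\t")
  writeLines(c("track type=bedGraph", lines), path)
  invisible(path)
}
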