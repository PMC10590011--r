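#' Dense zones by the binding region method
#'
#' Input binding regions sharing at least one base are transitively merged
#' into maximal zones (book-ended regions stay separate: adjacency is not
#' overlap). Each zone's accumulation index is the number of distinct TFs
#' with at least one region inside it, so the index is always greater than
#' or equal to the maximum per-base TF accumulation (at `w = 0`) within the
#' zone. The moving window plays no role here: the zones are built from the
#' original input regions without any neighborhood.
#'
#' @param regions a region set (see [region_set()]).
#' @return a zone set: sorted `GRanges` with an integer `index` metadata
#'   column and `metadata()` fields `method`, `acc_type`, `w`.
#' @examples
#' rs <- region_set(c("chr1", "chr1"), c(1, 5), c(10, 20),
#'                  tf = c("X", "Y"))
#' binding_region_zones(rs)  # one zone [1, 20] with index 2
#' @export
binding_region_zones <- function(regions) {
  zones <- reduce(granges(regions), min.gapwidth = 0L)
  if (length(zones) > 0) {
    hits <- findOverlaps(regions, zones)
    idx <- tapply(mcols(regions)$tf[queryHits(hits)], subjectHits(hits),
                  function(tfs) length(unique(tfs)))
    index <- integer(length(zones))
    index[as.integer(names(idx))] <- as.integer(idx)
    mcols(zones)$index <- index
  } else {
    mcols(zones)$index <- integer(0)
  }
  metadata(zones) <- list(method = "binding_region", acc_type = "tf", w = 0L)
  sort(zones)
}

#' Dense zones by the overlap method
#'
#' Extracts one zone per maximal run of contiguous bases sharing the same
#' non-zero accumulation value; the run's value is inherited as the zone's
#' accumulation index. Zones tile the non-zero support of the track exactly,
#' and adjacent zones always carry different indexes.
#'
#' @param tracks an `RleList` from [accumulation_track()].
#' @return a zone set (see [binding_region_zones()] for the layout), whose
#'   metadata records the track's accumulation type and window semi-width.
#' @export
overlap_zones <- function(tracks) {
  seg <- track_segments(tracks)
  if (nrow(seg) == 0) {
    zones <- GRanges()
    mcols(zones)$index <- integer(0)
  } else {
    zones <- GRanges(seg$chrom, IRanges(seg$start, seg$end),
                     index = as.integer(seg$value))
  }
  md <- metadata(tracks)
  metadata(zones) <- list(method = "overlap",
                          acc_type = md$acc_type, w = md$w)
  GenomeInfoDb::seqlevels(zones) <- sort(GenomeInfoDb::seqlevels(zones))
  sort(zones)
}

#' Zone length summary statistics
#'
#' @param zones a zone set.
#' @return list with `n`, `min`, `max`, `mean`, `median`, `sd` of zone
#'   lengths in bases (statistics are `NA` for an empty set; `sd` is `NA`
#'   for a single zone).
#' @export
zone_length_stats <- function(zones) {
  len <- width(zones)
  if (length(len) == 0) {
    return(list(n = 0L, min = NA_real_, max = NA_real_, mean = NA_real_,
                median = NA_real_, sd = NA_real_))
  }
  list(n = length(len), min = min(len), max = max(len), mean = mean(len),
       median = median(len), sd = if (length(len) > 1) sd(len) else NA_real_)
}

#' Specify a thresholding procedure
#'
#' Two data-driven procedures plus an absolute escape hatch:
#'
#' * `"top_k_pct"` — sort zones by accumulation index, take the top
#'   `ceiling(k / 100 * N)` zones, and use the minimum index among them as
#'   the threshold (ties are then never split, since selection is by index).
#'   Requires `0 < k <= 100`. Larger `k` never yields fewer HOT zones.
#' * `"k_std"` — `ceiling(mean + k * sd)` of the per-base accumulation over
#'   all (and only) the bases with non-zero accumulation. Requires `k >= 0`;
#'   larger `k` never yields more HOT zones.
#' * `"absolute"` — use `k` itself (integer `>= 1`) as the threshold.
#'
#' @param procedure `"top_k_pct"`, `"k_std"` or `"absolute"`.
#' @param k the procedure's parameter.
#' @return a `threshold_spec` object.
#' @export
threshold_spec <- function(procedure = c("top_k_pct", "k_std", "absolute"),
                           k) {
  procedure <- match.arg(procedure)
  if (length(k) != 1 || is.na(k) || !is.numeric(k)) {
    hz_stop_usage("'k' must be a single number")
  }
  ok <- switch(procedure,
    top_k_pct = k > 0 && k <= 100,
    k_std = k >= 0,
    absolute = k >= 1 && k == floor(k))
  if (!ok) {
    hz_stop_usage("invalid k = ", k, " for procedure '", procedure,
                  "' (top_k_pct: 0 < k <= 100; k_std: k >= 0; ",
                  "absolute: integer k >= 1)")
  }
  structure(list(procedure = procedure, k = k), class = "threshold_spec")
}

#' Resolve a threshold specification to a numeric threshold
#'
#' @param spec a [threshold_spec()].
#' @param zones the dense zone set (required for `"top_k_pct"`).
#' @param stats an [accumulation_stats()] result over the relevant track
#'   (required for `"k_std"`).
#' @return a `threshold_result`: list with `procedure`, `k`, `threshold`
#'   (positive integer) and the quantities it was derived from.
#' @export
resolve_threshold <- function(spec, zones = NULL, stats = NULL) {
  stopifnot(inherits(spec, "threshold_spec"))
  out <- list(procedure = spec$procedure, k = spec$k)
  if (spec$procedure == "top_k_pct") {
    if (is.null(zones) || length(zones) == 0) {
      hz_stop_data("top_k_pct thresholding needs a non-empty dense zone set")
    }
    idx <- sort(mcols(zones)$index, decreasing = TRUE)
    m <- ceiling(spec$k / 100 * length(idx))
    out$n_zones <- length(idx)
    out$n_top <- m
    out$threshold <- as.integer(idx[m])
  } else if (spec$procedure == "k_std") {
    if (is.null(stats) || stats$n_nonzero_bases == 0) {
      hz_stop_data("k_std thresholding needs bases with non-zero ",
                   "accumulation")
    }
    out$mean <- stats$mean
    out$sd <- stats$sd
    out$threshold <- as.integer(ceiling(stats$mean + spec$k * stats$sd))
  } else {
    out$threshold <- as.integer(spec$k)
  }
  structure(out, class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("threshold %d (%s, k = %g)\n", x$threshold, x$procedure, x$k))
  invisible(x)
}

#' Select HOT zones from a dense zone set
#'
#' HOT zones are the dense zones whose accumulation index is at least equal
#' to the threshold (inclusive comparison, so index ties at the threshold
#' are never split and the selection may exceed k% of the zones under
#' top-k-percentage thresholding).
#'
#' @param zones a dense zone set.
#' @param threshold a `threshold_result` from [resolve_threshold()], or a
#'   bare positive integer.
#' @return the HOT zone set, with the resolved threshold recorded in its
#'   `metadata()`.
#' @export
select_hot <- function(zones, threshold) {
  thr <- if (inherits(threshold, "threshold_result")) threshold$threshold
         else as.integer(threshold)
  if (is.na(thr) || thr < 1) hz_stop_usage("threshold must be >= 1")
  hot <- zones[mcols(zones)$index >= thr]
  md <- metadata(zones)
  md$threshold <- thr
  metadata(hot) <- md
  hot
}

#' Full HOT zone search
#'
#' Orchestrates the whole procedure: accumulation track computation, dense
#' zone identification by the chosen method, data-driven threshold
#' resolution and HOT zone selection.
#'
#' For the overlap method the dense zones are the maximal constant-value
#' runs of the `acc_type` track at semi-width `w`. For the binding region
#' method the dense zones are the merged input regions scored by distinct
#' bound TFs (`acc_type` and `w` do not shape those zones); when the k-std
#' threshold is requested, its base statistics are taken from the TF
#' accumulation track at the same `w`, matching the distinct-TF scale of the
#' zone indexes.
#'
#' By default zones and base statistics are pooled across chromosomes into a
#' single genome-wide threshold; with `per_chromosome = TRUE` the full
#' search runs independently on each chromosome and a named list of results
#' is returned.
#'
#' @param regions a region set.
#' @param method `"overlap"` or `"binding_region"`.
#' @param acc_type accumulation strategy for the overlap method (and
#'   reported in provenance); see [accumulation_track()].
#' @param w moving-window semi-width; 1000 bases is the suggested value for
#'   smoothing ChIP-seq discontinuities without aggregating distant bases.
#' @param spec a [threshold_spec()]; default: top 1 percent of zones.
#' @param chroms optional chromosome filter.
#' @param per_chromosome run the search per chromosome instead of pooled.
#' @return a `hot_zone_result`: list with `dense` (zone set), `hot` (zone
#'   set), `threshold` (`threshold_result`), `stats` (per-base accumulation
#'   statistics or `NULL`), and the call parameters. With
#'   `per_chromosome = TRUE`, a named list of such objects.
#' @examples
#' res <- find_hot_zones(fig3_regions(), method = "overlap", acc_type = "tf",
#'                       w = 0, spec = threshold_spec("absolute", 2))
#' res$hot
#' @export
find_hot_zones <- function(regions,
                           method = c("overlap", "binding_region"),
                           acc_type = c("tf", "region", "base"),
                           w = 1000L,
                           spec = threshold_spec("top_k_pct", 1),
                           chroms = NULL, per_chromosome = FALSE) {
  method <- match.arg(method)
  acc_type <- match.arg(acc_type)
  w <- check_w(w)
  if (per_chromosome) {
    use <- if (is.null(chroms)) GenomeInfoDb::seqlevels(regions) else chroms
    res <- lapply(use, function(chr) {
      find_hot_zones(regions, method, acc_type, w, spec, chroms = chr,
                     per_chromosome = FALSE)
    })
    names(res) <- use
    return(res)
  }
  if (!is.null(chroms)) {
    regions <- regions[as.character(seqnames(regions)) %in% chroms]
  }
  stats <- NULL
  if (method == "overlap") {
    tracks <- accumulation_track(regions, acc_type, w, chroms)
    dense <- overlap_zones(tracks)
    if (spec$procedure == "k_std") stats <- accumulation_stats(tracks)
  } else {
    dense <- binding_region_zones(regions)
    if (spec$procedure == "k_std") {
      stats <- accumulation_stats(accumulation_track(regions, "tf", w,
                                                     chroms))
    }
  }
  if (length(dense) == 0 && spec$procedure != "absolute") {
    hz_stop_data("no dense zones found; cannot resolve a data-driven ",
                 "threshold")
  }
  thr <- resolve_threshold(spec, zones = dense, stats = stats)
  hot <- select_hot(dense, thr)
  structure(list(dense = dense, hot = hot, threshold = thr, stats = stats,
                 method = method, acc_type = acc_type, w = w, spec = spec,
                 n_input_regions = n_regions(regions)),
            class = "hot_zone_result")
}

#' @export
print.hot_zone_result <- function(x, ...) {
  cat(sprintf("HOT zone search (%s method, %s accumulation, w = %d)\n",
              x$method, x$acc_type, x$w))
  cat(sprintf("  input regions: %d\n", x$n_input_regions))
  cat(sprintf("  dense zones:   %d\n", length(x$dense)))
  cat(sprintf("  threshold:     %d (%s, k = %g)\n", x$threshold$threshold,
              x$threshold$procedure, x$threshold$k))
  cat(sprintf("  HOT zones:     %d\n", length(x$hot)))
  invisible(x)
}

#' Tabular report of a HOT zone search
#'
#' Summarizes a [find_hot_zones()] result with the standard reporting
#' columns: input regions, moving window, dense zone count / covered bases /
#' average length, maximum accumulation index, threshold procedure and
#' resolved value, and HOT zone count / covered bases / average length plus
#' full length statistics.
#'
#' @param result a `hot_zone_result`.
#' @return a named list, ready for JSON serialization.
#' @export
zone_report <- function(result) {
  stopifnot(inherits(result, "hot_zone_result"))
  dense_stats <- zone_length_stats(result$dense)
  hot_stats <- zone_length_stats(result$hot)
  list(
    input_regions = result$n_input_regions,
    method = result$method,
    acc_type = result$acc_type,
    moving_window = result$w,
    dense_zones = length(result$dense),
    dense_bases = sum(as.double(width(result$dense))),
    dense_zone_avg_length = dense_stats$mean,
    max_index = if (length(result$dense) > 0)
      max(mcols(result$dense)$index) else NA,
    threshold_procedure = result$threshold$procedure,
    threshold_k = result$threshold$k,
    threshold = result$threshold$threshold,
    hot_zones = length(result$hot),
    hot_bases = sum(as.double(width(result$hot))),
    hot_zone_avg_length = hot_stats$mean,
    hot_zone_length_stats = hot_stats
  )
}
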