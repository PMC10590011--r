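#' Build a validated set of TF binding regions
#'
#' A region set is a `GRanges` with a `tf` metadata column, using 1-based
#' inclusive coordinates (the native GenomicRanges convention: `start` and
#' `end` both number real bases and both belong to the region). Regions are
#' sorted deterministically by chromosome, start, end and TF name; duplicate
#' rows are retained, as repeated identical binding regions are distinct
#' observations for region- and base-level accumulation.
#'
#' @param chrom chromosome names, or a `GRanges` already carrying a `tf`
#'   metadata column (in which case the remaining arguments are ignored).
#' @param start,end 1-based inclusive positions, `start >= 1`, `start <= end`.
#' @param tf transcription factor name per region (non-empty after trimming).
#' @param strand `"+"`, `"-"` or `"*"`; kept for provenance, ignored by all
#'   accumulation computations.
#' @return a sorted `GRanges` with a `tf` metadata column.
#' @examples
#' rs <- region_set(c("chr1", "chr1"), c(100, 150), c(200, 250),
#'                  tf = c("CTCF", "JUN"))
#' n_regions(rs)
#' tf_names(rs)
#' @export
region_set <- function(chrom, start = NULL, end = NULL, tf = NULL,
                       strand = "*") {
  if (is(chrom, "GRanges")) {
    gr <- chrom
    if (is.null(mcols(gr)$tf)) {
      hz_stop_data("GRanges input must carry a 'tf' metadata column")
    }
    gr <- GRanges(as.character(seqnames(gr)),
                  IRanges(start(gr), end(gr)),
                  strand = as.character(strand(gr)),
                  tf = as.character(mcols(gr)$tf))
  } else {
    if (length(start) == 0 && length(chrom) == 0) {
      gr <- GRanges()
      mcols(gr)$tf <- character(0)
    } else {
      strand <- normalize_strand(strand)
      gr <- GRanges(as.character(chrom), IRanges(as.integer(start),
                                                 as.integer(end)),
                    strand = strand, tf = as.character(tf))
    }
  }
  validate_region_set(gr)
}

normalize_strand <- function(strand) {
  strand <- as.character(strand)
  strand[strand == "."] <- "*"
  strand[strand == "−"] <- "-"   # typeset minus sign
  strand
}

validate_region_set <- function(gr) {
  if (length(gr) == 0) {
    mcols(gr)$tf <- as.character(mcols(gr)$tf)
    return(gr)
  }
  tf <- trimws(as.character(mcols(gr)$tf))
  if (anyNA(tf) || any(tf == "")) {
    hz_stop_data("every region needs a non-empty TF name")
  }
  mcols(gr)$tf <- tf
  if (any(start(gr) < 1L)) {
    hz_stop_data("start positions must be >= 1 (1-based inclusive)")
  }
  if (any(end(gr) < start(gr))) {
    hz_stop_data("found regions with end < start")
  }
  # deterministic order: chromosome (character sort), start, end, tf
  GenomeInfoDb::seqlevels(gr) <- sort(GenomeInfoDb::seqlevels(gr))
  gr[order(as.integer(seqnames(gr)), start(gr), end(gr), mcols(gr)$tf)]
}

#' Number of regions and distinct TF names in a region set
#'
#' @param rs a region set (`GRanges` with `tf` column).
#' @return `n_regions`: integer count of regions; `tf_names`: sorted
#'   character vector of distinct TF names.
#' @export
n_regions <- function(rs) length(rs)

#' @rdname n_regions
#' @export
tf_names <- function(rs) sort(unique(as.character(mcols(rs)$tf)))

#' Read TF binding regions from disk
#'
#' Three dialects are supported. `"tsv"`: whitespace-separated columns
#' `chrom start end strand tf`, 1-based inclusive coordinates (an optional
#' header line and `#` comments are skipped). `"bed"`: BED with 0-based
#' half-open coordinates (converted on read: start + 1, end kept); the TF is
#' taken from the `tf` argument, or from the BED name column when `tf` is
#' `NULL`. `"narrowPeak"`: ENCODE narrowPeak, which has no TF column, so a TF
#' name must be supplied explicitly via `tf`.
#'
#' @param path input file.
#' @param format one of `"tsv"`, `"bed"`, `"narrowPeak"`.
#' @param tf optional single TF name assigned to every region in the file
#'   (required for narrowPeak).
#' @return a validated region set (see [region_set()]).
#' @export
read_regions <- function(path, format = c("tsv", "bed", "narrowPeak"),
                         tf = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) hz_stop_usage("input file not found: ", path)
  switch(format,
    tsv = read_regions_tsv(path),
    bed = read_regions_bed(path, tf),
    narrowPeak = {
      if (is.null(tf)) {
        hz_stop_usage("narrowPeak files carry no TF column; supply 'tf'")
      }
      read_regions_narrowpeak(path, tf)
    })
}

read_regions_tsv <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) return(region_set(character(0)))
  fields <- strsplit(trimws(lines), "\\s+")
  # tolerate a header line: drop line 1 when its start field is not numeric
  if (suppressWarnings(is.na(as.integer(fields[[1]][2])))) {
    fields <- fields[-1]
    lineno <- lineno[-1]
    if (length(fields) == 0) return(region_set(character(0)))
  }
  nf <- lengths(fields)
  if (any(nf != 5L)) {
    hz_stop_data("line ", lineno[which(nf != 5L)[1]],
                 ": expected 5 fields (chrom start end strand tf), got ",
                 nf[which(nf != 5L)[1]])
  }
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) {
    hz_stop_data("line ", lineno[bad[1]], ": non-integer coordinates")
  }
  bad <- which(end < start | start < 1L)
  if (length(bad) > 0) {
    hz_stop_data("line ", lineno[bad[1]], ": invalid interval [",
                 start[bad[1]], ", ", end[bad[1]], "]")
  }
  region_set(m[, 1], start, end, tf = m[, 5], strand = m[, 4])
}

read_regions_bed <- function(path, tf) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) hz_stop_data("BED parse error in ",
                                                  path, ": ",
                                                  conditionMessage(e)))
  if (is.null(tf)) {
    if (is.null(mcols(gr)$name)) {
      hz_stop_data("BED file has no name column to use as TF; supply 'tf'")
    }
    mcols(gr)$tf <- as.character(mcols(gr)$name)
  } else {
    mcols(gr)$tf <- rep(as.character(tf), length.out = length(gr))
  }
  region_set(gr)
}

read_regions_narrowpeak <- function(path, tf) {
  np_cols <- c(signalValue = "numeric", pValue = "numeric",
               qValue = "numeric", peak = "integer")
  gr <- tryCatch(rtracklayer::import(path, format = "BED",
                                     extraCols = np_cols),
                 error = function(e) hz_stop_data("narrowPeak parse error in ",
                                                  path, ": ",
                                                  conditionMessage(e)))
  mcols(gr)$tf <- rep(as.character(tf), length.out = length(gr))
  region_set(gr)
}

#' Write a region set in the native TSV dialect
#'
#' Columns `chrom start end strand tf`, tab-separated, 1-based inclusive,
#' with a header line. `read_regions(path, "tsv")` inverts this exactly.
#'
#' @param rs region set.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_regions <- function(rs, path) {
  df <- data.frame(chrom = as.character(seqnames(rs)), start = start(rs),
                   end = end(rs), strand = as.character(strand(rs)),
                   tf = mcols(rs)$tf)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write and read zone sets
#'
#' `write_zones()` writes a zone set either as BED6 (`"bed"`: coordinates
#' converted to 0-based half-open, i.e. start - 1 and end unchanged; the
#' score column carries the accumulation index) or as a TSV keeping 1-based
#' inclusive coordinates. A JSON sidecar (`<path>.json`) records the zone
#' count, zone length statistics, and — when present in the zone set's
#' metadata — the search method, accumulation type, window semi-width and
#' resolved threshold. `read_zones()` inverts both formats.
#'
#' @param zones a zone set (`GRanges` with an `index` metadata column, as
#'   returned by [binding_region_zones()], [overlap_zones()] or
#'   [select_hot()]).
#' @param path output (or input) file.
#' @param format `"bed"` or `"tsv"`.
#' @param sidecar write the JSON sidecar? (default `TRUE`)
#' @return `write_zones()`: `path` invisibly; `read_zones()`: a zone set.
#' @export
write_zones <- function(zones, path, format = c("bed", "tsv"),
                        sidecar = TRUE) {
  format <- match.arg(format)
  n <- length(zones)
  if (format == "bed") {
    lines <- if (n == 0) character(0) else
      paste(as.character(seqnames(zones)), start(zones) - 1L, end(zones),
            paste0("zone_", seq_len(n)), mcols(zones)$index, ".",
            sep = "\t")
    writeLines(lines, path)
  } else {
    df <- data.frame(chrom = as.character(seqnames(zones)),
                     start = start(zones), end = end(zones),
                     index = if (n == 0) integer(0) else mcols(zones)$index)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (sidecar) {
    md <- metadata(zones)
    stats <- zone_length_stats(zones)
    side <- list(n_zones = n, length_stats = stats)
    for (f in c("method", "acc_type", "w", "threshold")) {
      if (!is.null(md[[f]])) side[[f]] <- md[[f]]
    }
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null", na = "null")
  }
  invisible(path)
}

#' @rdname write_zones
#' @export
read_zones <- function(path, format = c("bed", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) hz_stop_usage("zone file not found: ", path)
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    sc <- mcols(gr)$score
    if (is.null(sc)) sc <- rep(NA_integer_, length(gr))
    z <- GRanges(as.character(seqnames(gr)), IRanges(start(gr), end(gr)),
                 index = as.integer(sc))
  } else {
    df <- read.table(path, header = TRUE, sep = "\t",
                     colClasses = c("character", "integer", "integer",
                                    "integer"))
    z <- GRanges(df$chrom, IRanges(df$start, df$end), index = df$index)
  }
  GenomeInfoDb::seqlevels(z) <- sort(GenomeInfoDb::seqlevels(z))
  sort(z)
}
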