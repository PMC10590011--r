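# put two (or more) GRanges on a shared seqlevel universe so overlap
# counting across samples with disjoint chromosomes stays quiet
align_seqlevels <- function(grs) {
  univ <- sort(unique(unlist(lapply(grs, GenomeInfoDb::seqlevels))))
  lapply(grs, function(g) {
    GenomeInfoDb::seqlevels(g) <- univ
    g
  })
}

#' Two-way overlap summary between zones and annotation features
#'
#' Counts how many zones share at least one base with at least one feature,
#' and symmetrically how many features share at least one base with at
#' least one zone (each element counted once, whatever the number of
#' partners). This is the usual reporting layout for questions such as "how
#' many HOT zones fall in CpG islands, and how many CpG islands contain a
#' HOT zone".
#'
#' @param zones a zone set (`GRanges`).
#' @param features an annotation interval set (`GRanges`), e.g. promoters
#'   or CpG islands, in 1-based inclusive coordinates.
#' @return list with `n_zones`, `n_features`, `zones_hitting_features`,
#'   `zones_hitting_fraction`, `features_hitting_zones`,
#'   `features_hitting_fraction` (fractions are 0 for empty inputs).
#' @export
overlap_summary <- function(zones, features) {
  aligned <- align_seqlevels(list(zones, features))
  zones <- aligned[[1]]; features <- aligned[[2]]
  zh <- if (length(zones) == 0) 0L else
    sum(countOverlaps(zones, features, type = "any") > 0)
  fh <- if (length(features) == 0) 0L else
    sum(countOverlaps(features, zones, type = "any") > 0)
  list(
    n_zones = length(zones),
    n_features = length(features),
    zones_hitting_features = zh,
    zones_hitting_fraction = if (length(zones) > 0) zh / length(zones) else 0,
    features_hitting_zones = fh,
    features_hitting_fraction = if (length(features) > 0)
      fh / length(features) else 0
  )
}

#' Concordance between two zone sets
#'
#' Fraction of the zones of `zonesA` sharing at least one base with a zone
#' of `zonesB` (a one-directional overlap summary, used to quantify the
#' agreement between the two search methods or between window settings).
#'
#' @param zonesA,zonesB zone sets.
#' @return a single fraction in `[0, 1]`; `NA` when `zonesA` is empty.
#' @export
method_concordance <- function(zonesA, zonesB) {
  if (length(zonesA) == 0) return(NA_real_)
  aligned <- align_seqlevels(list(zonesA, zonesB))
  mean(countOverlaps(aligned[[1]], aligned[[2]], type = "any") > 0)
}

#' Conserved and exclusive zones across samples
#'
#' For each sample, partitions its zones into: `conserved` — overlapping
#' (at least partially) at least one zone of *every* other sample;
#' `exclusive` — overlapping no zone of any other sample; `other` — the
#' remainder. The typical use is comparing HOT zones across cell lines.
#'
#' @param zone_sets a named list of at least two zone sets.
#' @return list with `summary` (a data.frame: one row per sample with
#'   counts and fractions) and `zones` (the input zone sets, each with an
#'   added `status` metadata column).
#' @export
conserved_exclusive <- function(zone_sets) {
  if (length(zone_sets) < 2) {
    hz_stop_usage("conserved_exclusive needs at least 2 samples")
  }
  if (is.null(names(zone_sets)) || any(names(zone_sets) == "")) {
    names(zone_sets) <- paste0("sample", seq_along(zone_sets))
  }
  zone_sets <- align_seqlevels(zone_sets)
  out_zones <- list()
  rows <- list()
  for (s in names(zone_sets)) {
    z <- zone_sets[[s]]
    others <- zone_sets[setdiff(names(zone_sets), s)]
    hit <- vapply(others, function(o) countOverlaps(z, o, type = "any") > 0,
                  logical(length(z)))
    if (length(z) == 1) hit <- matrix(hit, nrow = 1)
    if (length(z) == 0) hit <- matrix(logical(0), nrow = 0,
                                      ncol = length(others))
    conserved <- apply(hit, 1, all)
    exclusive <- apply(hit, 1, function(r) !any(r))
    status <- ifelse(conserved, "conserved",
                     ifelse(exclusive, "exclusive", "other"))
    mcols(z)$status <- status
    out_zones[[s]] <- z
    n <- length(z)
    rows[[s]] <- data.frame(
      sample = s, n_zones = n,
      conserved = sum(conserved),
      conserved_fraction = if (n > 0) sum(conserved) / n else 0,
      exclusive = sum(exclusive),
      exclusive_fraction = if (n > 0) sum(exclusive) / n else 0,
      other = sum(!conserved & !exclusive))
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  list(summary = summary, zones = out_zones)
}
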