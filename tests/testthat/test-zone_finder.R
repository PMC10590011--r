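test_that("binding region method merges shared-base regions, not book-ends", {
  rs <- region_set(c("chr1", "chr1"), c(1, 5), c(10, 20), tf = c("X", "Y"))
  z <- binding_region_zones(rs)
  expect_equal(zones_df(z),
               data.frame(chrom = "chr1", start = 1L, end = 20L, value = 2L))
  # adjacency is not overlap: [1,10] and [11,20] stay separate
  rs2 <- region_set(c("chr1", "chr1"), c(1, 11), c(10, 20), tf = c("X", "X"))
  z2 <- binding_region_zones(rs2)
  expect_equal(length(z2), 2)
  expect_equal(mcols(z2)$index, c(1L, 1L))
})

test_that("fixture regions Z-Z-Y merge into one zone scored by 2 TFs", {
  z <- binding_region_zones(fig3_regions())
  big <- z[start(z) == 2800]
  expect_equal(end(big), 6000)
  expect_equal(mcols(big)$index, 2L)   # TFs {Y, Z}
  # brute-force reimplementation agrees on zones and indexes
  expect_equal(zones_df(z), brute_binding_zones(fig3_regions()))
})

test_that("overlap zones are exactly the non-zero constant runs", {
  rs <- fig3_regions()
  z_tf <- overlap_zones(accumulation_track(rs, "tf", 0))
  # [4250,4500] has value 2 throughout; its maximal tf run is [4000,5000]
  run <- z_tf[start(z_tf) <= 4250 & end(z_tf) >= 4500]
  expect_equal(start(run), 4000)
  expect_equal(end(run), 5000)
  expect_equal(mcols(run)$index, 2L)
  # on the region track, [4250,4500] is itself a maximal run, of value 3
  z_rg <- overlap_zones(accumulation_track(rs, "region", 0))
  expect_true(any(start(z_rg) == 4250 & end(z_rg) == 4500 &
                    mcols(z_rg)$index == 3L))
  # empty track
  z0 <- overlap_zones(accumulation_track(rs, "tf", 0, chroms = "chrZ"))
  expect_equal(length(z0), 0)
})

test_that("overlap zones tile the support; adjacent zones differ in index", {
  for (seed in c(31, 32)) {
    rs <- random_regions(n_regions = 40, n_tfs = 4, span = 3000, seed = seed)
    tr <- accumulation_track(rs, "region", 5)
    z <- overlap_zones(tr)
    expect_equal(sum(width(z)), accumulation_stats(tr)$n_nonzero_bases)
    # agree with brute-force run extraction of the naive vector
    expect_equal(zones_df(z),
                 runs_from_vector(naive_track_vector(rs, "region", 5)),
                 ignore_attr = TRUE)
    adj <- which(start(z)[-1] == end(z)[-length(z)] + 1)
    expect_true(all(mcols(z)$index[adj + 1] != mcols(z)$index[adj]))
  }
})

test_that("top-k-percentage threshold takes the minimum of the top slice", {
  z <- GRanges("chr1", IRanges((1:10) * 100, (1:10) * 100 + 10),
               index = 10:1)
  thr <- resolve_threshold(threshold_spec("top_k_pct", 10), zones = z)
  expect_equal(thr$threshold, 10L)   # ceiling(0.1 * 10) = 1 zone, min = 10
  expect_equal(resolve_threshold(threshold_spec("top_k_pct", 100),
                                 zones = z)$threshold, 1L)
  # 25% of 10 zones -> ceiling = 3 zones -> min index among {10, 9, 8}
  expect_equal(resolve_threshold(threshold_spec("top_k_pct", 25),
                                 zones = z)$threshold, 8L)
  expect_error(resolve_threshold(threshold_spec("top_k_pct", 10),
                                 zones = z[0]), "non-empty")
})

test_that("k-std threshold is the ceiling of mean + k * sd", {
  # constant accumulation: sd = 0, threshold = the constant
  st <- accumulation_stats(RleList(chr1 = Rle(5L, 40L)))
  expect_equal(resolve_threshold(threshold_spec("k_std", 2),
                                 stats = st)$threshold, 5L)
  # ten 2s + ten 4s: mean 3, sd sqrt(20/19); k = 2 -> ceiling(5.052) = 6
  st2 <- accumulation_stats(RleList(chr1 = Rle(c(2L, 4L), c(10L, 10L))))
  expect_equal(resolve_threshold(threshold_spec("k_std", 2),
                                 stats = st2)$threshold, 6L)
  empty <- accumulation_stats(RleList(chr1 = Rle(0L, 5L)))
  expect_error(resolve_threshold(threshold_spec("k_std", 1), stats = empty),
               "non-zero")
})

test_that("threshold specs validate their k parameter", {
  expect_error(threshold_spec("top_k_pct", 0), "invalid k")
  expect_error(threshold_spec("top_k_pct", 101), "invalid k")
  expect_error(threshold_spec("k_std", -1), "invalid k")
  expect_error(threshold_spec("absolute", 1.5), "invalid k")
  expect_silent(threshold_spec("k_std", 0))
})

test_that("HOT selection is inclusive and keeps index ties together", {
  z <- GRanges("chr1", IRanges(c(10, 100, 200), c(20, 120, 220)),
               index = c(3L, 3L, 2L))
  hot <- select_hot(z, 3L)
  expect_equal(length(hot), 2)
  expect_true(all(mcols(hot)$index == 3L))
  expect_equal(length(select_hot(z, 1L)), 3)  # threshold 1 is the identity
  expect_equal(length(select_hot(z, 4L)), 0)  # empty result is valid
  expect_equal(metadata(select_hot(z, 3L))$threshold, 3L)
})

test_that("zone length statistics follow the usual conventions", {
  z <- GRanges("chr1", IRanges(c(1, 100, 200, 300), c(10, 119, 229, 339)),
               index = rep(1L, 4))
  st <- zone_length_stats(z)
  expect_equal(st$n, 4)
  expect_equal(st$min, 10)
  expect_equal(st$max, 40)
  expect_equal(st$mean, 25)
  expect_equal(st$median, 25)   # even count: mean of the two central values
  expect_equal(st$sd, sd(c(10, 20, 30, 40)))
  expect_equal(zone_length_stats(z[0])$n, 0)
})

test_that("binding-region index dominates the in-zone per-base tf values", {
  for (seed in c(51, 52, 53)) {
    rs <- random_regions(n_regions = 40, n_tfs = 5, span = 3000,
                         overlap_rate = 0.5, seed = seed)
    z <- binding_region_zones(rs)
    tr <- accumulation_track(rs, "tf", 0)
    for (i in seq_along(z)) {
      maxv <- max(track_value(tr, "chr1", start(z)[i]:end(z)[i]))
      expect_gte(mcols(z)$index[i], maxv)
    }
  }
})

test_that("overlap-method HOT bases lie inside binding-region HOT zones", {
  for (seed in c(61, 62)) {
    rs <- random_regions(n_regions = 50, n_tfs = 5, span = 4000,
                         overlap_rate = 0.4, seed = seed)
    for (Tthr in 2:3) {
      hot_o <- select_hot(overlap_zones(accumulation_track(rs, "tf", 0)),
                          Tthr)
      hot_b <- select_hot(binding_region_zones(rs), Tthr)
      if (length(hot_o) > 0) {
        cov_b <- reduce(granges(hot_b))
        within <- countOverlaps(hot_o, cov_b, type = "within")
        expect_true(all(within > 0))
      }
      # overlap-method HOT zones contain only bases >= threshold by design
      expect_true(all(mcols(hot_o)$index >= Tthr))
    }
  }
})

test_that("HOT zone counts are monotone in k for both procedures", {
  rs <- random_regions(n_regions = 80, n_tfs = 6, span = 4000,
                       overlap_rate = 0.5, seed = 77)
  tr <- accumulation_track(rs, "tf", 10)
  dense <- overlap_zones(tr)
  st <- accumulation_stats(tr)
  n_top <- vapply(c(1, 5, 20, 60, 100), function(k) {
    length(select_hot(dense, resolve_threshold(threshold_spec("top_k_pct", k),
                                               zones = dense)))
  }, integer(1))
  expect_true(all(diff(n_top) >= 0))
  thr_std <- vapply(c(0, 0.5, 1, 2, 4), function(k) {
    resolve_threshold(threshold_spec("k_std", k), stats = st)$threshold
  }, integer(1))
  expect_true(all(diff(thr_std) >= 0))
  n_std <- vapply(thr_std, function(t) length(select_hot(dense, t)),
                  integer(1))
  expect_true(all(diff(n_std) <= 0))
})

test_that("find_hot_zones orchestrates methods, stats and thresholds", {
  rs <- fig3_regions()
  res <- find_hot_zones(rs, "overlap", "tf", 0, threshold_spec("absolute", 3))
  expect_s3_class(res, "hot_zone_result")
  expect_true(all(mcols(res$hot)$index == 3L))
  expect_equal(max(mcols(res$dense)$index), length(tf_names(rs)))
  # binding-region + k_std draws base statistics from the tf track at w
  res_b <- find_hot_zones(rs, "binding_region", "tf", 0,
                          threshold_spec("k_std", 0))
  st <- accumulation_stats(accumulation_track(rs, "tf", 0))
  expect_equal(res_b$threshold$threshold,
               as.integer(ceiling(st$mean)))
  # empty input after chromosome filter: no crash with an absolute threshold
  res0 <- find_hot_zones(rs, "overlap", "tf", 0,
                         threshold_spec("absolute", 2), chroms = "chrNA")
  expect_equal(length(res0$dense), 0)
  expect_equal(length(res0$hot), 0)
  # ... and a clean data error when a data-driven threshold is impossible
  expect_error(find_hot_zones(rs, "overlap", "tf", 0,
                              threshold_spec("top_k_pct", 1),
                              chroms = "chrNA"),
               "no dense zones")
})

test_that("per-chromosome mode thresholds each chromosome separately", {
  rs <- region_set(rep(c("chr1", "chr2"), each = 3),
                   c(1, 1, 1, 1, 100, 200), c(50, 50, 50, 50, 150, 250),
                   tf = c("A", "B", "C", "A", "A", "A"))
  res <- find_hot_zones(rs, "overlap", "tf", 0, threshold_spec("top_k_pct", 50),
                        per_chromosome = TRUE)
  expect_named(res, c("chr1", "chr2"))
  expect_equal(res$chr1$threshold$threshold, 3L)
  expect_equal(res$chr2$threshold$threshold, 1L)
})

test_that("zone reports carry the standard summary columns", {
  res <- find_hot_zones(fig3_regions(), "binding_region", "tf", 0,
                        threshold_spec("absolute", 2))
  rep <- zone_report(res)
  expect_true(all(c("input_regions", "moving_window", "dense_zones",
                    "dense_bases", "dense_zone_avg_length", "max_index",
                    "threshold", "hot_zones", "hot_bases",
                    "hot_zone_avg_length") %in% names(rep)))
  expect_equal(rep$dense_zones, 4)
  expect_equal(rep$hot_zones, 3)   # indexes 3, 2, 3 reach the threshold
  expect_equal(rep$hot_bases, sum(width(res$hot)))
})
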