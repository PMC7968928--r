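# ChIP coverage, the sliding-window peak caller, overlaps and offsets.

test_that("reads are extended from their 5' end in the strand direction", {
  plus <- read_set("chr1", 1000, 1037, "+")
  cov <- coverage_from_reads(plus, c(chr1 = 5000), extend_to = 300)
  raw <- cov$values$chr1 / max(cov$values$chr1)
  expect_equal(which(raw > 0) - 1, 1000:1299)

  minus <- read_set("chr1", 1000, 1037, "-")
  cov2 <- coverage_from_reads(minus, c(chr1 = 5000), extend_to = 300)
  raw2 <- cov2$values$chr1 / max(cov2$values$chr1)
  expect_equal(which(raw2 > 0) - 1, 737:1036)

  expect_equal(mean(cov$values$chr1), 1, tolerance = 1e-9)
  expect_error(coverage_from_reads(read_set(), c(chr1 = 100)), "zero reads")
  expect_error(coverage_from_reads(plus, c(chr1 = 5000), extend_to = 20),
               "read length")
})

test_that("window threshold is inclusive at exactly 3.0", {
  v <- numeric(10000); v[3001:3400] <- 3.0
  tr <- toy_track(v, kind = "coverage", normalized = TRUE)
  p <- call_peaks(tr, window = 400, threshold = 3.0)
  expect_equal(nrow(p), 1)
  v2 <- numeric(10000); v2[3001:3400] <- 2.99
  expect_equal(nrow(call_peaks(toy_track(v2, "coverage", TRUE),
                               window = 400, threshold = 3.0)), 0)
})

test_that("a broad enriched region yields exactly one merged peak", {
  v <- rep(0.5, 20000); v[5001:6000] <- 4.0
  tr <- toy_track(v, kind = "coverage", normalized = TRUE)
  p <- call_peaks(tr, window = 400, threshold = 3.0)
  expect_equal(nrow(p), 1)
  expect_lte(p$start, 5000)
  expect_gte(p$end, 6000)
  expect_true(p$center >= p$start && p$center < p$end)
  expect_lte(abs(p$center - 5500), 10)
  # and matches the exhaustive window-scan oracle
  want <- exhaustive_peak_scan(v, 400, 3.0)
  expect_equal(p[, c("start", "end")], want, ignore_attr = TRUE)
})

test_that("caller equals the exhaustive oracle on random tracks", {
  for (seed in 1:5) {
    set.seed(seed)
    v <- pmax(0, rnorm(20000, mean = 1, sd = 2.5))
    tr <- toy_track(v, kind = "coverage", normalized = TRUE)
    got <- call_peaks(tr, window = 250, threshold = 3.0)
    want <- exhaustive_peak_scan(v, 250, 3.0)
    expect_equal(got[, c("start", "end")], want, ignore_attr = TRUE)
  }
})

test_that("raising the threshold never widens the called area", {
  set.seed(9)
  v <- pmax(0, rnorm(30000, mean = 1, sd = 2))
  tr <- toy_track(v, kind = "coverage", normalized = TRUE)
  bp <- vapply(c(2, 2.5, 3, 3.5, 4), function(th) {
    p <- call_peaks(tr, window = 300, threshold = th)
    sum(p$end - p$start)
  }, numeric(1))
  expect_true(all(diff(bp) <= 0))
})

test_that("peak calls depend only on the normalized signal", {
  set.seed(11)
  raw <- pmax(0, rnorm(20000, mean = 1, sd = 2))
  t1 <- normalize_mean(toy_track(raw, kind = "coverage"))
  t2 <- normalize_mean(toy_track(raw * 37.5, kind = "coverage"))
  expect_equal(call_peaks(t1), call_peaks(t2))
  expect_error(call_peaks(toy_track(raw, kind = "coverage")), "normalized")
})

test_that("short chromosomes are skipped with a message", {
  tr <- signal_track(list(chr1 = rep(5, 10000), chr2 = rep(5, 100)),
                     kind = "coverage", normalized = TRUE)
  expect_message(p <- call_peaks(tr, window = 400, threshold = 3),
                 "skipping chr2")
  expect_true(all(p$chrom == "chr1"))
})

test_that("overlap statistics match hand enumeration", {
  mk <- function(s, e) {
    df <- data.frame(chrom = "chr1", start = s, end = e,
                     center = (s + e) %/% 2,
                     max_enrichment = 5, mean_enrichment = 4)
    class(df) <- c("peak_set", "data.frame"); df
  }
  a <- mk(c(0, 200), c(100, 300))
  b <- mk(50, 150)
  st <- peak_overlap_stats(a, b)
  expect_equal(st$n_A, 2); expect_equal(st$n_B, 1)
  expect_equal(st$n_overlapping, 1)
  # |A n B| = 50 bp, |A u B| = 250 bp
  expect_equal(st$jaccard_bp, 50 / 250)
  ident <- peak_overlap_stats(a, a)
  expect_equal(ident$jaccard_bp, 1.0)
  expect_equal(ident$n_overlapping, 2)
  expect_equal(peak_overlap_stats(a, mk(5000, 5100))$jaccard_bp, 0)
})

test_that("offset pairing is one-to-one, signed and side-classified", {
  mk <- function(centers) {
    df <- data.frame(chrom = "chr1", start = centers - 50,
                     end = centers + 50, center = centers,
                     max_enrichment = 5, mean_enrichment = 4)
    class(df) <- c("peak_set", "data.frame"); df
  }
  offs <- pair_offsets(mk(5000), mk(4850), max_pair_dist = 500)
  expect_equal(offs$offset, -150)
  expect_equal(offs$side, "left")

  # B center out of reach: A reported unpaired
  offs2 <- pair_offsets(mk(5000), mk(9000), max_pair_dist = 500)
  expect_equal(nrow(offs2), 0)
  expect_equal(nrow(attr(offs2, "unpaired_A")), 1)

  # antisymmetry on a one-to-one pairing
  a <- mk(c(1000, 3000, 6000)); b <- mk(c(1120, 2910, 6040))
  ab <- pair_offsets(a, b, 500); ba <- pair_offsets(b, a, 500)
  expect_equal(sort(ab$offset), sort(-ba$offset))
})

test_that("offsets summarise by side with conserved counts", {
  offs <- data.frame(label = c("p1", "p2", "p3"), chrom = "chr1",
                     center_A = c(1, 2, 3), center_B = c(0, 0, 0),
                     offset = c(-150, -140, 160),
                     side = c("left", "left", "right"))
  s <- offsets_by_cluster(offs)
  expect_equal(s$n, c(2, 1))
  expect_equal(s$median_offset, c(-145, 160))
  expect_equal(sum(s$n), nrow(offs))
  one <- offsets_by_cluster(offs[offs$side == "left", ])
  expect_equal(one$n[one$side == "right"], 0)
  expect_true(is.na(one$median_offset[one$side == "right"]))
  expect_error(offsets_by_cluster(offs[0, ]), "no offsets")
})
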