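# Motif scanning, anchor-centred matrices, meta-profiles, differences,
# clustering.

test_that("IUPAC semantics: W admits A/T, rejects C/G", {
  pad <- strrep("C", 20)
  hit <- setNames(paste0(pad, "ANGGCGGCAT", pad), "chr1")
  miss <- setNames(paste0(pad, "CNGGCGGCTT", pad), "chr1")
  expect_equal(nrow(scan_motif(hit, "WNGGCGGCWW", strand_mode = "forward")), 1)
  expect_equal(scan_motif(hit, "WNGGCGGCWW", strand_mode = "forward")$center,
               20 + 5)
  expect_equal(nrow(scan_motif(miss, "WNGGCGGCWW", strand_mode = "forward")),
               0)
  expect_error(scan_motif(hit, "WXGG"), "IUPAC")
})

test_that("scanner equals the positionwise IUPAC oracle on a 100-kb genome", {
  g <- make_genome(chrom_length = 100000, n_motif_sites = 30,
                   n_features = 40, seed = 21)
  got <- scan_motif(g)
  want <- brute_iupac_scan(as.character(g$sequence), g$motif_iupac)
  expect_equal(paste(got$chrom, got$center, got$strand),
               paste(want$chrom, want$center, want$strand))
})

test_that("intergenic filtering removes genic planted motifs only", {
  g <- make_genome(chrom_length = 60000, n_motif_sites = 12,
                   n_features = 30, seed = 23)
  all_hits <- scan_motif(g)
  inter <- scan_motif(g, intergenic_only = TRUE)
  planted_inter <- g$motifs[g$motifs$intergenic, ]
  planted_genic <- g$motifs[!g$motifs$intergenic, ]
  expect_true(all(paste(planted_inter$chrom, planted_inter$center) %in%
                    paste(inter$chrom, inter$center)))
  expect_false(any(paste(planted_genic$chrom, planted_genic$center) %in%
                     paste(inter$chrom, inter$center)))
  expect_lte(nrow(inter), nrow(all_hits))
})

test_that("site_matrix extracts oriented windows and drops out-of-bounds", {
  v <- numeric(1000); v[101] <- 7  # signal at 0-based 100
  tr <- toy_track(v)
  a <- anchor_set("chr1", 100, "+")
  m <- site_matrix(tr, a, flank = 5)
  expect_equal(dim(m), c(1, 11))
  expect_equal(unname(m[1, ]), v[96:106])
  expect_equal(unname(m[1, "0"]), 7)

  # minus-strand anchor sees the window reversed under orientation
  am <- anchor_set("chr1", 100, "-")
  mm <- site_matrix(tr, am, flank = 5)
  expect_equal(unname(mm[1, ]), rev(v[96:106]))
  expect_equal(unname(site_matrix(tr, am, flank = 5,
                                  orient_by_strand = FALSE)[1, ]),
               v[96:106])

  # near-edge anchors are dropped and counted
  a2 <- anchor_set(c("chr1", "chr1"), c(3, 500), c("+", "+"))
  m2 <- site_matrix(tr, a2, flank = 10)
  expect_equal(nrow(m2), 1)
  expect_equal(attr(m2, "n_dropped"), 1)
  expect_error(site_matrix(tr, anchor_set("chr1", 3, "+"), flank = 10),
               "out of bounds")
})

test_that("meta profile is the column mean of the site matrix", {
  set.seed(31)
  tr <- toy_track(runif(5000))
  a <- anchor_set(rep("chr1", 6), c(500, 1200, 2100, 3000, 3900, 4500),
                  rep(c("+", "-"), 3))
  m <- site_matrix(tr, a, flank = 50)
  expect_equal(meta_profile(tr, a, flank = 50), colMeans(m),
               tolerance = 1e-12)
  # impulses at +10 and -10 from two unoriented anchors average symmetric
  v <- numeric(2000); v[1000 + 10 + 1] <- 1; v[1500 - 10 + 1] <- 1
  mp <- meta_profile(toy_track(v), anchor_set(c("chr1", "chr1"),
                                              c(1000, 1500), c("+", "+")),
                     flank = 20, orient_by_strand = FALSE)
  expect_equal(unname(mp["10"]), unname(mp["-10"]))
  # a flat normalized track gives a flat unit profile
  flat <- normalize_mean(toy_track(rep(2, 3000)))
  expect_true(all(meta_profile(flat, a, flank = 50) == 1))
})

test_that("orientation involution: flipping strands reverses columns", {
  set.seed(33)
  tr <- toy_track(runif(4000))
  a <- anchor_set(rep("chr1", 4), c(600, 1600, 2600, 3400),
                  c("+", "-", "+", "-"))
  flipped <- anchor_set(a$chrom, a$center,
                        ifelse(a$strand == "+", "-", "+"), label = a$label)
  m1 <- site_matrix(tr, a, flank = 30)
  m2 <- site_matrix(tr, flipped, flank = 30)
  expect_equal(unclass(m2), unclass(m1)[, ncol(m1):1],
               ignore_attr = TRUE)
})

test_that("difference matrices follow the mutant-minus-reference convention", {
  set.seed(35)
  tr <- toy_track(runif(3000))
  a <- anchor_set(rep("chr1", 3), c(500, 1500, 2500), rep("+", 3))
  m <- site_matrix(tr, a, flank = 20)
  expect_true(all(diff_matrix(m, m) == 0))

  # impulse moved from +10 (ref) to +15 (mut): negative at +10, positive at +15
  ref <- numeric(1000); ref[500 + 10 + 1] <- 1
  mut <- numeric(1000); mut[500 + 15 + 1] <- 1
  aa <- anchor_set("chr1", 500, "+")
  d <- diff_matrix(site_matrix(toy_track(mut), aa, 20),
                   site_matrix(toy_track(ref), aa, 20))
  expect_lt(d[1, "10"], 0)
  expect_gt(d[1, "15"], 0)

  m2 <- site_matrix(toy_track(runif(3000)), a, flank = 20)
  expect_equal(unclass(diff_matrix(m, m2)), -unclass(diff_matrix(m2, m)),
               ignore_attr = TRUE)
  m3 <- site_matrix(tr, a, flank = 10)
  expect_error(diff_matrix(m, m3), "identical row labels")
})

test_that("k-means recovers planted row archetypes deterministically", {
  set.seed(37)
  arch1 <- c(rep(0, 20), rep(5, 10), rep(0, 21))
  arch2 <- c(rep(5, 10), rep(0, 41))
  truth <- rep(1:2, each = 30)
  rows <- rbind(matrix(rep(arch1, 30), nrow = 30, byrow = TRUE),
                matrix(rep(arch2, 30), nrow = 30, byrow = TRUE)) +
    matrix(rnorm(60 * 51, sd = 0.5), nrow = 60)
  rownames(rows) <- sprintf("a%d", 1:60)
  labels <- cluster_rows(rows, k = 2, seed = 5)
  expect_equal(mclust::adjustedRandIndex(labels, truth), 1.0)
  expect_identical(labels, cluster_rows(rows, k = 2, seed = 5))
  expect_true(all(cluster_rows(rows, k = 1) == 1))
  expect_error(cluster_rows(rows, k = 61), "exceed")
})
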