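# Nucleosome dyad calling, anchor distances, shifts, phasing decay.

test_that("dyad calling finds isolated bumps and resolves close ones", {
  tr <- toy_track(gaussian_bump(10000, at = 5000))
  calls <- call_nucleosome_dyads(tr, min_height = 0.5, min_spacing = 100,
                                 sigma = 10)
  expect_equal(nrow(calls), 1)
  expect_lte(abs(calls$pos - 5000), 1)

  two <- toy_track(gaussian_bump(10000, 5000, height = 50) +
                     gaussian_bump(10000, 5040, height = 30))
  got <- call_nucleosome_dyads(two, min_height = 0.5, min_spacing = 100,
                               sigma = 5)
  expect_equal(nrow(got), 1)
  expect_lt(abs(got$pos - 5000), 10)  # the higher bump wins

  flat <- toy_track(rep(1, 5000))
  expect_equal(nrow(call_nucleosome_dyads(flat, min_height = 0.5,
                                          min_spacing = 100, sigma = 5)), 0)
})

test_that("proximal distances are strand-aware and bounded", {
  calls <- data.frame(chrom = "chr1", pos = c(897, 1103, 1310),
                      height = c(1, 1, 1))
  a_plus <- anchor_set("chr1", 1000, "+")
  expect_equal(proximal_distance(a_plus, calls, max_dist = 400,
                                 side = "downstream")$distance, 103)
  a_minus <- anchor_set("chr1", 1000, "-")
  expect_equal(proximal_distance(a_minus, calls, max_dist = 400,
                                 side = "downstream")$distance, 103)
  expect_equal(proximal_distance(a_plus, calls, max_dist = 400,
                                 side = "upstream")$distance, 103)
  # nothing within range: anchor retained with NA
  far <- anchor_set("chr1", 5000, "+")
  res <- proximal_distance(far, calls, max_dist = 400)
  expect_equal(nrow(res), 1)
  expect_true(is.na(res$distance))
})

test_that("shifts are mutant minus reference with direction labels", {
  ref <- data.frame(label = c("a", "b", "c"), chrom = "chr1",
                    center = 1:3, strand = "+", distance = c(103, 103, NA))
  mut <- data.frame(label = c("a", "b", "c"), chrom = "chr1",
                    center = 1:3, strand = "+", distance = c(153, 103, 120))
  expect_message(sh <- shift_per_anchor(ref, mut), "excluded 1")
  expect_equal(sh$shift, c(50, 0))
  expect_equal(sh$direction, c("toward_motif", "none"))
  expect_equal(attr(sh, "n_excluded"), 1)
  expect_error(shift_per_anchor(ref, transform(mut, label = c("x", "y", "z"))),
               "shared")
})

test_that("a configured 50-bp shift is recovered through the full MNase arm", {
  g <- array_genome(200, seed = 41)
  tr_wt <- mnase_track(g, "WT", seed = 42)
  tr_null <- mnase_track(g, "remodeler-null", seed = 43)
  anchors <- scan_motif(g)
  anchors <- anchors[anchors$label %in% g$motifs$label, ]
  class(anchors) <- c("anchor_set", "data.frame")
  d_wt <- proximal_distance(anchors,
                            call_nucleosome_dyads(tr_wt, min_height = 1,
                                                  min_spacing = 120,
                                                  sigma = 20))
  d_null <- proximal_distance(anchors,
                              call_nucleosome_dyads(tr_null, min_height = 1,
                                                    min_spacing = 120,
                                                    sigma = 20))
  sh <- shift_per_anchor(d_wt, d_null)
  expect_lte(abs(median(sh$shift) - 50), 2)
  expect_gt(mean(sh$direction == "toward_motif"), 0.9)
})

test_that("phasing decay: zero jitter gives near-zero spread", {
  g <- array_genome(100, seed = 45)
  cfg <- place_nucleosomes(g, "WT", n_per_array = 3,
                           jitter_schedule = c(0, 0, 0), seed = 46)
  sds <- phasing_decay(cfg, n_indices = 3)
  expect_true(all(sds <= 1))
})

test_that("phasing decay recovered from called dyads tracks the schedule", {
  g <- array_genome(400, seed = 47)
  sched <- c(3, 8, 16)
  cfg <- place_nucleosomes(g, "WT", n_per_array = 3,
                           jitter_schedule = sched, seed = 48)
  fr <- filter_fragments(simulate_mnase_fragments(cfg, depth = 100,
                                                  seed = 49))
  tr <- normalize_mean(dyads_from_fragments(fr, g$chrom_lengths))
  calls <- call_nucleosome_dyads(tr, min_height = 1, min_spacing = 120,
                                 sigma = 10)
  anchors <- scan_motif(g)
  anchors <- anchors[anchors$label %in% g$motifs$label, ]
  class(anchors) <- c("anchor_set", "data.frame")
  sds <- phasing_decay(calls, anchors, repeat_length = 207, n_indices = 3)
  expect_false(any(is.na(sds)))
  expect_true(all(diff(sds) > 0))  # decay is monotone like the schedule
})
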