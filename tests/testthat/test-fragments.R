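# Fragment containers, interval file readers/writers, and the size filter.

test_that("BEDPE fragments parse with validation and line numbers", {
  p <- tempfile(fileext = ".bedpe")
  writeLines(c("chr1\t100\t150\tchr1\t200\t250\tf1\t0\t+\t-",
               "chr1\t500\t540\tchr1\t600\t650\tf2\t0\t+\t-",
               "chr2\t10\t60\tchr2\t90\t160\tf3\t0\t+\t-"), p)
  fr <- read_fragment_intervals(p)
  expect_s3_class(fr, "fragment_set")
  expect_equal(nrow(fr), 3)
  expect_equal(fr$start[fr$chrom == "chr1"], c(100, 500))
  expect_equal(fr$end[fr$chrom == "chr1"], c(250, 650))

  writeLines(c("chr1\t100\t150\tchr1\t200\t250\tf1\t0\t+\t-",
               "chr1\t300\t250\tchr1\t400\t450\tf2\t0\t+\t-"), p)
  expect_error(read_fragment_intervals(p), "line 2")
})

test_that("BAM input keeps proper pairs and logs skipped orphans", {
  sam <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate", "@SQ\tSN:chr1\tLN:10000")
  pairs <- unlist(lapply(1:5, function(i) {
    s <- 1000 * i
    c(sprintf("p%d\t99\tchr1\t%d\t60\t37M\t=\t%d\t150\t*\t*", i, s, s + 113),
      sprintf("p%d\t147\tchr1\t%d\t60\t37M\t=\t%d\t-150\t*\t*", i, s + 113, s))
  }))
  orphans <- c("o1\t0\tchr1\t7000\t60\t37M\t*\t0\t0\t*\t*",
               "o2\t0\tchr1\t8000\t60\t37M\t*\t0\t0\t*\t*")
  writeLines(c(hdr, pairs, orphans), sam)
  bam <- Rsamtools::asBam(sam, destination = tempfile(),
                          indexDestination = FALSE)
  expect_message(fr <- read_fragment_intervals(bam, format = "BAM"),
                 "skipped 2")
  expect_equal(nrow(fr), 5)
  expect_equal(attr(fr, "n_skipped"), 2)
  expect_equal(fr$end - fr$start, rep(150, 5))
  expect_equal(fr$start, 1000 * (1:5) - 1)  # 0-based conversion
})

test_that("size filter keeps the inclusive 100-200 bp window and dedups", {
  lens <- c(99, 100, 150, 200, 201)
  fr <- fragment_set(rep("chr1", 5), seq(0, 4000, 1000),
                     seq(0, 4000, 1000) + lens)
  kept <- filter_fragments(fr)
  expect_equal(sort(kept$end - kept$start), c(100, 150, 200))

  dup <- fragment_set(c("chr1", "chr1"), c(500, 500), c(650, 650))
  expect_equal(nrow(dup), 1)        # aggregated on construction
  expect_equal(dup$multiplicity, 2)
  dd <- filter_fragments(dup, deduplicate = TRUE)
  expect_equal(dd$multiplicity, 1)
  nd <- filter_fragments(dup, deduplicate = FALSE)
  expect_equal(nd$multiplicity, 2)

  expect_equal(nrow(filter_fragments(fragment_set())), 0)
  expect_error(filter_fragments(fr, min_len = 250, max_len = 200), "min_len")
})

test_that("widening the length window never drops fragments", {
  set.seed(42)
  fr <- fragment_set(rep("chr1", 500), s <- sample.int(50000, 500),
                     s + sample(50:400, 500, replace = TRUE))
  n_narrow <- n_fragments_kept <- NULL
  windows <- list(c(120, 180), c(100, 200), c(80, 260), c(50, 400))
  counts <- vapply(windows, function(w)
    sum(filter_fragments(fr, w[1], w[2], deduplicate = FALSE)$multiplicity),
    numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("BEDPE and BAM writers round-trip through the readers", {
  fr <- fragment_set(c("chr1", "chr1", "chr2"), c(100, 900, 50),
                     c(250, 1060, 200), multiplicity = c(2, 1, 1))
  p <- tempfile(fileext = ".bedpe")
  write_fragments_bedpe(fr, p)
  back <- read_fragment_intervals(p)
  expect_equal(back, fr, ignore_attr = TRUE)

  bam <- write_fragments_bam(fr, c(chr1 = 2000, chr2 = 500),
                             tempfile(fileext = ".bam"))
  back2 <- read_fragment_intervals(bam, format = "BAM")
  expect_equal(back2, fr, ignore_attr = TRUE)
})

test_that("single-end read BED writer round-trips", {
  rs <- read_set(c("chr1", "chr1"), c(100, 300), c(137, 337), c("+", "-"))
  p <- tempfile(fileext = ".bed")
  write_reads_bed(rs, p)
  back <- read_reads(p)
  expect_equal(back, rs, ignore_attr = TRUE)
})
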