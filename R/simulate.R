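# Simulators for MNase-protected fragments and ChIP reads.

#' Simulate MNase-protected fragments from a nucleosome configuration
#'
#' Draws `depth` fragments per placed dyad. Each fragment's midpoint is its
#' dyad position plus a small Gaussian wobble; fragment lengths are drawn
#' from a truncated Normal confined to the mononucleosomal window
#' \[100, 200\] bp, except for an `out_of_range_rate` mass drawn from two
#' MNase-ladder side lobes (subnucleosomal ~80 bp and dinucleosomal
#' ~320 bp) that exercises the downstream size filter.
#'
#' @param config A `nuc_config` from [place_nucleosomes()].
#' @param depth Fragments per nucleosome (non-negative integer).
#' @param length_model List with `mean`, `sd` and `out_of_range_rate`.
#' @param wobble_sd Standard deviation (bp) of the midpoint-vs-dyad wobble.
#' @param seed Integer seed.
#' @return A `fragment_set`.
#' @examples
#' g <- make_genome(chrom_length = 50000, n_motif_sites = 6, seed = 1)
#' cfg <- place_nucleosomes(g, "WT", seed = 1)
#' fr <- simulate_mnase_fragments(cfg, depth = 20, seed = 1)
#' @export
simulate_mnase_fragments <- function(config, depth = 50L,
                                     length_model = list(
                                       mean = 147, sd = 15,
                                       out_of_range_rate = 0),
                                     wobble_sd = 3, seed = 1L) {
  stopifnot(inherits(config, "nuc_config"))
  stop_if_not_scalar_number(depth, "depth", min = 0)
  lm <- length_model
  if (is.null(lm$out_of_range_rate)) lm$out_of_range_rate <- 0
  if (lm$out_of_range_rate < 0 || lm$out_of_range_rate > 1)
    stop("`out_of_range_rate` must be in [0, 1]", call. = FALSE)
  if (depth == 0 || nrow(config$dyads) == 0L) return(fragment_set())

  with_seed(seed, {
    n <- as.integer(depth) * nrow(config$dyads)
    dyad <- rep(config$dyads$pos, each = as.integer(depth))
    chrom <- rep(config$dyads$chrom, each = as.integer(depth))
    mid <- dyad + round(rnorm(n, 0, wobble_sd))
    len <- integer(n)
    oob <- runif(n) < lm$out_of_range_rate
    len[!oob] <- rnorm_trunc(sum(!oob), lm$mean, lm$sd, 100, 200)
    if (any(oob)) {
      sub <- runif(sum(oob)) < 0.5
      lobes <- integer(sum(oob))
      lobes[sub] <- rnorm_trunc(sum(sub), 80, 10, 1, 99)
      lobes[!sub] <- rnorm_trunc(sum(!sub), 320, 30, 201, 600)
      len[oob] <- lobes
    }
    start <- mid - len %/% 2L
    end <- start + len
    keep <- start >= 0L & end <= config$chrom_lengths[chrom]
    fragment_set(chrom[keep], start[keep], end[keep])
  })
}

# Integer truncated-normal draws on [lo, hi] by rejection.
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  if (n == 0L) return(integer())
  x <- round(rnorm(n, mean, sd))
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- round(rnorm(length(bad), mean, sd))
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  as.integer(x)
}

#' Simulate single-end ChIP reads enriched at bound motif sites
#'
#' Places sonication-style fragments of length `frag_length` whose centers
#' fall either uniformly in the genome (background) or uniformly within a
#' `footprint`-wide window centred `subunit_offset` bp from each bound motif
#' center (signed; negative = upstream in genome coordinates). One
#' `read_length`-bp single-end read is taken from a random end of each
#' fragment, so downstream 5'-extension to `frag_length` reconstructs the
#' fragment coverage. The fraction of reads assigned to bound sites is
#' chosen so the expected coverage ratio between a bound footprint and the
#' genomic background equals `enrichment`.
#'
#' @param genome A `genome_model`.
#' @param enrichment Target fold coverage at bound sites over background.
#' @param footprint Width (bp) of the enriched window at each bound site.
#' @param subunit_offset Signed shift (bp) of the enriched window from the
#'   motif center; simulating two subunits with different offsets yields
#'   offset peak pairs.
#' @param n_reads Total reads to draw.
#' @param read_length Read length in bp.
#' @param frag_length Sonication fragment length in bp (the 5'-extension
#'   target used when rebuilding coverage).
#' @param seed Integer seed.
#' @return A `read_set`. `n_reads = 0` gives an empty set.
#' @export
simulate_chip_reads <- function(genome, enrichment = 6, footprint = 400L,
                                subunit_offset = 0L, n_reads = 200000L,
                                read_length = 37L, frag_length = 300L,
                                seed = 1L) {
  stopifnot(inherits(genome, "genome_model"))
  stop_if_not_scalar_number(enrichment, "enrichment", min = 1)
  stop_if_not_scalar_number(n_reads, "n_reads", min = 0)
  if (footprint < read_length)
    stop("`footprint` must be at least `read_length`", call. = FALSE)
  if (n_reads == 0) return(read_set())

  bound <- genome$motifs[genome$motifs$bound, , drop = FALSE]
  L <- sum(genome$chrom_lengths)
  S <- nrow(bound) * footprint
  # background reads are uniform genome-wide (bound footprints included);
  # the site component adds (enrichment - 1) x background density there, so
  # total site density / background density = enrichment
  p_site <- if (nrow(bound))
    (enrichment - 1) * S / (L + (enrichment - 1) * S) else 0

  with_seed(seed, {
    at_site <- runif(n_reads) < p_site
    n_site <- sum(at_site)
    n_bg <- n_reads - n_site

    centers <- numeric(0); chroms <- character(0)
    if (n_site > 0L) {
      si <- sample.int(nrow(bound), n_site, replace = TRUE)
      centers <- bound$center[si] + subunit_offset +
        round(runif(n_site, -footprint / 2, footprint / 2))
      chroms <- bound$chrom[si]
    }
    if (n_bg > 0L) {
      ch <- sample(genome$chrom_names, n_bg, replace = TRUE,
                   prob = genome$chrom_lengths / L)
      centers <- c(centers, floor(runif(n_bg) * genome$chrom_lengths[ch]))
      chroms <- c(chroms, ch)
    }
    strand <- sample(c("+", "-"), length(centers), replace = TRUE)
    # read 5' end sits at the fragment edge facing its strand
    start5 <- ifelse(strand == "+", centers - frag_length %/% 2L,
                     centers + frag_length %/% 2L - read_length)
    start <- pmax(0L, pmin(as.integer(start5),
                           genome$chrom_lengths[chroms] - read_length))
    read_set(chroms, start, start + as.integer(read_length), strand)
  })
}
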