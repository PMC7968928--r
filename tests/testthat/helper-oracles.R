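# Independent oracles and small builders used across the test suite.
# These deliberately avoid the package's own code paths (and Biostrings)
# so they can serve as cross-checks.

# Positionwise IUPAC scan: hand-rolled degenerate-code table, explicit
# offset-by-offset membership test on both strands. Returns 0-based centers.
brute_iupac_scan <- function(seqs, pattern, strand_mode = "both") {
  code <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))
  pat <- strsplit(toupper(pattern), "")[[1]]
  len <- length(pat)
  scan_one <- function(chars, pat_chars) {
    L <- length(chars)
    if (L < len) return(integer())
    ok <- rep(TRUE, L - len + 1L)
    for (j in seq_len(len)) {
      allowed <- code[[pat_chars[j]]]
      ok <- ok & chars[seq(j, L - len + j)] %in% allowed
    }
    which(ok) - 1L
  }
  out <- list()
  for (ch in names(seqs)) {
    chars <- strsplit(toupper(as.character(seqs[[ch]])), "")[[1]]
    s <- scan_one(chars, pat)
    if (length(s))
      out[[length(out) + 1L]] <- data.frame(chrom = ch,
                                            center = s + len %/% 2L,
                                            strand = "+",
                                            stringsAsFactors = FALSE)
    if (strand_mode == "both") {
      # reverse-complement of the *pattern*: complement each code
      comp_code <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                     S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                     D = "H", H = "D", N = "N")
      rc_pat <- rev(unname(comp_code[pat]))
      s <- scan_one(chars, rc_pat)
      if (length(s))
        out[[length(out) + 1L]] <- data.frame(chrom = ch,
                                              center = s + len %/% 2L,
                                              strand = "-",
                                              stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), center = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[!duplicated(res), , drop = FALSE]
  res[order(res$chrom, res$center, res$strand), , drop = FALSE]
}

# Exhaustive sliding-window peak scan: loop every start position, compute
# the window mean by direct summation, merge qualifying windows by union.
# Returns 0-based half-open peak intervals.
exhaustive_peak_scan <- function(v, window, threshold) {
  L <- length(v)
  if (L < window)
    return(data.frame(start = integer(), end = integer()))
  starts <- integer(0)
  for (i in 0:(L - window)) {
    if (sum(v[(i + 1):(i + window)]) / window >= threshold)
      starts <- c(starts, i)
  }
  if (!length(starts))
    return(data.frame(start = integer(), end = integer()))
  covered <- rep(FALSE, L)
  for (s in starts) covered[(s + 1):(s + window)] <- TRUE
  r <- rle(covered)
  e <- cumsum(r$lengths)
  s <- e - r$lengths
  data.frame(start = s[r$values], end = e[r$values])
}

# One-chromosome track with given values.
toy_track <- function(v, kind = "dyad", normalized = FALSE,
                      chrom = "chr1") {
  signal_track(setNames(list(as.numeric(v)), chrom), kind = kind,
               normalized = normalized)
}

# Gaussian bump centred at `at` (0-based) on a zero track of length L.
gaussian_bump <- function(L, at, sd = 15, height = 50) {
  x <- seq_len(L) - 1L
  height * exp(-((x - at)^2) / (2 * sd^2))
}

# Bound-only genome tuned for array simulations: no genic features, all
# planted motifs bound, spacing wide enough for the default arrays.
array_genome <- function(n_sites, seed, site_spacing = 2500,
                         motif = "WNGGCGGCWW") {
  make_genome(n_chrom = 1, chrom_length = as.integer(n_sites * site_spacing
                                                     + 4000),
              motif_iupac = motif, n_motif_sites = n_sites,
              bound_fraction = 1, n_features = 0, seed = seed,
              min_motif_separation = 1000L)
}

# Full MNase arm: place -> simulate -> filter -> dyad track (normalized).
mnase_track <- function(genome, genotype, seed, depth = 100, ...) {
  cfg <- place_nucleosomes(genome, genotype, seed = seed, ...)
  fr <- simulate_mnase_fragments(cfg, depth = depth, seed = seed + 1)
  fr <- filter_fragments(fr)
  normalize_mean(dyads_from_fragments(fr, genome$chrom_lengths))
}
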