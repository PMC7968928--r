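#' Generate a synthetic genome with planted motifs
#'
#' Builds one or more random chromosomes, plants non-overlapping instances of
#' a degenerate (IUPAC) motif — by default half in intergenic space and half
#' inside genic feature intervals — and flags a configurable fraction of the
#' planted motifs as factor-bound. The returned registry of planted centers
#' is the ground truth against which motif scanning, nucleosome placement and
#' shift recovery can be verified.
#'
#' Coordinates are 0-based half-open. The center of an even-length motif of
#' length `L` starting at `s` is `s + L/2` (right of the middle base);
#' reverse-strand instances share the center of their forward-strand
#' footprint.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp.
#' @param motif_iupac Motif as an IUPAC degenerate string (e.g.
#'   `"WNGGCGGCWW"`, the URS element bound by the repressor Ume6).
#' @param n_motif_sites Total number of motif instances to plant.
#' @param bound_fraction Fraction of planted motifs flagged as factor-bound.
#' @param n_features Number of genic feature intervals to place; positions
#'   not covered by a feature are "intergenic".
#' @param seed Integer seed; output is deterministic given identical
#'   parameters and seed.
#' @param base_comp Background base composition, a probability vector named
#'   `A`, `C`, `G`, `T`. Uniform by default.
#' @param intergenic_fraction Fraction of planted motifs placed in intergenic
#'   space (the rest are placed inside features).
#' @param min_motif_separation Minimum bp between planted motif centers, so
#'   downstream nucleosome arrays do not collide.
#' @param edge_margin Keep-out zone (bp) at each chromosome end where no
#'   motif is planted, leaving room for a full nucleosome array.
#' @param feature_length_range Range of feature interval lengths in bp.
#'
#' @return A `genome_model`: list with `chrom_names`, `chrom_lengths` (named
#'   integer vector), `sequence` (named [Biostrings::DNAStringSet]),
#'   `features` (data.frame `chrom`, `start`, `end`), `motifs` (data.frame
#'   `chrom`, `center`, `strand`, `bound`, `intergenic`, `label`), and
#'   `motif_iupac`.
#' @examples
#' g <- make_genome(chrom_length = 50000, n_motif_sites = 10, seed = 1)
#' table(g$motifs$bound)
#' @export
make_genome <- function(n_chrom = 1L, chrom_length = 100000L,
                        motif_iupac = "WNGGCGGCWW", n_motif_sites = 20L,
                        bound_fraction = 0.5, n_features = 50L, seed = 1L,
                        base_comp = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                        intergenic_fraction = 0.5,
                        min_motif_separation = 1500L,
                        edge_margin = 1200L,
                        feature_length_range = c(500L, 1500L)) {
  motif_iupac <- check_iupac(motif_iupac)
  stop_if_not_scalar_number(n_chrom, "n_chrom", min = 1)
  stop_if_not_scalar_number(chrom_length, "chrom_length", min = 1)
  stop_if_not_scalar_number(n_motif_sites, "n_motif_sites", min = 0)
  if (bound_fraction < 0 || bound_fraction > 1)
    stop("`bound_fraction` must be in [0, 1]", call. = FALSE)
  mlen <- nchar(motif_iupac)

  with_seed(seed, {
    chrom_names <- sprintf("chr%d", seq_len(n_chrom))
    chrom_lengths <- setNames(rep(as.integer(chrom_length), n_chrom),
                              chrom_names)
    seqs <- vapply(chrom_names, function(ch) {
      paste(sample(c("A", "C", "G", "T"), chrom_length, replace = TRUE,
                   prob = base_comp), collapse = "")
    }, character(1))

    features <- place_feature_intervals(chrom_names, chrom_lengths,
                                        n_features, feature_length_range)

    if (n_features == 0L) intergenic_fraction <- 1  # no genic space exists
    n_inter <- round(intergenic_fraction * n_motif_sites)
    n_genic <- n_motif_sites - n_inter
    placements <- plant_motif_positions(chrom_names, chrom_lengths, features,
                                        mlen, n_inter, n_genic,
                                        min_motif_separation, edge_margin)
    motifs <- placements
    if (nrow(motifs)) {
      motifs$strand <- sample(c("+", "-"), nrow(motifs), replace = TRUE)
      n_bound <- round(bound_fraction * nrow(motifs))
      bound <- rep(FALSE, nrow(motifs))
      bound[sample.int(nrow(motifs), n_bound)] <- TRUE
      motifs$bound <- bound
      # overwrite the background sequence with a concrete realization of the
      # pattern (reverse-complemented for minus-strand instances)
      for (i in seq_len(nrow(motifs))) {
        real <- realize_iupac(motif_iupac)
        if (motifs$strand[i] == "-") real <- revcomp(real)
        ch <- motifs$chrom[i]
        s <- motifs$start[i]
        substr(seqs[[ch]], s + 1L, s + mlen) <- real
      }
      motifs$center <- motifs$start + mlen %/% 2L
      motifs$label <- sprintf("%s:%d%s", motifs$chrom, motifs$center,
                              motifs$strand)
    } else {
      motifs <- data.frame(chrom = character(), start = integer(),
                           intergenic = logical(), strand = character(),
                           bound = logical(), center = integer(),
                           label = character(), stringsAsFactors = FALSE)
    }
    motifs <- motifs[order(motifs$chrom, motifs$center),
                     c("chrom", "center", "strand", "bound", "intergenic",
                       "label")]
    rownames(motifs) <- NULL

    structure(list(
      chrom_names = chrom_names,
      chrom_lengths = chrom_lengths,
      sequence = Biostrings::DNAStringSet(seqs),
      features = features,
      motifs = motifs,
      motif_iupac = motif_iupac
    ), class = "genome_model")
  })
}

# Non-overlapping genic intervals, spread uniformly across chromosomes.
place_feature_intervals <- function(chrom_names, chrom_lengths, n_features,
                                    len_range) {
  if (n_features == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  rows <- list()
  occupied <- lapply(chrom_names, function(x) IRanges::IRanges())
  names(occupied) <- chrom_names
  tries <- 0L
  while (length(rows) < n_features && tries < n_features * 200L) {
    tries <- tries + 1L
    ch <- sample(chrom_names, 1L)
    L <- chrom_lengths[[ch]]
    w <- sample(seq(len_range[1], len_range[2]), 1L)
    if (w >= L) next
    s <- sample.int(L - w, 1L) - 1L
    cand <- IRanges::IRanges(start = s + 1L, end = s + w)
    if (IRanges::overlapsAny(cand, occupied[[ch]])) next
    occupied[[ch]] <- c(occupied[[ch]], cand)
    rows[[length(rows) + 1L]] <- data.frame(chrom = ch, start = s,
                                            end = s + w,
                                            stringsAsFactors = FALSE)
  }
  if (length(rows) < n_features)
    stop("genome too small to place the requested feature intervals",
         call. = FALSE)
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

# Motif start positions: n_inter with footprints clear of all features,
# n_genic with footprints inside a feature; mutually separated.
plant_motif_positions <- function(chrom_names, chrom_lengths, features,
                                  mlen, n_inter, n_genic, min_sep,
                                  edge_margin = 0L) {
  total <- n_inter + n_genic
  if (total == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      intergenic = logical(), stringsAsFactors = FALSE))
  placed <- data.frame(chrom = character(), start = integer(),
                       intergenic = logical(), stringsAsFactors = FALSE)
  try_place <- function(intergenic) {
    for (attempt in seq_len(2000L)) {
      ch <- sample(chrom_names, 1L)
      L <- chrom_lengths[[ch]]
      margin <- if (L > 2L * edge_margin + mlen + 2L) edge_margin else 0L
      if (L <= mlen + 2L * margin + 2L) next
      s <- margin + sample.int(L - mlen - 2L * margin, 1L) - 1L
      in_feature <- overlaps_features(ch, s, s + mlen, features)
      if (intergenic && in_feature) next
      if (!intergenic && !in_feature) next
      same <- placed[placed$chrom == ch, , drop = FALSE]
      if (nrow(same) && any(abs(same$start - s) < min_sep)) next
      return(data.frame(chrom = ch, start = s, intergenic = intergenic,
                        stringsAsFactors = FALSE))
    }
    NULL
  }
  for (i in seq_len(n_inter)) {
    row <- try_place(TRUE)
    if (is.null(row))
      stop("genome too small for the requested intergenic motif sites",
           call. = FALSE)
    placed <- rbind(placed, row)
  }
  for (i in seq_len(n_genic)) {
    row <- try_place(FALSE)
    if (is.null(row))
      stop("genome too small for the requested genic motif sites",
           call. = FALSE)
    placed <- rbind(placed, row)
  }
  placed
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d chromosome(s), %s bp total\n",
              length(x$chrom_names),
              format(sum(x$chrom_lengths), big.mark = ",")))
  cat(sprintf("  motif %s: %d planted (%d bound, %d intergenic)\n",
              x$motif_iupac, nrow(x$motifs), sum(x$motifs$bound),
              sum(x$motifs$intergenic)))
  cat(sprintf("  features: %d genic intervals\n", nrow(x$features)))
  invisible(x)
}

#' Write a genome to FASTA
#'
#' @param genome A `genome_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome$sequence, filepath = path)
  invisible(path)
}

#' Read genome sequences from FASTA
#'
#' @param path FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write intervals to BED
#'
#' Writes a (chrom, start, end) table as BED (0-based half-open). Optional
#' `name`, `score` and `strand` columns produce BED6.
#'
#' @param x data.frame with columns `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  cols <- data.frame(chrom = x$chrom, start = x$start, end = x$end)
  if (!is.null(x$name) || !is.null(x$strand)) {
    cols$name <- if (is.null(x$name)) "." else x$name
    cols$score <- if (is.null(x$score)) 0 else x$score
    cols$strand <- if (is.null(x$strand)) "." else x$strand
  }
  write.table(cols, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
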