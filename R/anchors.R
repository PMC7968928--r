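# Anchor sets and IUPAC motif scanning.

#' Construct an anchor set
#'
#' Oriented anchor points (motif centers, pre-initiation-complex sites, peak
#' centers, ...) used to center signal matrices and meta-profiles.
#'
#' @param chrom,center,strand Vectors of equal length; strand in `{+, -}`.
#' @param label Unique row labels; defaults to `chrom:center strand`.
#' @param source Provenance tag (`"motif_scan"`, `"external_bed"`, ...).
#' @return An `anchor_set` data.frame.
#' @export
anchor_set <- function(chrom = character(), center = integer(),
                       strand = character(), label = NULL,
                       source = "unknown") {
  stopifnot(length(chrom) == length(center),
            length(center) == length(strand))
  if (length(strand) && !all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'", call. = FALSE)
  if (is.null(label))
    label <- sprintf("%s:%d%s", chrom, as.integer(center), strand)
  df <- data.frame(chrom = as.character(chrom), center = as.integer(center),
                   strand = as.character(strand),
                   label = as.character(label), stringsAsFactors = FALSE)
  if (anyDuplicated(df[c("chrom", "center", "strand")]))
    stop("duplicate (chrom, center, strand) anchors", call. = FALSE)
  attr(df, "source") <- source
  class(df) <- c("anchor_set", "data.frame")
  df
}

#' Scan sequences for a degenerate IUPAC motif
#'
#' Finds every instance of an IUPAC pattern (e.g. `"WNGGCGGCWW"`) on both
#' strands using [Biostrings::matchPattern()] with `fixed = FALSE`. Each
#' match is reported at the center of its forward-strand footprint
#' (`start + length/2`, 0-based); reverse-strand matches carry strand `-`
#' but share the forward-footprint center. With `intergenic_only = TRUE`,
#' matches whose footprint overlaps any supplied feature interval are
#' removed — "intergenic" is defined entirely by the caller's feature set.
#'
#' @param x A `genome_model`, a named [Biostrings::DNAStringSet], or a named
#'   character vector of chromosome sequences.
#' @param iupac Motif pattern; defaults to the genome's planted pattern when
#'   `x` is a `genome_model`.
#' @param feature_intervals data.frame (`chrom`, `start`, `end`, 0-based
#'   half-open) of genic intervals; defaults to the genome's features.
#' @param strand_mode `"both"` or `"forward"`.
#' @param intergenic_only Drop matches overlapping a feature interval.
#' @return An `anchor_set` with source `"motif_scan"`.
#' @examples
#' g <- make_genome(chrom_length = 50000, n_motif_sites = 10, seed = 1)
#' a <- scan_motif(g, intergenic_only = TRUE)
#' @export
scan_motif <- function(x, iupac = NULL, feature_intervals = NULL,
                       strand_mode = c("both", "forward"),
                       intergenic_only = FALSE) {
  strand_mode <- match.arg(strand_mode)
  if (inherits(x, "genome_model")) {
    if (is.null(iupac)) iupac <- x$motif_iupac
    if (is.null(feature_intervals)) feature_intervals <- x$features
    seqs <- x$sequence
  } else if (is.character(x)) {
    seqs <- Biostrings::DNAStringSet(toupper(x))
  } else {
    seqs <- x
  }
  if (is.null(iupac)) stop("`iupac` pattern required", call. = FALSE)
  iupac <- check_iupac(iupac)
  mlen <- nchar(iupac)
  if (is.null(names(seqs)))
    stop("sequences must be named by chromosome", call. = FALSE)

  hits <- list()
  for (ch in names(seqs)) {
    fwd <- Biostrings::matchPattern(iupac, seqs[[ch]], fixed = FALSE)
    s0 <- BiocGenerics::start(fwd) - 1L
    if (length(s0))
      hits[[length(hits) + 1L]] <- data.frame(
        chrom = ch, start = s0, strand = "+", stringsAsFactors = FALSE)
    if (strand_mode == "both") {
      rev <- Biostrings::matchPattern(revcomp(iupac), seqs[[ch]],
                                      fixed = FALSE)
      s0 <- BiocGenerics::start(rev) - 1L
      if (length(s0))
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = ch, start = s0, strand = "-", stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(anchor_set(source = "motif_scan"))
  df <- do.call(rbind, hits)
  if (intergenic_only) {
    drop <- overlaps_features(df$chrom, df$start, df$start + mlen,
                              feature_intervals)
    df <- df[!drop, , drop = FALSE]
  }
  df <- df[!duplicated(df[c("chrom", "start", "strand")]), , drop = FALSE]
  df <- df[order(df$chrom, df$start, df$strand), , drop = FALSE]
  anchor_set(df$chrom, df$start + mlen %/% 2L, df$strand,
             source = "motif_scan")
}

#' Read anchors from BED6
#'
#' Each anchor is a 1-bp interval whose start is the center (0-based), with
#' the label in column 4 and strand in column 6.
#'
#' @param path BED6 file.
#' @param source Provenance tag for the result.
#' @return An `anchor_set`.
#' @export
read_anchors_bed <- function(path, source = "external_bed") {
  tab <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(tab) < 6L)
    stop("anchor BED must have 6 columns", call. = FALSE)
  anchor_set(tab[[1]], tab[[2]], tab[[6]], label = tab[[4]], source = source)
}

#' Write anchors to BED6
#'
#' @param anchors An `anchor_set`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_anchors_bed <- function(anchors, path) {
  df <- data.frame(anchors$chrom, anchors$center, anchors$center + 1L,
                   anchors$label, 0, anchors$strand)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
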