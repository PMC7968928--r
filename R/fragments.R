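# FragmentSet / ReadSet containers and interval file I/O.
# Coordinates are 0-based half-open throughout.

#' Construct a fragment set
#'
#' A fragment set records paired-end template intervals as
#' (`chrom`, `start`, `end`, `multiplicity`), 0-based half-open. Identical
#' coordinates are aggregated by summing multiplicity, so the table holds
#' unique keys.
#'
#' @param chrom,start,end Vectors of equal length; `start < end` required.
#' @param multiplicity Positive integer copies per record (default 1).
#' @return A `fragment_set` data.frame.
#' @export
fragment_set <- function(chrom = character(), start = integer(),
                         end = integer(), multiplicity = NULL) {
  if (is.null(multiplicity)) multiplicity <- rep(1L, length(chrom))
  stopifnot(length(chrom) == length(start), length(start) == length(end),
            length(end) == length(multiplicity))
  if (length(start) && any(start >= end))
    stop("fragment intervals must satisfy start < end", call. = FALSE)
  if (length(multiplicity) && any(multiplicity < 1))
    stop("multiplicity must be >= 1", call. = FALSE)
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end),
                   multiplicity = as.integer(multiplicity),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    df <- aggregate(multiplicity ~ chrom + start + end, data = df, FUN = sum)
    df <- df[order(df$chrom, df$start, df$end), ]
    rownames(df) <- NULL
  }
  class(df) <- c("fragment_set", "data.frame")
  df
}

#' Construct a single-end read set
#'
#' @param chrom,start,end,strand Vectors of equal length; `start < end`,
#'   strand in `{+, -}`.
#' @return A `read_set` data.frame.
#' @export
read_set <- function(chrom = character(), start = integer(),
                     end = integer(), strand = character()) {
  stopifnot(length(chrom) == length(start), length(start) == length(end),
            length(end) == length(strand))
  if (length(start) && any(start >= end))
    stop("read intervals must satisfy start < end", call. = FALSE)
  if (length(strand) && !all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'", call. = FALSE)
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), strand = as.character(strand),
                   stringsAsFactors = FALSE)
  class(df) <- c("read_set", "data.frame")
  df
}

#' Total fragment count (multiplicities included)
#'
#' @param fragments A `fragment_set`.
#' @return Integer count of fragments, counting multiplicity.
#' @export
n_fragments <- function(fragments) sum(fragments$multiplicity)

#' Read paired-end fragment intervals from BAM, BEDPE or BED
#'
#' BAM input keeps properly paired first-mate records and derives one
#' fragment per template from the leftmost mate start and the template
#' length; records that are not properly paired are skipped and their count
#' reported (message plus `attr(, "n_skipped")`). BEDPE input spans each
#' mate pair from the leftmost mate start to the rightmost mate end. BED
#' input takes each line as a fragment. All coordinates are returned
#' 0-based half-open.
#'
#' @param path Input file.
#' @param format `"BAM"`, `"BEDPE"` or `"BED"`; guessed from the file
#'   extension by default.
#' @return A `fragment_set`.
#' @export
read_fragment_intervals <- function(path,
                                    format = c("auto", "BAM", "BEDPE",
                                               "BED")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     bam = "BAM", bedpe = "BEDPE", bed = "BED",
                     stop("cannot guess format from extension; pass `format`",
                          call. = FALSE))
  }
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  switch(format,
         BAM = read_fragments_bam(path),
         BEDPE = read_fragments_bedpe(path),
         BED = read_fragments_bed(path))
}

read_fragments_bam <- function(path) {
  p_all <- Rsamtools::ScanBamParam(what = c("flag"))
  flags_all <- Rsamtools::scanBam(path, param = p_all)[[1]]$flag
  proper <- bitwAnd(flags_all, 2L) > 0L
  n_skipped <- sum(!proper)

  p <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isPaired = TRUE, isProperPair = TRUE,
                                  isFirstMateRead = TRUE),
    what = c("rname", "pos", "mpos", "isize"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  keep <- !is.na(b$pos) & !is.na(b$isize) & b$isize != 0L
  left <- pmin(b$pos[keep], b$mpos[keep]) - 1L  # to 0-based
  width <- abs(b$isize[keep])
  out <- fragment_set(as.character(b$rname[keep]), left, left + width)
  if (n_skipped > 0L)
    message(sprintf("read_fragment_intervals: skipped %d record(s) not in a proper pair",
                    n_skipped))
  attr(out, "n_skipped") <- n_skipped
  out
}

read_fragments_bedpe <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(fragment_set())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 6L)
  if (length(bad))
    stop(sprintf("BEDPE parse error at line %d: fewer than 6 fields",
                 bad[1]), call. = FALSE)
  m <- do.call(rbind, lapply(parts, `[`, 1:6))
  s1 <- suppressWarnings(as.integer(m[, 2])); e1 <- suppressWarnings(as.integer(m[, 3]))
  s2 <- suppressWarnings(as.integer(m[, 5])); e2 <- suppressWarnings(as.integer(m[, 6]))
  bad <- which(is.na(s1) | is.na(e1) | is.na(s2) | is.na(e2))
  if (length(bad))
    stop(sprintf("BEDPE parse error at line %d: non-numeric coordinate",
                 bad[1]), call. = FALSE)
  bad <- which(e1 <= s1 | e2 <= s2)
  if (length(bad))
    stop(sprintf("BEDPE parse error at line %d: end <= start", bad[1]),
         call. = FALSE)
  bad <- which(m[, 1] != m[, 4])
  if (length(bad))
    stop(sprintf("BEDPE parse error at line %d: mates on different chromosomes",
                 bad[1]), call. = FALSE)
  fragment_set(m[, 1], pmin(s1, s2), pmax(e1, e2))
}

read_fragments_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (!length(lines)) return(fragment_set())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop(sprintf("BED parse error at line %d: fewer than 3 fields", bad[1]),
         call. = FALSE)
  m <- do.call(rbind, lapply(parts, `[`, 1:3))
  s <- suppressWarnings(as.integer(m[, 2])); e <- suppressWarnings(as.integer(m[, 3]))
  bad <- which(is.na(s) | is.na(e) | e <= s)
  if (length(bad))
    stop(sprintf("BED parse error at line %d: bad coordinates", bad[1]),
         call. = FALSE)
  fragment_set(m[, 1], s, e)
}

#' Filter fragments by length and deduplicate
#'
#' Retains fragments whose length (`end - start`) lies in
#' `[min_len, max_len]`, both bounds inclusive — the mononucleosome size
#' selection used before dyad mapping. With `deduplicate = TRUE`, records
#' sharing exact (chrom, start, end) coordinates collapse to multiplicity 1
#' (PCR-duplicate removal).
#'
#' @param fragments A `fragment_set`.
#' @param min_len,max_len Inclusive length bounds in bp.
#' @param deduplicate Collapse identical coordinates to a single copy.
#' @return A filtered `fragment_set`.
#' @export
filter_fragments <- function(fragments, min_len = 100L, max_len = 200L,
                             deduplicate = TRUE) {
  if (min_len > max_len)
    stop("`min_len` must be <= `max_len`", call. = FALSE)
  len <- fragments$end - fragments$start
  out <- fragments[len >= min_len & len <= max_len, , drop = FALSE]
  if (deduplicate) out$multiplicity <- rep(1L, nrow(out))
  rownames(out) <- NULL
  class(out) <- c("fragment_set", "data.frame")
  out
}

#' Write fragments to BEDPE
#'
#' Each template is emitted as two abutting synthetic mates spanning the
#' fragment (left half / right half), repeated per multiplicity, so the file
#' round-trips through [read_fragment_intervals()].
#'
#' @param fragments A `fragment_set`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fragments_bedpe <- function(fragments, path) {
  i <- rep(seq_len(nrow(fragments)), times = fragments$multiplicity)
  s <- fragments$start[i]; e <- fragments$end[i]
  mid <- (s + e) %/% 2L
  df <- data.frame(fragments$chrom[i], s, pmax(mid, s + 1L),
                   fragments$chrom[i], pmin(mid, e - 1L), e,
                   sprintf("frag%d", seq_along(i)), 0, "+", "-")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write fragments to BAM
#'
#' Emits each template as a properly paired mate pair (via a temporary SAM
#' file converted with [Rsamtools::asBam()]), so BAM output round-trips
#' through [read_fragment_intervals()].
#'
#' @param fragments A `fragment_set`.
#' @param chrom_lengths Named vector of chromosome lengths (bp) for the
#'   header.
#' @param path Output path; `.bam` extension added if missing.
#' @return Path of the BAM file written, invisibly.
#' @export
write_fragments_bam <- function(fragments, chrom_lengths, path) {
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam))
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   as.integer(chrom_lengths)))
  i <- rep(seq_len(nrow(fragments)), times = fragments$multiplicity)
  o <- order(fragments$chrom[i], fragments$start[i])
  i <- i[o]
  qname <- sprintf("frag%d", seq_along(i))
  s <- fragments$start[i]; e <- fragments$end[i]
  w <- e - s
  half <- pmax(w %/% 2L, 1L)
  r2len <- pmax(w - half, 1L)
  # R1 forward at the left edge, R2 reverse ending at the right edge
  r1 <- sprintf("%s\t99\t%s\t%d\t60\t%dM\t=\t%d\t%d\t*\t*",
                qname, fragments$chrom[i], s + 1L, half, e - r2len + 1L, w)
  r2 <- sprintf("%s\t147\t%s\t%d\t60\t%dM\t=\t%d\t%d\t*\t*",
                qname, fragments$chrom[i], e - r2len + 1L, r2len, s + 1L, -w)
  body <- as.vector(rbind(r1, r2))
  writeLines(c(hdr, body), sam)
  dest <- sub("\\.bam$", "", path)
  bam <- Rsamtools::asBam(sam, destination = dest, overwrite = TRUE,
                          indexDestination = FALSE)
  invisible(bam)
}

#' Read single-end ChIP reads from BED or BAM
#'
#' @param path Input file.
#' @param format `"BED"` or `"BAM"`; guessed from the extension by default.
#' @return A `read_set`.
#' @export
read_reads <- function(path, format = c("auto", "BED", "BAM")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     bam = "BAM", bed = "BED",
                     stop("cannot guess format from extension; pass `format`",
                          call. = FALSE))
  }
  if (format == "BED") {
    tab <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
    if (ncol(tab) < 6L)
      stop("read BED must have 6 columns (strand in column 6)",
           call. = FALSE)
    return(read_set(tab[[1]], tab[[2]], tab[[3]], tab[[6]]))
  }
  p <- Rsamtools::ScanBamParam(what = c("rname", "pos", "qwidth", "strand"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  keep <- !is.na(b$pos)
  read_set(as.character(b$rname[keep]), b$pos[keep] - 1L,
           b$pos[keep] - 1L + b$qwidth[keep], as.character(b$strand[keep]))
}

#' Write single-end reads to BED6
#'
#' @param reads A `read_set`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_reads_bed <- function(reads, path) {
  df <- data.frame(reads$chrom, reads$start, reads$end,
                   sprintf("read%d", seq_len(nrow(reads))), 0, reads$strand)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
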