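# ChIP coverage, sliding-window peak calling, overlap statistics and
# paired-subunit centre offsets.

#' Build normalized coverage from single-end ChIP reads
#'
#' Each read is extended from its 5' end in its strand direction to
#' `extend_to` bp (the average sonication fragment size), clipped at
#' chromosome ends; per-bp coverage is then normalized so the genome-wide
#' mean is 1.0, putting the track on an enrichment scale.
#'
#' @param reads A `read_set`.
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param extend_to Extension length in bp; must be at least the read
#'   length.
#' @return A normalized `signal_track` of kind `"coverage"`.
#' @export
coverage_from_reads <- function(reads, chrom_lengths, extend_to = 300L) {
  if (nrow(reads) == 0L)
    stop("cannot build coverage from zero reads", call. = FALSE)
  if (any(reads$end - reads$start > extend_to))
    stop("`extend_to` must be at least the read length", call. = FALSE)
  stopifnot(!is.null(names(chrom_lengths)))
  plus <- reads$strand == "+"
  s <- ifelse(plus, reads$start, pmax(0L, reads$end - extend_to))
  e <- ifelse(plus, pmin(reads$start + extend_to,
                         chrom_lengths[reads$chrom]), reads$end)
  values <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    i <- reads$chrom == ch
    delta <- numeric(L + 1L)
    if (any(i)) {
      ts <- rowsum(rep(1, sum(i)), s[i])
      te <- rowsum(rep(1, sum(i)), e[i])
      delta[as.integer(rownames(ts)) + 1L] <-
        delta[as.integer(rownames(ts)) + 1L] + ts[, 1]
      delta[as.integer(rownames(te)) + 1L] <-
        delta[as.integer(rownames(te)) + 1L] - te[, 1]
    }
    cumsum(delta)[seq_len(L)]
  })
  names(values) <- names(chrom_lengths)
  normalize_mean(signal_track(values, kind = "coverage"))
}

#' Call enrichment peaks with a sliding-window threshold
#'
#' Slides a `window`-bp window along the normalized track in `step`-bp
#' increments; every window whose mean enrichment is at least `threshold`
#' (inclusive) qualifies, and overlapping or adjacent qualifying windows are
#' merged (via [IRanges::reduce()]) into one peak spanning their union. The
#' peak center is the signal-weighted centroid of the merged interval
#' (`center_method = "max"` takes the highest position instead).
#' Chromosomes shorter than the window are skipped with a message.
#'
#' @param track A normalized `signal_track` (see [normalize_mean()] or
#'   [coverage_from_reads()]).
#' @param window Window width in bp.
#' @param threshold Minimum qualifying mean enrichment within the window.
#' @param step Window step in bp.
#' @param center_method `"centroid"` (signal-weighted) or `"max"`.
#' @return A `peak_set` data.frame (`chrom`, `start`, `end`, `center`,
#'   `max_enrichment`, `mean_enrichment`).
#' @export
call_peaks <- function(track, window = 400L, threshold = 3.0, step = 1L,
                       center_method = c("centroid", "max")) {
  stopifnot(inherits(track, "signal_track"))
  if (!isTRUE(track$normalized))
    stop("`track` must be normalized (see normalize_mean()) so the ",
         "threshold is on the enrichment scale", call. = FALSE)
  stop_if_not_scalar_number(window, "window", min = 1)
  stop_if_not_scalar_number(step, "step", min = 1)
  center_method <- match.arg(center_method)
  window <- as.integer(window); step <- as.integer(step)

  out <- list()
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    L <- length(v)
    if (L < window) {
      message(sprintf("call_peaks: skipping %s (length %d < window %d)",
                      ch, L, window))
      next
    }
    cs <- cumsum(c(0, v))
    starts <- seq(0L, L - window, by = step)  # 0-based window starts
    wmean <- (cs[starts + window + 1L] - cs[starts + 1L]) / window
    q <- starts[wmean >= threshold]
    if (!length(q)) next
    merged <- IRanges::reduce(IRanges::IRanges(start = q + 1L,
                                               width = window))
    for (j in seq_along(merged)) {
      s <- BiocGenerics::start(merged)[j] - 1L
      e <- BiocGenerics::end(merged)[j]
      seg <- v[(s + 1L):e]
      pos <- s:(e - 1L)
      center <- if (center_method == "centroid") {
        if (sum(seg) > 0) round(sum(pos * seg) / sum(seg)) else
          (s + e - 1L) %/% 2L
      } else pos[which.max(seg)]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = s, end = e, center = as.integer(center),
        max_enrichment = max(seg), mean_enrichment = mean(seg),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               center = integer(), max_enrichment = numeric(),
               mean_enrichment = numeric(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("peak_set", "data.frame")
  res
}

#' Overlap statistics between two peak sets
#'
#' @param peaks_A,peaks_B `peak_set` data.frames on the same genome.
#' @return List with `n_A`, `n_B`, `n_overlapping` (A-peaks intersecting any
#'   B-peak by at least 1 bp) and `jaccard_bp` (bp-level Jaccard index of
#'   the two peak unions).
#' @export
peak_overlap_stats <- function(peaks_A, peaks_B) {
  n_over <- 0L
  inter_bp <- 0
  union_bp <- 0
  chroms <- union(peaks_A$chrom, peaks_B$chrom)
  for (ch in chroms) {
    a <- peaks_A[peaks_A$chrom == ch, , drop = FALSE]
    b <- peaks_B[peaks_B$chrom == ch, , drop = FALSE]
    ra <- IRanges::reduce(IRanges::IRanges(start = a$start + 1L, end = a$end))
    rb <- IRanges::reduce(IRanges::IRanges(start = b$start + 1L, end = b$end))
    if (nrow(a) && nrow(b))
      n_over <- n_over + sum(IRanges::overlapsAny(
        IRanges::IRanges(start = a$start + 1L, end = a$end), rb))
    inter_bp <- inter_bp + sum(BiocGenerics::width(
      IRanges::intersect(ra, rb)))
    union_bp <- union_bp + sum(BiocGenerics::width(
      IRanges::union(ra, rb)))
  }
  list(n_A = nrow(peaks_A), n_B = nrow(peaks_B), n_overlapping = n_over,
       jaccard_bp = if (union_bp > 0) inter_bp / union_bp else NA_real_)
}

#' Pair peaks between two subunits and record centre offsets
#'
#' Greedy one-to-one pairing of A-peaks with B-peak centers by increasing
#' distance (ties: leftmost A, then leftmost B) within `max_pair_dist`.
#' `offset = center_B - center_A`; peaks with `offset < 0` are classified
#' `side = "left"`, otherwise `"right"`. Unpaired peaks of either set are
#' attached as attributes.
#'
#' @param peaks_A,peaks_B `peak_set` data.frames.
#' @param max_pair_dist Maximum centre distance in bp.
#' @return An `offset_records` data.frame (`label`, `chrom`, `center_A`,
#'   `center_B`, `offset`, `side`) with attributes `unpaired_A` and
#'   `unpaired_B`.
#' @export
pair_offsets <- function(peaks_A, peaks_B, max_pair_dist = 500L) {
  stop_if_not_scalar_number(max_pair_dist, "max_pair_dist", min = 1)
  cand <- list()
  for (ch in intersect(peaks_A$chrom, peaks_B$chrom)) {
    ia <- which(peaks_A$chrom == ch)
    ib <- which(peaks_B$chrom == ch)
    grid <- expand.grid(a = ia, b = ib)
    d <- abs(peaks_B$center[grid$b] - peaks_A$center[grid$a])
    keep <- d <= max_pair_dist
    if (any(keep))
      cand[[length(cand) + 1L]] <- data.frame(
        a = grid$a[keep], b = grid$b[keep], d = d[keep])
  }
  used_a <- logical(nrow(peaks_A)); used_b <- logical(nrow(peaks_B))
  rows <- list()
  if (length(cand)) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(cand$d, peaks_A$center[cand$a],
                       peaks_B$center[cand$b]), ]
    for (i in seq_len(nrow(cand))) {
      a <- cand$a[i]; b <- cand$b[i]
      if (used_a[a] || used_b[b]) next
      used_a[a] <- TRUE; used_b[b] <- TRUE
      off <- peaks_B$center[b] - peaks_A$center[a]
      rows[[length(rows) + 1L]] <- data.frame(
        label = sprintf("%s:%d", peaks_A$chrom[a], peaks_A$center[a]),
        chrom = peaks_A$chrom[a], center_A = peaks_A$center[a],
        center_B = peaks_B$center[b], offset = off,
        side = if (off < 0) "left" else "right",
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = character(), chrom = character(),
               center_A = integer(), center_B = integer(),
               offset = integer(), side = character(),
               stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$center_A), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unpaired_A") <- peaks_A[!used_a, , drop = FALSE]
  attr(out, "unpaired_B") <- peaks_B[!used_b, , drop = FALSE]
  class(out) <- c("offset_records", "data.frame")
  out
}

#' Summarise centre offsets by side
#'
#' Partitions offset records into left-side and right-side clusters and
#' reports per-side counts and median offsets. Both sides are always
#' reported; an absent side has `n = 0` and `NA` median.
#'
#' @param offsets An `offset_records` data.frame from [pair_offsets()].
#' @return data.frame (`side`, `n`, `median_offset`).
#' @export
offsets_by_cluster <- function(offsets) {
  if (nrow(offsets) == 0L)
    stop("no offsets to summarise", call. = FALSE)
  out <- do.call(rbind, lapply(c("left", "right"), function(s) {
    o <- offsets$offset[offsets$side == s]
    data.frame(side = s, n = length(o),
               median_offset = if (length(o)) median(o) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write peaks as BED6+ with centre and max-enrichment columns
#'
#' @param peaks A `peak_set`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  df <- data.frame(peaks$chrom, peaks$start, peaks$end,
                   sprintf("peak%d", seq_len(nrow(peaks))),
                   peaks$mean_enrichment, ".", peaks$center,
                   peaks$max_enrichment)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
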