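# Per-bp signal tracks: construction, dyad counting, normalization,
# smoothing and bedGraph/wiggle I/O.

#' Construct a per-bp signal track
#'
#' @param values Named list of non-negative numeric vectors, one per
#'   chromosome, one value per bp.
#' @param kind `"dyad"` or `"coverage"`.
#' @param normalized Whether values are already on the genome-mean-1.0
#'   enrichment scale.
#' @return A `signal_track`.
#' @export
signal_track <- function(values, kind = c("dyad", "coverage"),
                         normalized = FALSE) {
  kind <- match.arg(kind)
  stopifnot(is.list(values), !is.null(names(values)))
  for (v in values) {
    if (!is.numeric(v)) stop("track values must be numeric", call. = FALSE)
    if (length(v) && min(v) < 0)
      stop("track values must be non-negative", call. = FALSE)
  }
  structure(list(values = values, kind = kind, normalized = normalized),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("signal_track [%s%s]: %d chromosome(s), %s bp, total mass %.4g\n",
              x$kind, if (x$normalized) ", normalized" else "",
              length(x$values),
              format(track_length(x), big.mark = ","), track_sum(x)))
  invisible(x)
}

track_length <- function(track) sum(vapply(track$values, length, numeric(1)))
track_sum <- function(track) sum(vapply(track$values, sum, numeric(1)))
track_mean <- function(track) track_sum(track) / track_length(track)

#' Build a dyad track from fragment midpoints
#'
#' Each fragment contributes `multiplicity` counts at its midpoint
#' `floor((start + end) / 2)` — the dyad position estimate for a
#' nucleosome-protected fragment. The track's total mass equals the number
#' of fragments counted.
#'
#' @param fragments A `fragment_set`.
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @return An unnormalized `signal_track` of kind `"dyad"`.
#' @export
dyads_from_fragments <- function(fragments, chrom_lengths) {
  stopifnot(!is.null(names(chrom_lengths)))
  unknown <- setdiff(unique(fragments$chrom), names(chrom_lengths))
  if (length(unknown))
    stop(sprintf("fragments on undeclared chromosome(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  if (nrow(fragments) &&
      any(fragments$start < 0 |
            fragments$end > chrom_lengths[fragments$chrom]))
    stop("fragment outside declared chromosome length", call. = FALSE)
  mid <- (fragments$start + fragments$end) %/% 2L
  values <- lapply(names(chrom_lengths), function(ch) {
    i <- fragments$chrom == ch
    v <- numeric(chrom_lengths[[ch]])
    if (any(i)) {
      tab <- rowsum(as.numeric(fragments$multiplicity[i]), mid[i])
      v[as.integer(rownames(tab)) + 1L] <- tab[, 1]
    }
    v
  })
  names(values) <- names(chrom_lengths)
  signal_track(values, kind = "dyad", normalized = FALSE)
}

#' Normalize a track to genome-wide mean 1.0
#'
#' Scales every value by `genome_length / total_mass` so the average signal
#' per bp across the genome is exactly 1.0. Idempotent; linear in the
#' input's scale.
#'
#' @param track A `signal_track` with nonzero total mass.
#' @return The normalized `signal_track`.
#' @export
normalize_mean <- function(track) {
  stopifnot(inherits(track, "signal_track"))
  total <- track_sum(track)
  if (total <= 0)
    stop("cannot normalize an all-zero track", call. = FALSE)
  scale <- track_length(track) / total
  track$values <- lapply(track$values, function(v) v * scale)
  track$normalized <- TRUE
  track
}

#' Smooth a track with a Gaussian kernel
#'
#' Convolution with a discrete Gaussian (truncated at 4 sigma), reflected
#' boundaries, followed by an exact rescale so total mass is conserved.
#' `sigma = 0` returns the input unchanged.
#'
#' @param track A `signal_track`.
#' @param sigma Kernel standard deviation in bp.
#' @return The smoothed `signal_track`.
#' @export
smooth_track <- function(track, sigma) {
  stopifnot(inherits(track, "signal_track"))
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  if (sigma == 0) return(track)
  r <- ceiling(4 * sigma)
  kern <- dnorm(seq(-r, r), sd = sigma)
  kern <- kern / sum(kern)
  track$values <- lapply(track$values, function(v) {
    L <- length(v)
    if (L == 0L) return(v)
    rr <- min(r, L)
    pad <- c(v[seq(rr, 1L)], v, v[seq(L, L - rr + 1L)])
    if (rr < r) pad <- c(rep(v[1], r - rr), pad, rep(v[L], r - rr))
    sm <- stats::filter(pad, kern, method = "convolution", sides = 2)
    out <- as.numeric(sm[(r + 1L):(r + L)])
    s_in <- sum(v); s_out <- sum(out)
    if (s_out > 0) out <- out * (s_in / s_out)
    out
  })
  track
}

#' Write a track to bedGraph or fixed-step wiggle
#'
#' bedGraph output is 0-based half-open with equal-value runs merged into
#' single intervals (zero runs included, so files round-trip without needing
#' separate chromosome lengths); wiggle output is 1-based `fixedStep`
#' `step=1`. Values are printed with full double precision.
#'
#' @param track A `signal_track`.
#' @param path Output file.
#' @param format `"bedGraph"` or `"wig"`.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path, format = c("bedGraph", "wig")) {
  format <- match.arg(format)
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    if (format == "bedGraph") {
      r <- rle(v)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths
      writeLines(sprintf("%s\t%d\t%d\t%s", ch, starts, ends,
                         fmt_num(r$values)), con)
    } else {
      writeLines(sprintf("fixedStep chrom=%s start=1 step=1", ch), con)
      writeLines(fmt_num(v), con)
    }
  }
  invisible(path)
}

#' Read a track written by [write_track()]
#'
#' @param path Input file.
#' @param format `"bedGraph"` or `"wig"`.
#' @param kind Track kind to stamp on the result.
#' @param normalized Normalization flag to stamp on the result.
#' @return A `signal_track`.
#' @export
read_track <- function(path, format = c("bedGraph", "wig"),
                       kind = c("dyad", "coverage"), normalized = FALSE) {
  format <- match.arg(format)
  kind <- match.arg(kind)
  lines <- readLines(path)
  values <- list()
  if (format == "bedGraph") {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    chrom <- vapply(parts, `[`, character(1), 1L)
    start <- as.integer(vapply(parts, `[`, character(1), 2L))
    end <- as.integer(vapply(parts, `[`, character(1), 3L))
    val <- as.numeric(vapply(parts, `[`, character(1), 4L))
    for (ch in unique(chrom)) {
      i <- chrom == ch
      v <- numeric(max(end[i]))
      for (j in which(i)) v[(start[j] + 1L):end[j]] <- val[j]
      values[[ch]] <- v
    }
  } else {
    hdr <- grepl("^fixedStep", lines)
    grp <- cumsum(hdr)
    for (g in unique(grp[grp > 0])) {
      head_line <- lines[hdr & grp == g]
      ch <- sub(".*chrom=([^ ]+).*", "\\1", head_line)
      values[[ch]] <- as.numeric(lines[!hdr & grp == g])
    }
  }
  signal_track(values, kind = kind, normalized = normalized)
}
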