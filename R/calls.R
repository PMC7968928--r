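# Nucleosome dyad calling, anchor-relative distances, shift and
# phasing-decay quantification.

#' Call nucleosome dyad positions from a dyad track
#'
#' Local maxima of the sigma-smoothed track with height at least
#' `min_height`; maxima closer than `min_spacing` are resolved by keeping
#' the higher one (ties: leftmost). Plateau maxima are reported at their
#' leftmost position.
#'
#' @param track A `signal_track` (kind `"dyad"`).
#' @param min_height Minimum smoothed height of a call.
#' @param min_spacing Minimum bp between retained calls.
#' @param sigma Gaussian smoothing sd in bp applied before peak picking.
#' @return A `nucleosome_calls` data.frame (`chrom`, `pos` 0-based,
#'   `height`).
#' @export
call_nucleosome_dyads <- function(track, min_height = 0, min_spacing = 120L,
                                  sigma = 20) {
  stopifnot(inherits(track, "signal_track"))
  stop_if_not_scalar_number(min_spacing, "min_spacing", min = 1)
  sm <- smooth_track(track, sigma)
  out <- list()
  for (ch in names(sm$values)) {
    v <- sm$values[[ch]]
    if (length(v) < 3L) next
    r <- rle(v)
    n <- length(r$values)
    if (n < 2L) next
    run_start <- cumsum(c(0L, r$lengths[-n]))  # 0-based leftmost of run
    is_max <- rep(FALSE, n)
    inner <- seq(2L, n - 1L)
    if (length(inner))
      is_max[inner] <- r$values[inner] > r$values[inner - 1L] &
        r$values[inner] > r$values[inner + 1L]
    pos <- run_start[is_max]
    height <- r$values[is_max]
    keep <- height >= min_height
    pos <- pos[keep]; height <- height[keep]
    if (!length(pos)) next
    # greedy spacing resolution: highest first, leftmost on ties
    o <- order(-height, pos)
    accepted <- integer(0)
    for (i in o) {
      if (!length(accepted) || all(abs(pos[accepted] - pos[i]) >= min_spacing))
        accepted <- c(accepted, i)
    }
    accepted <- sort(accepted)
    out[[length(out) + 1L]] <- data.frame(
      chrom = ch, pos = as.integer(pos[accepted]),
      height = height[accepted], stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), pos = integer(), height = numeric(),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("nucleosome_calls", "data.frame")
  res
}

#' Distance from each anchor to its nearest qualifying nucleosome call
#'
#' Distances are strand-aware: "downstream" of a minus-strand anchor lies at
#' decreasing genomic coordinates. A call exactly at the anchor center
#' counts as downstream. Anchors with no qualifying call within `max_dist`
#' are retained with `NA` distance.
#'
#' @param anchors An `anchor_set`.
#' @param calls A `nucleosome_calls` data.frame.
#' @param max_dist Maximum distance in bp.
#' @param side `"downstream"`, `"upstream"` or `"either"` relative to the
#'   anchor's orientation.
#' @return data.frame (`label`, `chrom`, `center`, `strand`, `distance`).
#' @export
proximal_distance <- function(anchors, calls, max_dist = 400L,
                              side = c("downstream", "upstream", "either")) {
  side <- match.arg(side)
  stop_if_not_scalar_number(max_dist, "max_dist", min = 1)
  dist <- rep(NA_real_, nrow(anchors))
  for (i in seq_len(nrow(anchors))) {
    cc <- calls[calls$chrom == anchors$chrom[i], , drop = FALSE]
    if (!nrow(cc)) next
    sgn <- if (anchors$strand[i] == "+") 1L else -1L
    rel <- sgn * (cc$pos - anchors$center[i])
    d <- switch(side,
                downstream = rel[rel >= 0],
                upstream = -rel[rel < 0],
                either = abs(rel))
    d <- d[d <= max_dist]
    if (length(d)) dist[i] <- min(d)
  }
  data.frame(label = anchors$label, chrom = anchors$chrom,
             center = anchors$center, strand = anchors$strand,
             distance = dist, stringsAsFactors = FALSE)
}

#' Per-anchor nucleosome shift between two conditions
#'
#' For anchors shared between two [proximal_distance()] tables, the shift is
#' `distance_B - distance_A` where condition B is the remodeler-deficient
#' (or factor-deficient) condition. A positive shift means the nucleosome
#' sits closer to the anchor when the remodeler is present — i.e. the
#' remodeler pulls the nucleosome toward the motif.
#'
#' @param dist_ref Distances in the reference (remodeler-on) condition A.
#' @param dist_mut Distances in the mutant condition B.
#' @return A `shift_result` data.frame (`label`, `distance_ref`,
#'   `distance_mut`, `shift`, `direction`), with the count of anchors
#'   missing in either condition in `attr(, "n_excluded")`.
#' @export
shift_per_anchor <- function(dist_ref, dist_mut) {
  shared <- intersect(dist_ref$label, dist_mut$label)
  if (!length(shared))
    stop("no shared anchor labels between conditions", call. = FALSE)
  a <- dist_ref[match(shared, dist_ref$label), ]
  b <- dist_mut[match(shared, dist_mut$label), ]
  ok <- !is.na(a$distance) & !is.na(b$distance)
  n_excluded <- sum(!ok)
  if (n_excluded > 0L)
    message(sprintf("shift_per_anchor: excluded %d anchor(s) missing a call in one condition",
                    n_excluded))
  shift <- b$distance[ok] - a$distance[ok]
  out <- data.frame(label = shared[ok], distance_ref = a$distance[ok],
                    distance_mut = b$distance[ok], shift = shift,
                    direction = ifelse(shift > 0, "toward_motif",
                                       ifelse(shift < 0, "away_from_motif",
                                              "none")),
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- n_excluded
  class(out) <- c("shift_result", "data.frame")
  out
}

#' Positional spread of nucleosomes by array index (phasing decay)
#'
#' Quantifies how nucleosome positioning decays along an array: for each
#' array index the standard deviation, across anchors, of the anchor-relative
#' dyad position assigned to that index. Given a `nuc_config` the planted
#' dyads are used directly; given a `nucleosome_calls` table, each index is
#' assigned the nearest downstream call within half a repeat length of its
#' expected position (anchored on the median proximal distance).
#'
#' @param x A `nuc_config` or `nucleosome_calls`.
#' @param anchors An `anchor_set` (required for call input).
#' @param repeat_length Expected dyad-to-dyad spacing in bp.
#' @param n_indices Number of array indices to report.
#' @return Numeric vector of per-index sds (bp), `NA` where fewer than 3
#'   anchors had an assignment.
#' @export
phasing_decay <- function(x, anchors = NULL, repeat_length = 207L,
                          n_indices = 3L) {
  stop_if_not_scalar_number(n_indices, "n_indices", min = 2)
  n_indices <- as.integer(n_indices)
  if (inherits(x, "nuc_config")) {
    centers <- setNames(x$sites$center, x$sites$label)
    strands <- setNames(x$sites$strand, x$sites$label)
    sgn <- ifelse(strands[x$dyads$site] == "+", 1L, -1L)
    rel <- sgn * (x$dyads$pos - centers[x$dyads$site])
    sds <- vapply(seq_len(n_indices) - 1L, function(k) {
      d <- rel[x$dyads$index == k]
      if (length(d) < 3L) NA_real_ else sd(d)
    }, numeric(1))
    return(setNames(sds, sprintf("index%d", seq_len(n_indices) - 1L)))
  }
  if (is.null(anchors))
    stop("`anchors` required when `x` is a call set", call. = FALSE)
  # anchor-relative downstream positions of all calls
  rel_by_anchor <- lapply(seq_len(nrow(anchors)), function(i) {
    cc <- x[x$chrom == anchors$chrom[i], , drop = FALSE]
    sgn <- if (anchors$strand[i] == "+") 1L else -1L
    rel <- sgn * (cc$pos - anchors$center[i])
    sort(rel[rel >= 0 & rel <= (n_indices + 1L) * repeat_length])
  })
  prox <- vapply(rel_by_anchor, function(r)
    if (length(r)) r[1] else NA_real_, numeric(1))
  if (all(is.na(prox)))
    return(setNames(rep(NA_real_, n_indices),
                    sprintf("index%d", seq_len(n_indices) - 1L)))
  d0 <- median(prox, na.rm = TRUE)
  sds <- vapply(seq_len(n_indices) - 1L, function(k) {
    expected <- d0 + k * repeat_length
    assigned <- vapply(rel_by_anchor, function(r) {
      if (!length(r)) return(NA_real_)
      dd <- abs(r - expected)
      j <- which.min(dd)
      if (dd[j] <= repeat_length / 2) r[j] else NA_real_
    }, numeric(1))
    assigned <- assigned[!is.na(assigned)]
    if (length(assigned) < 3L) NA_real_ else sd(assigned)
  }, numeric(1))
  setNames(sds, sprintf("index%d", seq_len(n_indices) - 1L))
}
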