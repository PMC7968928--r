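# Anchor-centred signal matrices, meta-profiles, genotype differences and
# row clustering.

#' Extract an anchor-centred signal matrix
#'
#' One row per anchor, columns covering relative positions
#' `-flank..+flank`. With `orient_by_strand = TRUE`, minus-strand rows are
#' reversed so "downstream of the anchor" is a consistent column direction.
#' Anchors whose window leaves the chromosome are dropped (not padded); the
#' dropped count is recorded in `attr(, "n_dropped")`.
#'
#' @param track A `signal_track`.
#' @param anchors An `anchor_set`.
#' @param flank Half-window in bp (columns = `2 * flank + 1`).
#' @param orient_by_strand Reverse minus-strand rows.
#' @return A `signal_matrix`: numeric matrix with anchor labels as rownames,
#'   relative positions as colnames, and attributes `positions`,
#'   `oriented`, `n_dropped`.
#' @export
site_matrix <- function(track, anchors, flank, orient_by_strand = TRUE) {
  stopifnot(inherits(track, "signal_track"))
  stop_if_not_scalar_number(flank, "flank", min = 1)
  flank <- as.integer(flank)
  positions <- seq(-flank, flank)
  lens <- vapply(track$values, length, numeric(1))
  ok <- anchors$chrom %in% names(track$values)
  ok[ok] <- anchors$center[ok] - flank >= 0L &
    anchors$center[ok] + flank < lens[anchors$chrom[ok]]
  n_dropped <- sum(!ok)
  kept <- anchors[ok, , drop = FALSE]
  if (nrow(kept) == 0L)
    stop("all anchors fall out of bounds for this flank", call. = FALSE)

  m <- matrix(NA_real_, nrow = nrow(kept), ncol = length(positions),
              dimnames = list(kept$label, positions))
  for (i in seq_len(nrow(kept))) {
    v <- track$values[[kept$chrom[i]]]
    row <- v[(kept$center[i] - flank + 1L):(kept$center[i] + flank + 1L)]
    if (orient_by_strand && kept$strand[i] == "-") row <- rev(row)
    m[i, ] <- row
  }
  structure(m, positions = positions, oriented = orient_by_strand,
            n_dropped = n_dropped, class = c("signal_matrix", class(m)))
}

#' Average signal profile around anchors
#'
#' The column-mean vector of [site_matrix()] on the same inputs: the mean
#' signal at each position relative to the anchor centers.
#'
#' @inheritParams site_matrix
#' @return Named numeric vector over relative positions `-flank..+flank`.
#' @export
meta_profile <- function(track, anchors, flank, orient_by_strand = TRUE) {
  m <- site_matrix(track, anchors, flank, orient_by_strand)
  colMeans(m)
}

#' Difference between two signal matrices (mutant minus reference)
#'
#' Elementwise `matrix_mut - matrix_ref` with row order preserved, so rows
#' stay linked across genotype panels. Positive values mark signal gained in
#' the mutant condition.
#'
#' @param matrix_mut,matrix_ref `signal_matrix` objects with identical row
#'   labels, columns and orientation.
#' @return A `signal_matrix` of differences.
#' @export
diff_matrix <- function(matrix_mut, matrix_ref) {
  if (!identical(rownames(matrix_mut), rownames(matrix_ref)) ||
      !identical(colnames(matrix_mut), colnames(matrix_ref)))
    stop("matrices must share identical row labels and columns",
         call. = FALSE)
  if (!identical(attr(matrix_mut, "oriented"), attr(matrix_ref, "oriented")))
    stop("matrices must share the same orientation mode", call. = FALSE)
  d <- unclass(matrix_mut) - unclass(matrix_ref)
  structure(d, positions = attr(matrix_mut, "positions"),
            oriented = attr(matrix_mut, "oriented"), n_dropped = NA_integer_,
            class = class(matrix_mut))
}

#' Cluster matrix rows by k-means
#'
#' Squared-Euclidean k-means on rows with a fixed seed, for ordering
#' difference-heatmap rows into response classes.
#'
#' @param matrix A `signal_matrix` (or any numeric matrix).
#' @param k Number of clusters (`1 <= k <= nrow`).
#' @param seed Integer seed; labels are deterministic given the seed.
#' @param nstart Random restarts passed to [stats::kmeans()].
#' @return Integer cluster labels named by row label.
#' @export
cluster_rows <- function(matrix, k, seed = 1L, nstart = 10L) {
  stop_if_not_scalar_number(k, "k", min = 1)
  if (k > nrow(matrix))
    stop("`k` cannot exceed the number of rows", call. = FALSE)
  m <- unclass(matrix)
  labels <- if (k == 1L) rep(1L, nrow(m)) else
    with_seed(seed, kmeans(m, centers = k, nstart = nstart,
                           iter.max = 100L)$cluster)
  setNames(as.integer(labels), rownames(m))
}

#' Write a signal matrix as TSV
#'
#' Tab-separated with a header row of relative positions and anchor labels
#' in the first column.
#'
#' @param matrix A `signal_matrix`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(matrix, path) {
  df <- data.frame(anchor = rownames(matrix), unclass(matrix),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
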