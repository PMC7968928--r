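# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. All exported stochastic operations funnel through this so a
# `seed` argument is the only source of randomness.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a distinct sub-seed from a master seed, kept below 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) * 7919L + as.integer(offset) * 104729L) %% 2147483587L
}

stop_if_not_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min)
    stop(sprintf("`%s` must be a single finite number >= %s", name, min),
         call. = FALSE)
  invisible(x)
}

# 0-based half-open interval overlap against a (chrom, start, end) table,
# via IRanges (converted to 1-based closed).
overlaps_features <- function(chrom, start, end, features) {
  if (is.null(features) || nrow(features) == 0L)
    return(rep(FALSE, length(chrom)))
  out <- rep(FALSE, length(chrom))
  for (ch in unique(chrom)) {
    i <- chrom == ch
    f <- features[features$chrom == ch, , drop = FALSE]
    if (nrow(f) == 0L) next
    q <- IRanges::IRanges(start = start[i] + 1L, end = end[i])
    s <- IRanges::IRanges(start = f$start + 1L, end = f$end)
    out[i] <- IRanges::overlapsAny(q, s)
  }
  out
}

fmt_num <- function(x) sprintf("%.17g", x)
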