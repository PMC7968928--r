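#' Place genotype-dependent phased nucleosome arrays at planted motifs
#'
#' At every planted motif an array of `n_per_array` nucleosome dyads is laid
#' out on the motif's downstream (strand) side. In a remodeler-on genotype
#' (`"WT"`), factor-bound sites get their proximal nucleosome positioned so
#' the motif-proximal edge of the 147-bp core sits `edge_gap` bp from the
#' motif center, i.e. the proximal dyad lands
#' `edge_gap + floor((core_length - 1)/2)` bp from the center (103 bp with
#' the defaults). In remodeler-null or factor-null genotypes — and at
#' unbound sites in any genotype — the whole array sits `null_shift` bp
#' further from the motif. Subsequent dyads follow at `repeat_length`
#' increments, with per-index Gaussian positional jitter that grows along
#' the array (`jitter_schedule`), emulating the rapid decay of phasing away
#' from the positioned proximal nucleosome.
#'
#' @param genome A `genome_model` from [make_genome()].
#' @param genotype One of `"WT"` (remodeler on), `"remodeler-null"`,
#'   `"factor-null"`.
#' @param core_length Nucleosome core size in bp (147).
#' @param edge_gap Distance from motif center to the proximal core edge in
#'   the remodeler-on state, bp (30).
#' @param repeat_length Dyad-to-dyad spacing in bp (207 = 147-bp core plus
#'   60-bp linker).
#' @param n_per_array Nucleosomes per array.
#' @param jitter_schedule Non-decreasing vector (length >= `n_per_array`) of
#'   per-index dyad position standard deviations, bp.
#' @param null_shift Motif-distal displacement (bp) of arrays not positioned
#'   by the remodeler. Must not push the proximal core across the motif
#'   center.
#' @param seed Integer seed.
#'
#' @return A `nuc_config`: list with `genotype`, `sites` (the motif registry
#'   with the per-site expected proximal distance), `dyads` (data.frame
#'   `chrom`, `pos`, `site`, `index`, sorted by position within chromosome),
#'   and the geometry parameters.
#' @examples
#' g <- make_genome(chrom_length = 50000, n_motif_sites = 6, seed = 1)
#' cfg <- place_nucleosomes(g, "WT", seed = 1)
#' head(cfg$dyads)
#' @export
place_nucleosomes <- function(genome, genotype = "WT",
                              core_length = 147L, edge_gap = 30L,
                              repeat_length = 207L, n_per_array = 4L,
                              jitter_schedule = c(3, 8, 16, 26),
                              null_shift = 50L, seed = 1L) {
  stopifnot(inherits(genome, "genome_model"))
  genotype <- match.arg(genotype, c("WT", "remodeler-null", "factor-null"))
  stop_if_not_scalar_number(core_length, "core_length", min = 1)
  stop_if_not_scalar_number(n_per_array, "n_per_array", min = 1)
  if (length(jitter_schedule) < n_per_array)
    stop("`jitter_schedule` must supply an sd for every array index",
         call. = FALSE)
  if (is.unsorted(jitter_schedule))
    stop("`jitter_schedule` must be non-decreasing (phasing decays with ",
         "distance from the anchor)", call. = FALSE)

  half_core <- (core_length - 1L) %/% 2L
  d_on <- edge_gap + half_core
  d_null <- d_on + null_shift
  if (d_null < half_core)
    stop("`null_shift` would push the proximal nucleosome core across the ",
         "motif center", call. = FALSE)

  sites <- genome$motifs
  if (nrow(sites) == 0L)
    stop("genome has no planted motifs to anchor arrays on", call. = FALSE)
  remodeled <- switch(genotype,
    "WT" = sites$bound,
    "remodeler-null" = rep(FALSE, nrow(sites)),
    "factor-null" = rep(FALSE, nrow(sites)))
  sites$proximal_distance <- ifelse(remodeled, d_on, d_null)
  sites$remodeled <- remodeled

  # deterministic capacity check on the jitter-free extent of each array
  extent <- sites$proximal_distance + (n_per_array - 1L) * repeat_length +
    half_core
  L <- genome$chrom_lengths[sites$chrom]
  fits <- ifelse(sites$strand == "+", sites$center + extent < L,
                 sites$center - extent >= 0)
  if (!all(fits))
    stop(sprintf("%d array(s) would extend past chromosome bounds",
                 sum(!fits)), call. = FALSE)

  with_seed(seed, {
    n_sites <- nrow(sites)
    idx <- rep(seq_len(n_per_array) - 1L, times = n_sites)
    site_i <- rep(seq_len(n_sites), each = n_per_array)
    sgn <- ifelse(sites$strand[site_i] == "+", 1L, -1L)
    dist0 <- sites$proximal_distance[site_i]
    jit <- round(rnorm(length(idx), mean = 0,
                       sd = jitter_schedule[idx + 1L]))
    pos <- sites$center[site_i] + sgn * (dist0 + idx * repeat_length + jit)
    dyads <- data.frame(chrom = sites$chrom[site_i], pos = as.integer(pos),
                        site = sites$label[site_i], index = idx,
                        stringsAsFactors = FALSE)
    keep <- dyads$pos >= 0L &
      dyads$pos < genome$chrom_lengths[dyads$chrom]
    dyads <- dyads[keep, , drop = FALSE]
    dyads <- dyads[order(dyads$chrom, dyads$pos), ]
    rownames(dyads) <- NULL

    structure(list(
      genotype = genotype,
      sites = sites,
      dyads = dyads,
      core_length = as.integer(core_length),
      edge_gap = as.integer(edge_gap),
      repeat_length = as.integer(repeat_length),
      n_per_array = as.integer(n_per_array),
      jitter_schedule = jitter_schedule[seq_len(n_per_array)],
      null_shift = as.integer(null_shift),
      chrom_lengths = genome$chrom_lengths
    ), class = "nuc_config")
  })
}

#' @export
print.nuc_config <- function(x, ...) {
  cat(sprintf("nuc_config [%s]: %d dyads at %d sites (%d remodeled)\n",
              x$genotype, nrow(x$dyads), nrow(x$sites),
              sum(x$sites$remodeled)))
  cat(sprintf("  core %d bp, edge gap %d bp, repeat %d bp, null shift %d bp\n",
              x$core_length, x$edge_gap, x$repeat_length, x$null_shift))
  invisible(x)
}
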