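# Configuration-driven orchestration: simulate -> tracks -> anchors ->
# matrices -> clusters -> shifts -> peaks -> offsets.

pipeline_defaults <- function() {
  list(
    out_dir = NULL,
    seed = 1L,
    genome = list(n_chrom = 1L, chrom_length = 100000L,
                  motif_iupac = "WNGGCGGCWW", n_motif_sites = 20L,
                  bound_fraction = 0.5, n_features = 20L),
    genotypes = c("WT", "remodeler-null"),
    contrasts = list(c(mut = "remodeler-null", ref = "WT")),
    nucleosome = list(core_length = 147L, edge_gap = 30L,
                      repeat_length = 207L, n_per_array = 4L,
                      jitter_schedule = c(3, 8, 16, 26), null_shift = 50L),
    depth = 50L,
    length_model = list(mean = 147, sd = 15, out_of_range_rate = 0.05),
    min_len = 100L,
    max_len = 200L,
    deduplicate = TRUE,
    flank = 500L,
    k = 2L,
    window = 400L,
    threshold = 3.0,
    extend = 300L,
    chip = list(enrichment = 6, footprint = 400L, subunit_offset = -150L,
                n_reads = 100000L, read_length = 37L)
  )
}

#' Validate and complete a pipeline configuration
#'
#' Accepts a configuration list or a path to a YAML file, injects defaults
#' for omitted keys (size filter 100/200 bp, peak window 400 bp, threshold
#' 3.0, read extension 300 bp, core 147 bp, edge gap 30 bp, motif
#' WNGGCGGCWW, ...), and rejects unknown or contradictory settings.
#'
#' @param config Named list, or path to a YAML config file.
#' @return The completed configuration list (class `run_config`).
#' @examples
#' cfg <- validate_config(list(out_dir = tempfile(), depth = 20))
#' cfg$min_len
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop(sprintf("config file not found: %s", config), call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path",
                             call. = FALSE)
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  merged <- utils::modifyList(defaults, config)
  # modifyList merges by name, which cannot replace unnamed list entries
  if (!is.null(config$contrasts)) merged$contrasts <- config$contrasts
  if (!is.null(config$genotypes)) merged$genotypes <- unlist(config$genotypes)
  for (blk in c("genome", "nucleosome", "length_model", "chip")) {
    unknown <- setdiff(names(merged[[blk]]), names(defaults[[blk]]))
    if (length(unknown))
      stop(sprintf("unknown config key(s) in `%s`: %s", blk,
                   paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (merged$min_len > merged$max_len)
    stop("`min_len` must be <= `max_len`", call. = FALSE)
  if (merged$threshold <= 0) stop("`threshold` must be > 0", call. = FALSE)
  if (is.null(merged$out_dir))
    stop("`out_dir` is required", call. = FALSE)
  bad <- vapply(merged$contrasts, function(cc)
    !all(cc %in% merged$genotypes), logical(1))
  if (any(bad))
    stop("every contrast must name configured genotypes", call. = FALSE)
  class(merged) <- c("run_config", "list")
  merged
}

#' Run the full synthetic-chromatin analysis pipeline
#'
#' Executes all stages in dependency order: genome simulation, per-genotype
#' nucleosome placement and MNase fragment simulation, size filtering, dyad
#' tracks with mean-1.0 normalization, intergenic motif scanning,
#' anchor-centred matrices and meta-profiles, per-contrast difference
#' matrices with k-means row clusters, nucleosome calls, proximal distances
#' and shifts, and a two-subunit ChIP branch (coverage, sliding-window
#' peaks, overlap statistics, paired centre offsets). Artifacts are written
#' under `config$out_dir`, and a manifest of per-stage counts and file
#' checksums is written last; re-running an identical config reproduces
#' identical checksums.
#'
#' @param config A validated `run_config` (or anything accepted by
#'   [validate_config()]).
#' @return The run manifest (list, class `run_manifest`), invisibly.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  counts <- list()
  stage <- "init"
  manifest_path <- file.path(out_dir, "manifest.json")

  result <- tryCatch({
    stage <- "genome"
    g <- do.call(make_genome, c(config$genome,
                                list(seed = derive_seed(config$seed, 1L))))
    files["genome_fasta"] <- write_genome_fasta(
      g, file.path(out_dir, "genome.fa"))
    files["features_bed"] <- write_bed(
      g$features, file.path(out_dir, "features.bed"))
    mot <- g$motifs
    files["motifs_bed"] <- write_bed(
      data.frame(chrom = mot$chrom, start = mot$center,
                 end = mot$center + 1L, name = mot$label,
                 score = as.integer(mot$bound), strand = mot$strand),
      file.path(out_dir, "planted_motifs.bed"))
    counts$planted_motifs <- nrow(mot)

    stage <- "tracks"
    tracks <- list()
    for (gi in seq_along(config$genotypes)) {
      gt <- config$genotypes[[gi]]
      cfg <- do.call(place_nucleosomes, c(
        list(genome = g, genotype = gt),
        config$nucleosome,
        list(seed = derive_seed(config$seed, 10L + gi))))
      fr <- simulate_mnase_fragments(
        cfg, depth = config$depth, length_model = config$length_model,
        seed = derive_seed(config$seed, 20L + gi))
      counts[[paste0("fragments_in_", gt)]] <- n_fragments(fr)
      fr <- filter_fragments(fr, config$min_len, config$max_len,
                             config$deduplicate)
      counts[[paste0("fragments_retained_", gt)]] <- n_fragments(fr)
      tr <- normalize_mean(dyads_from_fragments(fr, g$chrom_lengths))
      tracks[[gt]] <- tr
      files[paste0("track_", gt)] <- write_track(
        tr, file.path(out_dir, sprintf("dyads_%s.bedGraph", gt)))
    }

    stage <- "anchors"
    anchors <- scan_motif(g, intergenic_only = TRUE)
    files["anchors_bed"] <- write_anchors_bed(
      anchors, file.path(out_dir, "anchors.bed"))
    counts$anchors <- nrow(anchors)

    stage <- "matrices"
    mats <- lapply(tracks, site_matrix, anchors = anchors,
                   flank = config$flank)
    counts$anchors_dropped <- attr(mats[[1]], "n_dropped")
    for (gt in names(mats))
      files[paste0("matrix_", gt)] <- write_matrix_tsv(
        mats[[gt]], file.path(out_dir, sprintf("matrix_%s.tsv", gt)))

    stage <- "contrasts"
    shift_summaries <- list()
    cluster_sizes <- list()
    calls <- lapply(tracks, call_nucleosome_dyads, min_height = 0,
                    min_spacing = 120L, sigma = 20)
    for (cc in config$contrasts) {
      tag <- sprintf("%s_vs_%s", cc[["mut"]], cc[["ref"]])
      dm <- diff_matrix(mats[[cc[["mut"]]]], mats[[cc[["ref"]]]])
      files[paste0("diff_", tag)] <- write_matrix_tsv(
        dm, file.path(out_dir, sprintf("diff_%s.tsv", tag)))
      k_eff <- min(config$k, nrow(unique(as.data.frame(unclass(dm)))))
      cl <- cluster_rows(dm, k = k_eff,
                         seed = derive_seed(config$seed, 30L))
      cluster_sizes[[tag]] <- as.integer(table(cl))
      files[paste0("clusters_", tag)] <- {
        p <- file.path(out_dir, sprintf("clusters_%s.tsv", tag))
        write.table(data.frame(anchor = names(cl), cluster = cl), p,
                    sep = "\t", quote = FALSE, row.names = FALSE)
        p
      }
      d_ref <- proximal_distance(anchors, calls[[cc[["ref"]]]])
      d_mut <- proximal_distance(anchors, calls[[cc[["mut"]]]])
      sh <- shift_per_anchor(d_ref, d_mut)
      files[paste0("shifts_", tag)] <- {
        p <- file.path(out_dir, sprintf("shifts_%s.tsv", tag))
        write.table(sh, p, sep = "\t", quote = FALSE, row.names = FALSE)
        p
      }
      shift_summaries[[tag]] <- list(n = nrow(sh),
                                     median_shift = median(sh$shift))
    }

    stage <- "chip"
    reads_a <- simulate_chip_reads(
      g, enrichment = config$chip$enrichment,
      footprint = config$chip$footprint, subunit_offset = 0L,
      n_reads = config$chip$n_reads,
      read_length = config$chip$read_length,
      frag_length = config$extend,
      seed = derive_seed(config$seed, 40L))
    reads_b <- simulate_chip_reads(
      g, enrichment = config$chip$enrichment,
      footprint = config$chip$footprint,
      subunit_offset = config$chip$subunit_offset,
      n_reads = config$chip$n_reads,
      read_length = config$chip$read_length,
      frag_length = config$extend,
      seed = derive_seed(config$seed, 41L))
    peaks_a <- call_peaks(coverage_from_reads(reads_a, g$chrom_lengths,
                                              config$extend),
                          window = config$window,
                          threshold = config$threshold)
    peaks_b <- call_peaks(coverage_from_reads(reads_b, g$chrom_lengths,
                                              config$extend),
                          window = config$window,
                          threshold = config$threshold)
    files["peaks_subunitA"] <- write_peaks_bed(
      peaks_a, file.path(out_dir, "peaks_subunitA.bed"))
    files["peaks_subunitB"] <- write_peaks_bed(
      peaks_b, file.path(out_dir, "peaks_subunitB.bed"))
    counts$peaks_subunitA <- nrow(peaks_a)
    counts$peaks_subunitB <- nrow(peaks_b)
    overlap <- peak_overlap_stats(peaks_a, peaks_b)
    offs <- pair_offsets(peaks_a, peaks_b,
                         max_pair_dist = config$chip$footprint + 200L)
    files["offsets"] <- {
      p <- file.path(out_dir, "offsets.tsv")
      write.table(offs, p, sep = "\t", quote = FALSE, row.names = FALSE)
      p
    }
    counts$peaks_paired <- nrow(offs)
    offset_summary <- if (nrow(offs)) offsets_by_cluster(offs) else NULL

    stage <- "manifest"
    manifest <- list(
      tool = "nucshift",
      version = as.character(utils::packageVersion("nucshift")),
      config = unclass(config),
      counts = counts,
      cluster_sizes = cluster_sizes,
      shift_summaries = shift_summaries,
      overlap = overlap,
      offset_summary = offset_summary,
      checksums = as.list(tools::md5sum(unname(files)))
    )
    class(manifest) <- c("run_manifest", "list")
    jsonlite::write_json(unclass(manifest), manifest_path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    manifest
  }, error = function(e) {
    partial <- list(tool = "nucshift", failed_stage = stage,
                    error = conditionMessage(e), counts = counts,
                    checksums = as.list(tools::md5sum(unname(files))))
    jsonlite::write_json(partial, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}

#' Write a human-readable run report
#'
#' Tabulates the manifest's stage counts, cluster sizes, shift medians,
#' peak counts and offset summaries. Apart from the timestamp line, report
#' regeneration from the same manifest is byte-identical.
#'
#' @param manifest A `run_manifest` from [run_pipeline()], or a path to a
#'   `manifest.json`.
#' @param path Optional output file; when `NULL` the lines are returned
#'   only.
#' @return Character vector of report lines, invisibly when written.
#' @export
write_report <- function(manifest, path = NULL) {
  if (is.character(manifest)) {
    if (!file.exists(manifest))
      stop(sprintf("manifest not found: %s", manifest), call. = FALSE)
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  }
  need <- c("counts", "checksums")
  missing <- setdiff(need, names(manifest))
  if (length(missing))
    stop(sprintf("manifest is missing: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  lines <- c(
    sprintf("# nucshift run report (generated %s)",
            format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    "",
    "## Stage counts",
    sprintf("  %-28s %s", names(manifest$counts),
            vapply(manifest$counts, function(x)
              paste(format(x), collapse = ","), character(1))))
  if (length(manifest$cluster_sizes)) {
    lines <- c(lines, "", "## Cluster sizes")
    for (tag in names(manifest$cluster_sizes))
      lines <- c(lines, sprintf("  %-28s %s", tag,
                                paste(manifest$cluster_sizes[[tag]],
                                      collapse = ", ")))
  }
  if (length(manifest$shift_summaries)) {
    lines <- c(lines, "", "## Nucleosome shifts (mutant - reference)")
    for (tag in names(manifest$shift_summaries)) {
      s <- manifest$shift_summaries[[tag]]
      lines <- c(lines, sprintf("  %-28s n=%d median=%g bp", tag, s$n,
                                s$median_shift))
    }
  }
  if (!is.null(manifest$overlap)) {
    ov <- manifest$overlap
    lines <- c(lines, "", "## ChIP peak overlap",
               sprintf("  n_A=%d n_B=%d overlapping=%d jaccard_bp=%.3f",
                       ov$n_A, ov$n_B, ov$n_overlapping, ov$jaccard_bp))
  }
  if (!is.null(manifest$offset_summary)) {
    os <- manifest$offset_summary
    lines <- c(lines, "", "## Subunit centre offsets")
    for (i in seq_len(nrow(os)))
      lines <- c(lines, sprintf("  %-6s n=%d median=%g bp", os$side[i],
                                os$n[i], os$median_offset[i]))
  }
  lines <- c(lines, "", "## Artifact checksums",
             sprintf("  %s  %s", unlist(manifest$checksums),
                     basename(names(manifest$checksums))))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
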