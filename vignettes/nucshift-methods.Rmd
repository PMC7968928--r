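---
title: "Methods: targeted nucleosome positioning analysis with nucshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: targeted nucleosome positioning analysis with nucshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucshift)
```

## The biological question and the measurement model

Chromatin remodeling enzymes of the ISWI family can be recruited by
sequence-specific DNA-binding factors (in budding yeast, the repressor Ume6
recruiting the Isw2–Itc1 complex is the canonical example). When recruitment
works, the remodeler positions a single nucleosome at a fixed distance from
the factor's binding motif: with a 147-bp nucleosome core whose
motif-proximal edge is held 30 bp from the motif center, the core's dyad
(its central base pair) sits at

$$ d_{\mathrm{prox}} = 30 + \lfloor (147-1)/2 \rfloor = 103\ \mathrm{bp} $$

from the motif center — about 100 nt, half the ~200-nt dyad-to-dyad repeat
that nonspecific spacing against a barrier would produce. Away from this
positioned proximal nucleosome, phasing decays: each successive nucleosome
in the array is less precisely placed.

MNase-seq measures this. Micrococcal nuclease digests unprotected DNA and
leaves ~147-bp nucleosome-protected fragments; the midpoint of a
paired-end fragment estimates the dyad of the nucleosome that protected it.
ChIP-seq maps where the remodeler (or a subunit fragment) binds; because
the accessory subunit engages the recruiting factor while the catalytic
subunit engages the nucleosome, the two subunits' ChIP peaks are offset
from one another by a fixed distance on a consistent side.

`nucshift` implements the complete computational arm of such a study —
dyad tracks, motif-anchored matrices and profiles, genotype contrasts,
shift and phasing-decay quantification, and sliding-window ChIP peak
calling with subunit-offset analysis — plus a synthetic-chromatin
generator that produces data with exactly this structure and full ground
truth, so every stage can be verified end to end without external data.

## The dyad-track pipeline

1. **Fragment input** (`read_fragment_intervals()`): paired-end templates
   from BAM (properly paired records only; orphans are counted and
   skipped), BEDPE or BED. All coordinates are converted to 0-based
   half-open.
2. **Size filter** (`filter_fragments()`): retain fragments of 100–200 bp,
   *inclusive* at both ends. This window selects mononucleosome-protected
   fragments; "between 100 and 200 bp" is read inclusively, and the
   boundary behaviour is pinned by tests. "Unique fragments" is read as
   exact-coordinate deduplication (PCR-duplicate removal), so identical
   (chrom, start, end) records collapse to multiplicity 1.
3. **Dyad counting** (`dyads_from_fragments()`): each fragment adds one
   count at `floor((start + end)/2)`. For even-span fragments the floor
   tie-break is a fixed, documented convention. Total track mass equals
   the retained fragment count exactly.
4. **Normalization** (`normalize_mean()`): values are scaled by
   genome length / total mass, giving a genome-wide mean of exactly 1.0
   read/bp. The operation is idempotent and scale-free. We normalize the
   *dyad* track (what the figures display) rather than fragment coverage;
   the choice is recorded here because the phrase "average read/bp" could
   support either reading.
5. **Smoothing** (`smooth_track()`) is deliberately separate and optional:
   dyad tracks are kept as unsmoothed single-bp counts, and smoothing
   (Gaussian, truncated at 4σ, reflected boundaries, exact mass rescale)
   is applied explicitly where a consumer wants it (display, peak
   picking).

## Anchor-centred analysis

`scan_motif()` finds degenerate-motif instances (IUPAC alphabet; W = A/T,
N = any, ...) on both strands via Biostrings. Conventions, chosen once and
used everywhere: the center of an even-length motif of length $L$ at start
$s$ is $s + L/2$; reverse-strand matches are reported at the center of
their forward-strand footprint with strand `-`; "intergenic" means the
motif footprint overlaps no interval in a *user-supplied* feature set —
the package hard-codes no annotation, so printed genome-specific counts
(e.g. a specific number of intergenic motif instances in yeast) are inputs,
not constants.

`site_matrix()` extracts one row per anchor over ±`flank` bp;
minus-strand rows are reversed when `orient_by_strand = TRUE` so
"downstream of the motif" is a consistent column direction. Anchors whose
window leaves the chromosome are dropped, not padded, and counted.
`meta_profile()` is defined as the column mean of this matrix (the two are
consistent by construction, asserted to 1e-12 in tests).

`diff_matrix()` uses the **mutant − reference** sign convention: positive
values mark signal gained in the mutant, and row order is preserved so
rows stay linked across panels. `cluster_rows()` is seed-fixed k-means
(squared Euclidean) with `k` supplied by the caller — the source analyses
never name their clustering algorithm or k, so this is a package design
choice: k-means is the simplest deterministic-under-seed method that
reproduces the qualitative "response classes" seen in such heatmaps, and
`k` is data-set specific, not an algorithmic constant.

`call_nucleosome_dyads()` picks local maxima of the σ-smoothed track
(plateaus report their leftmost position), then greedily enforces
`min_spacing` keeping the higher call (ties: leftmost).
`proximal_distance()` and `shift_per_anchor()` quantify the figures'
arrows: shift = distance(no-remodeler) − distance(remodeler), so a
positive shift means the remodeler pulls the nucleosome toward the motif.
`phasing_decay()` reports the per-array-index standard deviation of
anchor-relative dyad positions; from call sets, index *k* is assigned the
nearest call within half a repeat length of its expected position,
anchored on the median proximal distance.

## ChIP enrichment and subunit offsets

`coverage_from_reads()` extends each single-end read from its 5′ end in
its strand direction to 300 bp — the study's average sonication fragment
size — and normalizes coverage to genome mean 1.0. There is no
input/mock subtraction: enrichment is relative to the genome-mean
baseline, which is how the source pipeline is described.

`call_peaks()` is the bespoke caller: a 400-bp window slides at 1-bp steps
(the step is unstated in the source; 1 bp is the resolution-maximal,
deterministic choice); any window whose mean is **≥ 3.0** (inclusive — the
threshold is read as the minimum qualifying value, pinned by a boundary
test) qualifies, and overlapping/adjacent qualifying windows merge into
one peak spanning their union. The peak center is the signal-weighted
centroid (a max-position alternative is available by flag), since the
source marks "centers" without defining them. The caller requires a
normalized track and refuses anything else, which makes calls invariant to
any positive rescaling of the raw coverage.

`pair_offsets()` matches each peak of one subunit to the nearest peak
center of the other (greedy one-to-one by distance, ties leftmost,
bounded by `max_pair_dist`), records `offset = center_B − center_A`, and
classifies `side = "left"` iff offset < 0; `offsets_by_cluster()`
summarises the two side clusters. `peak_overlap_stats()` reports
intersection counts and the standard bp-level Jaccard index
|A∩B|/|A∪B| of the two peak unions.

## What the synthetic generator emulates — and what it does not

`make_genome()` builds uniform-composition random chromosomes (a supplied
composition is accepted), plants non-overlapping IUPAC motif instances —
half intergenic, half inside feature intervals by default — and flags a
`bound_fraction` of them as factor-bound, so bound-vs-unbound contrasts
are testable. A keep-out margin at chromosome ends (default 1200 bp)
leaves room for complete arrays. Planted instances are concrete
realizations of the pattern, so a scanner must recover every planted
center; chance background matches are permitted and simply extend the
scan result.

`place_nucleosomes()` encodes the positioning rule. Remodeler-on
("WT") genotype, bound site: proximal dyad at 103 bp
(edge gap 30 + half-core 73). Remodeler-null and factor-null genotypes —
and unbound sites in any genotype — sit `null_shift` bp (default 50)
further from the motif, matching the observation that without the
remodeler nucleosomes are always more motif-distal. Arrays run on the
motif's strand-downstream side at `repeat_length` = 207 bp
(147-bp core + 60-bp linker) with per-index Gaussian jitter from a
non-decreasing `jitter_schedule` (default 3, 8, 16, 26 bp) encoding
phasing decay. The defaults *are* the study conditions; where the source
states no value (jitter magnitudes, fragment-length dispersion,
midpoint wobble of 3 bp) the defaults are one-time modeling choices of
plausible magnitude for yeast MNase data, and they are not tuned.

`simulate_mnase_fragments()` draws `depth` fragments per dyad with
midpoint = dyad + small wobble and truncated-Normal(147, 15) lengths
confined to [100, 200]; an `out_of_range_rate` mass comes from two
MNase-ladder side lobes (~80 bp subnucleosomal, ~320 bp dinucleosomal) to
exercise the size filter. `simulate_chip_reads()` places
sonication-style fragments uniformly either genome-wide (background) or
within a footprint window centred `subunit_offset` bp from bound motifs,
with the site fraction chosen so that site/background coverage equals the
requested fold `enrichment`; one read is taken from a random fragment
end, so 5′-extension reconstructs fragment coverage.

Deliberately **not** modelled: sequence-level reads (no errors or
qualities), alignment artefacts, MNase digestion sequence bias, chromatin
heterogeneity between cells, replicate structure, and real genome
composition. Passing tests therefore demonstrate that the *computational
pipeline* is correct and that its parameters are recoverable from data
with the assumed structure — not that the pipeline is robust to every
artefact of real sequencing data.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; BED-family files match on
  disk, wiggle and SAM convert at the boundary. bedGraph output includes
  zero runs so files round-trip without a separate chromosome-size file,
  and values are printed at full double precision (round-trip asserted to
  1e-9).
* Normalization requires nonzero mass (all-zero tracks are an error);
  smoothing with σ = 0 is the identity; negative σ is an error.
* k-means restarts (`nstart = 10`) under one seed make labels
  deterministic; `k` greater than the row count is an error, and the
  pipeline caps `k` at the number of distinct rows (an identical-genotype
  contrast yields an all-zero matrix).
* The peak caller skips chromosomes shorter than the window, with a
  logged message.
* The pipeline derives all stage seeds from one master seed, so a config
  re-run reproduces byte-identical artifacts (asserted via manifest
  checksums).

## Problem sizes used in the test suite

The suite verifies geometry at 1000–2000 planted sites, recovers
configured shifts of 20/50/80 bp over 20 seeds at 100 sites ×
depth 100, recovers the jitter schedule from ~300k fragments at 2000
anchors, compares the peak caller against an exhaustive window-scan
oracle on twenty 50-kb tracks, and the motif scanner against a
positionwise IUPAC oracle on 100-kb genomes. These sizes were chosen as
the smallest at which the Monte-Carlo tolerances (10–15% on standard
deviations, ±2 bp on median shifts, ±10 bp on subunit offsets) are
comfortably stable.

## Known limitations

* The generator's arrays are one-sided (strand-downstream of each motif);
  real loci often have arrays on both sides of a bound factor.
* `phasing_decay()` from call sets assumes the proximal distance is
  shared across anchors (it anchors index windows on the median), so
  mixtures of bound and unbound sites should be split before estimating
  decay.
* The peak caller has no background model; it is a faithful
  implementation of the threshold-on-normalized-coverage method, not a
  statistical caller, and inherits that method's behaviour on small or
  highly enriched genomes (mean-1.0 normalization compresses enrichment
  when a large genome fraction is enriched).
* Greedy offset pairing is one-to-one and distance-ordered; in dense peak
  landscapes a global assignment could differ.
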