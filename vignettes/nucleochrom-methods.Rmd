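---
title: "Methods: chromatin analysis of multi-compartment genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin analysis of multi-compartment genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Chlorarachniophyte algae such as *Bigelowiella natans* carry four genomes in
one cell: the host nucleus, the nucleomorph (the vestigial nucleus of a green
algal secondary endosymbiont, the smallest known eukaryotic genome at a few
hundred kilobases, organized as three highly AT-rich chromosomes with
subtelomeric rDNA arrays), a mitochondrion and a plastid. Bulk ATAC-seq,
KAS-seq and Hi-C libraries made from such cells mix fragments from all four
compartments, which differ enormously in copy number (the organelles are
present at tens of copies per nuclear genome, the nucleomorph at roughly
two), in chromatinization (organelles carry no nucleosomes), and in sequence
uniqueness (rDNA arrays are internally repetitive). Any statement like "the
nucleomorph is N-fold more accessible than the nucleus" therefore requires
copy-number-aware, mappability-corrected normalization against a DNA-mass
input. `nucleochrom` implements this analysis layer together with a
synthetic-data generator that makes every stage testable by parameter
recovery.

## Containers and conventions

A genome is a `comp_genome`: sequences, per-chromosome compartment labels and
relative copy numbers, gene annotations (with an `is_rdna` flag) and telomere
intervals. Fragments are plain data frames (`chrom`, `start`, `end`,
`weight`), where `weight` in (0, 1] carries multimapper normalization
(`assign_multimapper_weights()` gives each of a fragment's k placements
weight 1/k, conserving total library weight). All internal coordinates are
0-based half-open; GFF3 and `.pairs` files are converted exactly once at the
file boundary. TSSs are the annotated 5' gene ends; in compact genome
annotations these are often translation starts, a known caveat that shifts
but does not invalidate TSS-anchored profiles.

## Mappability and corrected RPKM

`compute_mappability(genome, L)` tiles every chromosome with length-`L`
reads at every start position. A tile is *uniquely mapping* iff its sequence,
counting the reverse complement as the same read, occurs exactly once in the
whole genome. The mappability of a position is (number of unique tiles
covering it) / (number of tiles covering it): `R/L` in chromosome interiors,
with the denominator shrinking to the number of valid placements near
chromosome ends, so a fully unique genome scores 1 everywhere. Uniqueness is
decided by exact k-mer multiplicity rather than a mismatch-tolerant aligner;
this is deterministic, dependency-free and slightly *stricter* than aligner
based tracks (a tile with a 1-mismatch twin still counts as unique here but
may multi-map under `-v 2` alignment policies). Note the palindrome corner
case: a reverse-complement-palindromic tile matches itself on both strands
and is therefore never unique under this definition.

RPKM values are corrected by multiplying with the reciprocal of the region's
mean mappability (`mappability_correct_rpkm()`); regions with zero mean
mappability are reported as unquantifiable rather than silently dropped.

## Enrichment over input

`compute_rpkm()` assigns each fragment to exactly one region by its
*midpoint*, which makes weight conservation across any partition of the
genome exact; whether overlap or midpoint counting was used in the original
analyses is unstated, and midpoint is fixed here for that conservation
property. `compute_enrichment()` reports, per compartment / chromosome /
region class (rDNA vs the rest of the nucleomorph), the ratio of
mappability-corrected treatment RPKM to input RPKM. Group values pool weight
and length over the group's regions (never a mean of per-chromosome ratios),
and each library is normalized by its own size, so the table is invariant to
sequencing depth. With `normalize_to = "nucleus"` the table is expressed
relative to the host genome; this removes the library-composition constant
and is how the compartment accessibility multipliers of the simulator are
recovered. `estimate_copy_numbers()` is the same machinery applied to an
input library alone, anchored to the median nuclear chromosome.

## Fragment-length spectra

`length_spectrum()` tallies weighted fragment lengths per compartment;
`detect_modes()` smooths the density with a Gaussian kernel (default
bandwidth 10 bp, reflective boundary at length 0) and reports local maxima
whose *topographic prominence* — height above the lowest point separating
the peak from the nearest higher point, or the spectrum boundary — exceeds
5% of the maximum smoothed density. The prominence definition matters: with
prominence measured only against adjacent candidate maxima, small bandwidths
fragment a true peak into noise candidates and suppress it; the topographic
definition keeps mode counts non-increasing in the bandwidth in practice. A
nucleosomal "shoulder" that never forms a local maximum is not forced into a
mode; it is simply not reported.

## TSS profiles, peaks and controls

`tss_profile()` accumulates full-span weighted fragment coverage around
anchors (cut-site counting is available via a flag), flipping minus-strand
rows so positive offsets point downstream. The metaplot is the column mean,
and profile matrices are additive over library splits, which the tests
exploit. `call_peaks_simple()` is a deliberately small stand-in for a peak
caller: sliding windows are tested against a Poisson with rate
`max(genome-wide, local +/- 5 kbp)` scaled to the window; overlapping
significant windows merge, the summit is the maximum-coverage base. It has
no fragment-shift model and no broad mode and is not expected to match MACS2
peak counts on real data; its job is the TSS-centric peak geography, and its
type-I error is calibrated against uniform simulations (at most twice the
nominal rate at p = 1e-3 and 1e-5). `random_control_peaks()` implements the
flat control used for peak-to-TSS distance histograms: boundary coordinates
of 500-bp genome bins. `peak_tss_distances()` reports strand-oriented signed
distances to the nearest TSS, ties broken toward the upstream anchor,
outliers pooled into edge bins.

## Positioned nucleosomes and V-plots

`call_dyads()` replaces a full occupancy model with midpoint-density
calling: within 1-kbp windows stepped every 500 bp (or windows centered on
TSSs), midpoints of nucleosome-sized fragments (160–250 bp) are smoothed
with a Gaussian kernel (bandwidth 20 bp, truncated at five bandwidths);
local maxima above twice the chromosome's uniform-placement density become
candidates, and candidates within 120 bp collapse to the highest-scoring
one. Because the kernel is truncated and maxima are taken against the
whole-chromosome density, calling on overlapping windows then deduplicating
is *exactly* equal to calling on one big window — an invariant the tests
check. This caller reproduces dyad positions and the fragment-size bands
around them, which is all the downstream analyses consume; it is not
equivalent to NucleoATAC and its absolute call counts are not comparable.
`make_vplot()` aggregates (fragment length, midpoint offset) incidences
around anchors with exact mass conservation; `dyad_tss_distribution()` maps
called dyads around TSSs with the conventional +/- 5 bp footprint.

## Hi-C

`bin_contacts()` bins `.pairs` records (1-based on disk, canonical
upper-triangular order) into a dense symmetric matrix whose
upper-triangle-plus-diagonal sum equals the pair count exactly.
`balance()` implements the four normalizations: NONE; VC (divide by row-sum
products) and VC_SQRT (by their square root), both rescaled to preserve
total mass; and KR, solved by the symmetric fixed-point iteration
`x <- x / sqrt(x * (Cx))`, converging when every `x_i (Cx)_i` is within
1e-7 of 1 so that balanced row sums agree within 1e-6. Zero-coverage bins
are always masked; for KR, bins with fewer than 5 raw contacts are masked by
default (sparse rows stall the iteration — the threshold is configurable).
`distance_decay()` gives the cis P(s) curve, `trans_profile()` the per-bin-
pair trans contact frequency of one chromosome against all others (bin-count
normalization; a copy-number divisor can be applied by the caller since
`comp_genome` carries copy numbers), and `telomere_network_score()` the
observed/expected contact ratio between telomeric bins across chromosomes,
plus each chromosome's cis end-to-end fold. Telomere intervals default to
the outermost 10 kbp of nucleomorph chromosomes when no annotation is given;
no numeric subtelomere width is established for these genomes, so the
default is a round number of bins at the 5-kbp working resolution.

## The synthetic-data generator

`sim_config()` states a miniature world with the documented hallmarks of the
chlorarachniophyte system, scaled to desk size:

| parameter | default | rationale |
|---|---|---|
| nucleus | 2 x 300 kbp, copy 1, AT 0.55 | haploid host genome, scaled down ~150x |
| nucleomorph | 140 + 130 + 110 kbp, copy 2, AT 0.75 | three AT-rich chromosomes, ~380 kbp, diploid |
| plastid / mitochondrion | 70 / 40 kbp, copies 20 / 50 | high-copy organelles |
| rDNA windows | 7 kbp per subtelomere | 2 x 7 x 3 / 380 ≈ 11% of the nucleomorph |
| accessibility multipliers | 1 / 10 / 50 / 100 | the ATAC enrichments observed for nucleus / nucleomorph / plastid / mitochondrion |
| fragment-length mixtures | nucleus (100, 200), nucleomorph (90, 220), organelles unimodal 80 | bimodal nucleosomal compartments, naked organelle DNA |
| NDR width / boost | 150 bp / 5x | upstream nucleosome-depleted region; no numeric width is reported, 150 bp is a typical promoter NDR |
| +1 / +2 / -1 dyads | +110 / +285 / -130 from the TSS, jitter sd 20 bp | phased promoter arrays; spacing 175 bp |
| nucleosome footprint dip | x0.2 across 147 bp | simplest multiplicative model producing phasing |
| rDNA accessibility | 2x its chromosome | rDNA arrays about twice as accessible as the rest of the nucleomorph |
| transcription rates | 1, rDNA 20x | near-uniform nucleomorph transcription, elevated rDNA |
| Hi-C | cis P(s) ~ s^-1, cis weight 3, telomere boost 5, trans multiplier 3 for mito–nucleomorph and mito–plastid | telomere-to-telomere network; elevated mitochondrion–endosymbiont trans contacts |

Two structural choices deserve emphasis because correctness of downstream
recovery depends on them. First, the per-base accessibility profile is
normalized to mean 1 per chromosome: the NDR/nucleosome/rDNA structure only
redistributes fragments *within* a chromosome, while the compartment
multiplier and copy number set its total yield. Without this, compartments
with different gene densities would leak gene architecture into the
compartment-level enrichment estimates. Second, cis Hi-C pair mass is
proportional to chromosome mass (length x copy), while trans mass is
proportional to the product of masses; per-bin coverage is then proportional
to copy number, and matrix balancing cancels copy numbers, leaving the trans
multipliers — which is why the trans-profile ranking survives all four
normalizations, as it does in real data.

Each library draws from its own RNG stream (derived from the master seed and
the library name), so libraries are individually reproducible. Fragment and
pair counts equal the configured depth exactly; every emitted coordinate is
bounds-checked at write time; a `truth.json` with planted dyads, rates and
multipliers accompanies every simulation.

What the generator does *not* emulate: sequencing errors, PCR duplicates,
chimeric fragments, Tn5 sequence bias, mismatch-tolerant mappability,
restriction-site granularity in Hi-C, or biological copy-number variation.
A green parameter-recovery test therefore establishes that the analysis
stack measures what the generative model plants, at stated depths — not
that it is robust to artefacts the model omits.

## Numerical choices

* Truncated-normal fragment lengths (minimum 20 bp) by rejection sampling.
* Gaussian kernels are truncated at 4 (spectra) or 5 (dyads) bandwidths;
  the dyad truncation is what makes windowed and global calling identical.
* Dyad dedup is greedy by score, ties toward the leftmost position.
* KR uses the symmetric fixed point rather than the inner–outer Newton
  scheme; on the dense, well-conditioned matrices produced at these scales
  it converges in tens of iterations, and non-convergence raises an error
  suggesting sparse-bin masking rather than returning a half-balanced
  matrix.
* Poisson p-values use `ceiling(count) - 1` on weighted counts, which is
  conservative for fractional weights.
* The peak-TSS tie-break (upstream anchor) and the 11-bp dyad footprint are
  plotting conventions made explicit in code.

## Known limitations

The peak caller and dyad caller are intentionally simplified stand-ins; use
them for geography and recovery statistics, not for benchmarking against
MACS2/NucleoATAC outputs. Mappability is exact-match only. The enrichment
table requires a genuine DNA-mass proxy as input; any fragment BED is
accepted and the responsibility for its suitability is the caller's. Dense
contact matrices are fine up to a few thousand bins but are not meant for
mammalian-scale genomes.
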