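---
title: "Window-based copy-number analysis of low-coverage pooled sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Window-based copy-number analysis of low-coverage pooled sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolcnv)
```

## The problem and the model

Tumor genomes accumulate chromosomal gains and losses, and for some
pediatric tumors (retinoblastoma being the classic example, with its
recurrent chromosome 13 deletions) the recurrent losses themselves are
informative. Deep per-sample coverage is not needed to see events that span
megabases: even very low-coverage whole-genome sequencing of *pooled* tumor
DNA — several patients' DNA combined before library preparation — carries a
dosage signal, because the expected number of reads originating from a
genomic interval is proportional to the average copy number of that
interval across the pool.

`poolcnv` implements that read-depth pipeline end to end:

1. **In-silico reference.** Instead of sequencing a matched normal, a
   reference read set is *simulated* by uniform random sampling of the
   reference genome sequence: each read start is uniform over all valid
   start positions genome-wide, so a chromosome's expected read share is
   proportional to its length and expected per-window counts are flat.
   Sampling is with replacement — the simplest model consistent with
   shotgun statistics.

2. **Read filtering.** Reads are filtered for mean base quality, sequence
   complexity (Shannon entropy or a DUST-style triplet score) and mapping
   uniqueness (reads that map exactly once), in that fixed order, with a
   partition report so every input read is accounted for exactly once.

3. **Window counting and the log2 ratio.** Every chromosome is tiled with
   fixed 40-kb windows and reads are counted by their start position. The
   per-window statistic is

   $$\log_2\!\frac{n_\text{sample}}{n_\text{reference}}$$

   which is symmetric in the two directions: +2 and −2 correspond to 4:1
   and 1:4 count relations respectively — both a fold change of 4. A
   hemizygous deletion carried by every pool member halves local dosage
   and sits at −1; carried by 2 of 4 members the pooled dosage is 0.75 and
   the expectation is $\log_2 0.75 \approx -0.415$; a 3-copy gain in all
   members sits at $\log_2 1.5 \approx +0.585$.

4. **Integrity score.** Per chromosome, mapped reads divided by chromosome
   length in kb (reads/kB) — a low-resolution whole-chromosome dosage
   summary — plus an ordinary least-squares fit of read counts against
   chromosome size (in Mbp) whose $r^2$ quantifies the expected linearity.
   In male-derived DNA the single-copy Y chromosome is the standing example
   of a low outlier, which is why the fit takes an exclusion list.

5. **Segmentation and cross-pool intersection.** Windows at or beyond a
   log2 threshold are merged into maximal runs, bridged across short gaps,
   and reported as loss/gain segments annotated with the cytogenetic bands
   they overlap. Segments called in *every* pool are intersected
   coordinate-wise into shared events — the reproducible core of a
   pooled design with biological replicates.

6. **Ideograms.** Each chromosome is rendered as a banded ideogram (Giemsa
   grayscale, pinched centromere, rounded telomeres) with the per-window
   log2 bars alongside, losses left of the axis and gains right, producing
   a panoramic gain/loss map per genome.

## Tunable parameters

| Parameter | Default | Units | Why this default |
|---|---|---|---|
| `window_bp` | 40000 | bp | the window length the pipeline is built around; large enough for stable counts at low coverage, small enough to resolve multi-megabase events |
| `read_length` | 75 | bp | typical short-read length for the instrument class this targets |
| `min_mean_quality` | 20 | Phred | conventional Q20 cut; inclusive boundary |
| `min_entropy_bits` | 1.0 | bits | halfway between a homopolymer (0) and maximally mixed sequence (2) |
| `max_dust_score` | 7 | 0–100 scale | conventional DUST-style cut; homopolymers score 100, random sequence near 0 |
| `min_mapq` | 30 | MAPQ | proxy uniqueness cut when alignment counts are unavailable |
| `loss_threshold` / `gain_threshold` | −0.5 / +0.5 | log2 | half-way to the all-carrier hemizygous (−1) and 3-copy (+0.585 ≈ clipped) expectations |
| `min_consecutive_windows` | 3 | windows | 120 kb minimum event size; suppresses single-window noise |
| `max_gap_windows` | 1 | windows | lets one noisy or undefined window sit inside a real event |
| `pseudocount` | 0 | counts | zero keeps extreme losses extreme; zero-count windows become explicit `NA` gaps instead |
| `k_mad` | 3 | MADs | conventional robust-outlier multiplier |

The filtering thresholds and the calling rule are package choices: the
procedure this package implements reports losses but publishes no numeric
calling rule, so all of these are exposed rather than hard-coded.

Library-size normalization is on by default: the reference count vector is
scaled by the ratio of total sample to total reference reads before the
ratio. When the in-silico reference is drawn with `n_reads` equal to the
sample's filtered read count the scale factor is ≈ 1, but normalization
guards the general case. Note one consequence: a large deletion slightly
depresses the sample total, shifting *all* windows up by
$\log_2(N_\text{ref-scale})$ — about +0.04 log2 units when the deletion
removes 2.5% of the library. Keeping engineered or expected events small
relative to the genome keeps this shift negligible.

## What the synthetic-data generator emulates — and what it does not

`make_toy_genome()` builds random A/C/G/T chromosomes with structurally
valid cytoband tables (an acen pair around a centromere at 40–60% of the
length, 4–8 bands tiling the chromosome exactly).
`simulate_pool_reads()` models a pool of patients as a mixture of
piecewise-constant sampling rates: each member contributes a fixed number
of reads whose start positions are drawn with local rate proportional to
that member's copy number (2 everywhere, `copies_per_cell` inside carried
CNV intervals). Pool defaults mirror a 4-patient design; 5 is the other
size this design used.

The generator deliberately omits sequencing error, GC bias, mappability
structure, insert-size geometry and breakpoint-spanning reads. Passing
tests therefore demonstrate the *statistical* correctness of the pipeline
(dosage in, log2 out; intersection arithmetic; score linearity), not
robustness to platform artifacts in real libraries — on real data,
GC-correlated coverage waves and low-mappability regions will add
structured noise that this model does not produce. The in-silico reference
shares the mappability blindness of the original design: a reference
sampled from the genome sequence has no mappability losses, so regions of
poor mappability in the *sample* can mimic loss; emitting the reference as
FASTQ (`write_reads_fastq()`) and mapping it with the same aligner as the
samples is the supported alternative path.

## Numerical and design choices

- **Coordinates.** 0-based half-open internally for reads and window
  arithmetic; interval containers are `GRanges` (1-based closed, the
  Bioconductor convention) converted at the boundaries; printed
  coordinates are 1-based inclusive. BED stays 0-based on disk.
- **Window assignment** is by read start, not midpoint or overlap
  fraction: the simplest rule, and boundary reads differ between rules, so
  the choice is documented and fixed.
- **The terminal short window is kept**, flagged, and *not*
  length-rescaled — the reference window is equally short, so its ratio is
  unbiased; the flag lets downstream consumers drop it.
- **Undefined windows.** With pseudocount 0, a zero in either count makes
  the window `NA` — rendered as a gap, never ±∞. In segment calling `NA`
  windows neither qualify nor hard-break a run; they count toward the
  bridgeable gap like any other non-qualifying window.
- **Uniqueness.** The original extraction rule ("reads mapping only
  once") is approximated two ways: `NH`-tag/secondary-record inspection
  (`tag_based`, default) and a MAPQ threshold. When neither tags nor
  secondary records make multiplicity decidable, `tag_based` errors
  rather than guessing.
- **DUST score.** Normalized to 0–100 as
  $100\sum_t c_t(c_t-1)/2 \,/\, [m(m-1)/2]$ over overlapping triplets
  ($c_t$ per-triplet counts, $m$ counted triplets, N-containing triplets
  skipped); fewer than two countable triplets scores 0 (pass).
- **Degenerate fits.** Constant counts across chromosomes have no size
  relation: $r^2$ is defined as 0 there rather than 0/0. Fewer than 3
  chromosomes after exclusion is a hard error, as is outlier detection on
  fewer than 4 scores. A zero MAD flags any score off the median and
  nothing when all scores are identical.
- **Intersection** reduces each pool's same-direction segments, then
  takes regions covered by at least `min_pools` pools (default: all) via
  coverage slicing — commutative and associative by construction, verified
  against a per-base membership oracle in the tests.
- **Rendering determinism.** SVG is generated as fixed-format text
  (`%.2f` coordinates), so identical inputs give byte-identical documents;
  every element carries an `id` (`band:chr:name`, `win:chr:index`) so
  tests query structure, not pixels. `gvar`/`stalk` stains use flat
  palette colors rather than hatching.

## Problem sizes used in the test suite

The acceptance-style tests run at deliberately desk-friendly scales,
chosen so the expected signal clears the assertion tolerance with room for
sampling noise: the null pipeline uses a 1.6-Mb five-chromosome genome
with 200k reads per read set (~5000 reads/window, per-window log2 noise
sd ≈ 0.03 against a |log2| < 0.1 assertion); CNV recovery and shared-loss
intersection use an 8-Mb two-chromosome genome with 40k reads (~200
reads/window) and 10-window (400-kb) events, so the mean over an event has
a standard error of ≈ 0.06 against ±0.15 tolerances, and an event removes
only ~1–2.5% of the library so the normalization shift stays within
0.04 log2 units.

## Known limitations

- No GC or mappability correction, no smoothing, and no statistical
  segmentation model (HMM/CBS): calling is thresholded windows, by design.
  For single-sample clinical-grade CNV calling, use a dedicated caller;
  this package reproduces a *pooled screening* analysis.
- Gene counts per segment require a user-supplied annotation
  (`count_genes()`); none is bundled, since counts depend entirely on the
  annotation version.
- Chromosome naming is strict: `"chr1"` and `"1"` do not match, and no
  silent harmonization is attempted (it would corrupt band lookups); the
  loaders fail with a hint when nothing matches.
- The integrity score is a coarse whole-chromosome summary; it carries no
  significance test and is not meant to detect sub-chromosomal events.

## A minimal worked run

```{r example}
toy <- make_toy_genome(c(480000, 400000, 320000, 240000, 160000), seed = 7)
pool <- simulate_pool_reads(
  toy$seqs, pool_size = 4, per_member_reads = 25000, seed = 8,
  cnvs = list(cnv_spec("chr1", 160000, 360000, copies_per_cell = 1,
                       carriers = 1:4)))
ref <- sample_reference_reads(toy$seqs, n_reads = 100000, seed = 9)

grid <- window_grid(toy$genome, 40000)
track <- log2_ratio_track(count_reads_in_windows(pool, grid),
                          count_reads_in_windows(ref, grid))
segs <- annotate_bands(call_segments(track), toy$bands)
segments_table(segs)

integrity_scores(count_reads_in_windows(pool, grid), toy$genome)$fit
```

The deletion engineered at chr1:160–360 kb comes back as a loss segment at
exactly the engineered window boundaries with mean log2 near −1, annotated
with the toy bands it overlaps. (The printed `location` column rounds to
0.1 Mb, so at toy scale read the BED export or the `GRanges` for exact
coordinates.) Note the reads-vs-size fit: this event spans 42% of its toy
chromosome at half dosage, so chr1 drops visibly below the line and $r^2$
falls to ≈ 0.89 — at real-genome scale the same 200-kb event would be
invisible to the chromosome-level score, which is exactly why the pipeline
pairs the coarse integrity diagnostic with the 40-kb window track.
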