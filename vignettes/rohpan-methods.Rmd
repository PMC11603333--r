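---
title: "rohpan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rohpan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohpan)
```

This vignette is the package's own account of what it computes, which
choices were genuinely open, and what a green test suite does and does not
establish. Every number quoted here is either a package default (inspect
`pipeline_params()`) or computed by the examples and tests themselves.

## The problem

Species that passed through severe demographic bottlenecks — the wisent is
the canonical case, restored from a dozen founders — carry megabase-scale
runs of homozygosity (ROH). These have two practical consequences this
package addresses. First, trio binning (assigning an offspring's long
reads to parental haplotypes via parent-specific *k*-mers) degrades inside
ROH: there is simply no parental-specific sequence to bin by, so
haplotype-resolved assemblies develop large gaps and phase errors. Second,
the realized inbreeding of such genomes is poorly summarized by genome-wide
heterozygosity; the quantity of interest is F~ROH~, the fraction of the
autosomal genome inside sufficiently long ROH. Around those two analyses
sit the supporting computations: small-variant post-filtering, a callable
mask, structural-variant (SV) presence/absence analytics from a
cross-species pangenome, and read-depth genotyping of a candidate deletion.

## Phasing diagnostics

Haplotype-tagged read starts (`paternal` / `maternal` / `unassigned`) are
counted in tumbling windows of `phase_window` = 100 kb, each read counted
once in the window containing its primary-alignment start — no length
weighting, because the diagnostic mirrors how binners tag whole reads.

*Open choice: weighting of the genome-wide binnability.* A single
"fraction of reads binned" number can be read-weighted or window-averaged.
The default is read-weighted (total assigned / total reads), because the
statistic describes the read set a binner consumes; `phase_summary(...,
weighting = "window")` exposes the alternative for sensitivity analysis.

*Bias conventions.* The per-window bias ratio is max/min of the two
parental counts. A window where exactly one parental class is absent is
maximally biased: it is reported as `Inf` and *counted* by the biased-window
tally (threshold strictly `> bias_fold` = 5). A window with no parental
reads at all carries no bias information and is excluded (`NA`).

## Variant post-filtering

The chain is fixed: depth masking, then InDel proximity, then quality and
allele count, then bi-allelic autosomal SNP selection. Each record is
removed at most once, attributed to the first failing rule, so the filter
report partitions the input exactly.

- Depth masking sets a *genotype* (not the record) to missing iff its depth
  is `< mean/3` or `> 2.5 × mean` (both strict; `depth_high_factor` at
  exactly 2.5 × mean is kept). The cohort allele count is recomputed from
  the surviving genotypes because masking precedes the AC filter.
- Proximity: SNPs strictly closer than `proximity_bp` = 5 bp to an InDel
  POS, and InDels strictly closer than 5 bp to another InDel, are removed.
  Distances are POS-anchor distances — the deterministic reading; a
  span-aware alternative would need the full allele geometry and is out of
  scope. Removals are judged against the *original* record set, matching
  typical bcftools semantics: an InDel later removed for quality still
  masks its neighbours.
- Quality/AC: strict `qual < 30`, strict `AC < 2`.

*Open choice: AC \< 2 on single-sample callsets.* On a one-sample VCF every
heterozygous singleton has AC = 1, so the literal rule removes the entire
heterozygosity signal. The package implements the literal rule (it is a
cohort filter); single-sample ROH workflows should pass
`pipeline_params(min_allele_count = 1)`, which is what
`scripts/acceptance.R` does for its single-sample branch.

## Heterozygosity, ROH and F~ROH~

A base is *callable* iff its depth lies strictly inside
(`mean/3`, `2.5 × mean`). Heterozygosity in a window is
n~het~/callable — the coverage correction — and windows with less than
`min_callable_fraction` = 60% callable bases are excluded. The genome mean
is the callable-weighted value Σn~het~/Σcallable over retained windows,
not a mean of window ratios.

ROH are called on `roh_window` = 10 kb windows, per chromosome, within
unbroken runs of non-excluded windows (excluded windows terminate runs, so
ROH are never called across unsequenced or pathological-coverage gaps).
Windows at or below the ceiling `roh_het_ceiling_factor` (0.25) × genome
mean are *seeds*. An admissible segment runs from one seed window to a
later seed window, absorbing every intervening heterozygosity peak,
provided the callable-weighted mean heterozygosity of the whole span stays
strictly below the ceiling — the "relaxed peak" rule that tolerates local
assembly or alignment errors inside a true ROH.

*Open choice: how to pick among admissible segments.* The upstream
description fixes only the window size, the relaxation idea and the
0.25 × mean ceiling; it does not say how overlapping admissible segments
are resolved. A natural first answer is greedy best-merge-first
(repeatedly bridge the pair of neighbouring candidate runs with the lowest
merged mean). We implemented it and found it violates a property we regard
as non-negotiable: calling is monotone, i.e. uniformly *lowering*
heterozygosity must never shrink the total called ROH length. The greedy
fails this on roughly one in a thousand random window vectors (its merge
order is path-dependent: an early cheap merge can block a longer merge
later). The shipped caller instead solves the selection exactly: a dynamic
program over seed-window endpoints chooses the disjoint admissible
segments maximizing total covered length, with ties resolved toward
longer, leftmost segments. Monotonicity is then structural — scaling
heterozygosity down only enlarges the admissible set, so the optimum
cannot decrease — and the property test over 1,000 random vectors is part
of the suite. On the worked spike example (49 zero-het windows around one
peak) both rules agree: a 10 × mean peak is absorbed
(10/50 = 0.2 < 0.25 of the mean), a 15 × mean peak splits the run
(15/50 = 0.3 ≥ 0.25).

F~ROH~ sums autosomal ROH of length ≥ `min_roh_length` = 100 kb and divides
by `autosome_length_L` (default 2,682,350,267 bp, the first 29 autosomes
of the wisent reference; always override it to Σ autosome lengths of the
layout in use — the `froh` subcommand does this when given `--layout`).
"Longer than 100 kb" is read inclusively (≥): at 10 kb window granularity
the two readings differ only at exact multiples, and the inclusive reading
keeps a 10-window segment eligible. The long-ROH tally `n_long` is strict
(`> long_roh_length` = 2 Mb), so a segment of exactly 2 Mb does not count.

Degenerate input: a genome mean of zero (no heterozygosity anywhere) makes
the ceiling zero; whole runs of zero-het windows are then returned as ROH,
and any nonzero window in that situation is an error rather than a silent
empty result.

## SV presence/absence analytics

The input is the VCF produced by deconstructing pangenome graph paths
against the cattle backbone, one genotype column per assembly.
Multi-allelic records are split per alternate allele; an assembly is
present iff it carries that allele; missing genotypes count as absent but
are tallied so a pathological deconstruction is visible. SV length is
|len(alt) − len(ref)| with class by sign; alleles shorter than
`min_sv_length` = 50 bp (the conventional minigraph-scale SV floor; the
upstream analysis states none) are dropped. Symbolic alleles carry no
length and are rejected.

Intersections use exact UpSet semantics: each SV is counted once under its
full presence pattern, so Σ pattern counts = number of SVs and a
per-assembly total equals the sum of patterns containing it (both are
asserted as properties).

*Open choice: the pairwise distance.* "Reciprocal of the number of SVs
between each pair" admits two readings: shared SVs (more sharing = closer)
or discordant SVs. Only the shared-count reciprocal yields a sensible
tree — under the generator's tree model the shared count is the cumulative
branch count down to the pair's most recent common ancestor, which is
monotone in clade depth — so d(i,j) = 1/|shared| is the default and
`method = "discordant"` (disagreement fraction) is available for
comparison. Pairs sharing nothing get the sentinel 2 × the largest finite
distance, keeping the matrix finite without inventing a scale.

UPGMA is implemented directly (size-weighted average linkage, merge height
= d/2) with a deterministic tie-break — the lexicographically smallest
pair of cluster labels, a cluster labelled by its sorted leaves — so
outputs are reproducible even on tied integer sharing counts. The test
suite checks merge-sequence equality against `stats::hclust(method =
"average")` on 1,000 random matrices, ultrametricity of every output, and
invariance of topology under label permutation. One internal subtlety:
`ape::as.phylo.hclust` halves `hclust` heights, so the internal `hclust`
object stores full joining distances while the user-facing merge table
reports heights = d/2.

## Deletion genotyping

Per-sample depth over the scan window (the reference case is
`29:17990000-18000000`) is normalized by its mean outside the exclusion
window (`29:17993500-17996000`), making the out-of-event mean exactly 1 by
construction — an identity the tests verify to machine precision, along
with invariance of the call under any positive rescaling of the raw track.
The event region defaults to the exclusion window because the deletion's
exact breakpoints are typically not known more precisely; when they are
(e.g. a 1,580 bp event), pass them explicitly.

*Open choice: genotype cutpoints.* The expected normalized event coverage
is 1 / 0.5 / 0 for absent / heterozygous / homozygous deletion; the
upstream analysis classified visually. The package uses the midpoints:
m < `del_hom_max` = 0.25 is homozygous, m ≤ `del_het_max` = 0.75
heterozygous, above that no deletion; both cutpoints sit in
`pipeline_params()`. Samples whose raw out-of-event mean is below
`min_sample_coverage` = 5 are `low_confidence` and excluded from cohort
means. Cohort confidence intervals are the normal approximation
mean ± 1.96 SD/√n; with n = 1 the SD is undefined and the interval is
reported zero-width with `ci_degenerate = TRUE` rather than silently
dropped.

## The synthetic-data generator

The generator is a stated world, not a tuning knob. Its defaults are the
conditions the analyses assume: background heterozygosity 10^-3^/bp (the
bovine genome-wide scale), residual heterozygosity inside ROH at 5% of
background (residual variant calls inside true ROH), mean depth 30 × with
negative-binomial noise (variance μ + 0.1 μ²; short-read depth is
overdispersed, and the deletion genotyper must tolerate that), binnability
0.619 with balanced parental assignment, and SV matrices generated by
placing each branch's SVs in exactly the leaves below it. One master seed
drives fixed-offset sub-streams per generator, so outputs are
byte-deterministic yet uncoupled. `depth_dispersion = 0` is special-cased
to a noise-free constant track (the distributional limit would be Poisson,
but a degenerate generator is the more useful boundary case for tests).

What it deliberately does not emulate: read sequences, alignment and
mapping error, GC-dependent coverage, linkage disequilibrium or
recombination, genotyping error correlated with depth, and SV breakpoint
uncertainty. A green recovery test therefore establishes that the
*statistics* are implemented correctly under the stated noise model — not
that the pipeline is robust to artifacts the generator does not produce.

## Numerical and interface conventions

- All in-memory coordinates are 1-based inclusive (VCF convention); BED is
  converted on write (`[s, e]` → `(s−1, e]`). Region strings follow
  samtools (`chrom:start-end`, inclusive).
- Readers reject malformed input (gaps or duplicates in depth tables,
  unknown read tags, overlapping BED segments) instead of repairing it.
- Windows tile from position 1 with step = size ("sliding" analyses in the
  upstream description are disjoint bins, as the histograms imply); the
  trailing partial window is kept and flagged `partial`, with
  `keep_partial = FALSE` to drop it.
- Depth tables must be dense (`samtools depth -aa` style): the
  normalization and callable arithmetic assume every base is present.

## Known limitations

- The ROH dynamic program is quadratic in the number of seed windows per
  unbroken run. At the test scales (10 kb windows, 100 Mb genomes) this is
  negligible; for a 2.7 Gb genome with very high seed density, expect the
  caller, not the I/O, to dominate runtime.
- `read_variants` materializes the VCF in memory via
  `VariantAnnotation::readVcf`; whole-genome callsets should be processed
  per chromosome.
- The proximity filter is POS-anchor based; a long deletion's span does not
  shadow SNPs beyond 5 bp of its anchor.
- The deletion genotyper assumes a single event per locus specification and
  does not discover breakpoints.
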