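---
title: "Calling termination sites and quantifying read-through with termseqr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling termination sites and quantifying read-through with termseqr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(termseqr)
```

## The analysis in one paragraph

Term-seq records the exact 3′-terminal nucleotide of transcripts as
per-base, strand-specific counts. In an organism with intrinsic,
U-tract-dependent termination, those counts pile up sharply at each
transcription termination site (TTS); when a termination factor is
depleted the pile-ups erode and RNA-seq coverage spills past the
terminator into the intergenic region (IGR) and sometimes into the next
gene. `termseqr` turns these two signals into four result tables: a set
of primary TTS calls with per-replicate evidence, a terminator motif
summary (position frequency matrix and U-tract enrichment), a
TTS-centred metaplot per condition, and a per-TU read-through (TRT)
record with an index, flags and a type I–IV classification.

## Coordinate model

Every interval is 0-based half-open on the forward genomic axis.
"Downstream" always means *in the direction of transcription*: +1 bp on
the plus strand, −1 bp on the minus strand, and the single helper
`downstream_pos()` centralizes that arithmetic. Minus-strand track
values are stored on forward-axis positions (never reversed); sequences
extracted for motif work are reverse-complemented so they always read
in transcription sense. bedGraph files carry no strand, so tracks
travel as paired `.plus.bedgraph` / `.minus.bedgraph` files.

## Primary TTS calling

For each TU the search window is the 200 nt immediately downstream of
the last base of the stop codon (the stop codon itself is excluded;
distances are 1-based, matching the convention "the TTS is located N nt
downstream of the stop codon"). A candidate −1 site must satisfy, in
**every** replicate:

* ratio criterion: `count(−1) / count(+1) > 1.1`, where the +1 site is
  1 nt downstream;
* difference criterion: `count(−1) − count(+1) > 5`.

Among the candidates, the primary TTS maximizes the difference summed
across replicates; at most one primary TTS is reported per TU.

Numerical choices worth knowing:

* A +1 count of zero makes the ratio `+Inf`, which passes the ratio
  criterion. No pseudocount is added anywhere — a pseudocount would
  silently shift the absolute difference threshold.
* Requiring the two per-replicate criteria in *each* replicate is the
  strict reading of replicate consistency; a looser reading (signal
  merely present in both replicates) would admit more sites. The strict
  rule is what the package implements.
* The ratio threshold is strict (`>`), not `≥`.
* Score ties break toward the stop codon (the shortest 3′ UTR is the
  conservative primary isoform), then toward the smaller forward
  coordinate.
* Windows running off a contig are truncated and flagged rather than
  dropped.

## Metaplot and the −2/+2 decrease

The metaplot averages 3′-end counts at transcription-sense positions
−21…−1 and +1…+20 around all primary TTSs (−1 *is* the TTS; there is no
position 0, so the profile has 41 points) and divides by the −21 value,
which is therefore exactly 1. A zero at −21 is an explicit error, since
the profile cannot be normalized. Termination strength is summarized as
`1 − normalized[+2] / normalized[−2]`: efficient termination gives
values above 0.5, read-through gives values near zero or negative
(negative values are allowed and meaningful).

## Terminator motif

`extract_terminator_pfm()` collects sense-strand windows from −30 to
+10 around each called TTS (wide enough to contain the ~23 nt U tract
described for archaeal terminators), excludes windows clipped by contig
edges or containing non-ACGT bases, and returns base counts per
position; every column sums to the number of used sequences. The
U-tract scan (`u_tract_enrichment()`) counts *maximal* runs of ≥ 5, 6,
7 T's in 200 nt windows flanking stop codons. Maximal-run counting —
one count per run regardless of length, rather than overlapping k-mers
— keeps the U5/U6/U7 columns disjoint and interpretable; a 7-T run
counts once for each of n = 5, 6, 7. The stop codon belongs to the
upstream (gene-body) side. Enrichment is tested per run class with a
two-sided exact binomial test of downstream counts against a null
proportion of 0.5 of the pooled count; no overlapping-gene masking is
applied to the downstream windows.

## The TRT index and classification

IGRs are derived from the annotation as the strand-specific region
between a TU's TTS (called where available, the annotated TU 3′ end
otherwise) and the TSS of the next TU *on the same strand*; convergent
neighbours never define an IGR, and overlapping tandem pairs are
skipped and counted. FPKMs are computed per feature as
`fragments / (length/1000) / (total/10^6)`, with fragments estimated as
coverage sums divided by the read length and the total taken over the
whole track. With the per-condition FPKMs of a TU and its IGR,

```
TRT_index = (FPKM_IGR,dep / FPKM_IGR,wt) / (FPKM_TU,dep / FPKM_TU,wt)
```

is exactly the defining ratio of ratios: when any of the three
denominators is zero the record is `NA` with a reason code rather than
pseudocounted, so reported indices are never approximations. The index
cancels any per-condition depth scaling by construction. Flags use
strict cuts: read-through at index > 1, strong read-through at > 2.

Classification walks downstream from the TTS through the
depleted-condition coverage, smoothed with a 50 bp centered moving
average so isolated Poisson dips do not truncate the span, and extends
the span while coverage stays at or above `alpha = 0.2` times the
source TU's mean body coverage. The first TU the span reaches with at
least 25 bp of overlap decides the type: opposite strand → I (antisense
read-through), same strand → II, none reached → III; a non-coding
source TU whose span reaches a downstream TU is type IV. `alpha`,
`min_overlap` and `smooth_bp` are exposed parameters: the operational
span rule is a package design choice, since "classified by location and
direction" admits many formalizations. When a span overlaps several
TUs, the first one reached along the transcription direction decides —
read-through extends *into* the first obstacle.

Expression ranks bin FPKMs (rounded to the nearest integer) at
≤ 42, 43–103, 104–214, 215–573, > 573 — inclusive integer bins that
partition the non-negative axis.

## Assay computations

`fit_half_life()` defaults to a linear regression of percent remaining
against time, reporting the time at which the fitted line crosses 50%
(`(50 − intercept)/slope`) — the method described for blot-quantified
decay series, even though first-order decay is exponential. The
`log_linear` method fits `ln(percent)` and reports `−ln 2 / slope`;
zero percents are excluded with a flag. Both return `NA` with reason
`"non-decaying"` for non-negative slopes. `bulk_half_life()` subtracts
stable-RNA counts before rescaling to 100% at time zero. qPCR
enrichment is `2^(−ΔΔCt)` with `ΔCt = Ct(sample) − adjusted Ct(input)`;
the input adjustment is user-supplied (a helper applies the standard
`Ct − log2(dilution)` correction), since dilution schemes vary.

## What the synthetic generator emulates

`sim_config()` fixes the study conditions the package is tested under;
its defaults are chosen once, on the scale a practitioner would call
realistic for a compact prokaryotic genome, and every draw is a
deterministic function of the master seed (one derived RNG stream per
condition/replicate/track, so adding a replicate never perturbs
existing tracks).

* **Geometry.** 200 TUs of 600–1200 bp with 150–300 bp gaps, strands
  assigned independently at probability 0.5, so tandem and convergent
  neighbours are both common. Each TU ends, in transcription sense,
  with a stop codon, a 3′ UTR of 20–150 nt and a planted 5–8 nt T
  tract whose last base is the true TTS — inside the 200 nt calling
  window by construction.
* **Term-seq tracks.** Per TU, a read budget `lambda` proportional to a
  log-normal abundance (expected 100 reads/TU at the default depth);
  terminated 3′ ends (share `eff`: 0.9 wild type, 0.3 depleted) fall on
  the true TTS and the 1–2 nt upstream with probabilities 0.7/0.2/0.1 —
  termination is positionally imprecise in real data, and this jitter
  is what gives the metaplot its signal just upstream of the TTS.
  Unterminated ends (share `1 − eff`) form a geometric tail downstream
  (p = 0.85). A uniform Poisson background of 0.05 counts/base
  exercises the absolute count threshold of the calling criteria.
* **Coverage tracks.** Poisson per-base counts around a body level over
  the TU and `body × rt × exp(−d/600)` downstream, with read-through
  fractions 0.12 (wt) and 0.40 (dep) and a 1.2-fold body change — a
  configured IGR fold change of 4.0 against a body fold of 1.2,
  mirroring the contrast scale such depletion experiments report. The
  600 bp decay length is deliberately shorter than typical same-strand
  TU spacing so that read-through decays before the next gene body and
  the configured folds remain identifiable from the tracks. The
  un-annotated region before the first TU carries a stable-RNA ballast
  block sized per condition so both conditions have equal expected
  totals: per-million normalization then preserves the configured
  folds, as it does in depth-matched libraries whose signal is
  dominated by a stable rRNA fraction.
* **Null runs** use two independent draws of the wild-type condition.
  Reusing one track for both conditions would give an index of exactly
  1 everywhere; two draws give the intended sampling null (median index
  ≈ 1, about half the TUs above 1).

What the generator does *not* model: fragment-level reads and
sequencing error, transcription kinetics, operon-internal processing
sites, secondary TTSs, or any mechanistic polymerase behaviour — its
tails are simple monotone families, sufficient for recovery testing.
Passing tests on this generator therefore demonstrate correctness of
the computations and robustness to Poisson noise, not performance on
the full complexity of real libraries.

## Problem sizes and determinism

The shipped tests run the full analysis on 200-TU genomes (~250 kb) for
recovery, contrast and determinism checks, 100 TUs for the null, and
small hand-built fixtures for every exact rule; the acceptance script
uses the same sizes. All pipeline stages are deterministic given their
inputs — identical configuration and seed reproduce byte-identical
output files.

## Known limitations

* TTS calling reports only the primary site per TU; secondary sites are
  out of scope.
* Fragment estimation from coverage is a stand-in for a transcript
  quantifier run on alignments; absolute FPKMs are approximate, though
  the TRT index (a ratio of ratios) is insensitive to this.
* The span-based type I–IV rule is an operationalization; events whose
  read-through is weaker than `alpha` times body coverage classify as
  type III even if a faint tail continues further.
* U-tract enrichment does not mask overlapping downstream genes.
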