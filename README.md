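# termseqr

Transcription termination analysis from Term-seq 3′-end count tracks,
for prokaryotic (especially archaeal) transcriptomes.

Term-seq captures the exact 3′ end of every transcript, giving per-base
3′-end counts on each strand. When a termination factor is depleted,
polymerases read through terminators: 3′-end pile-ups at termination
sites flatten, and RNA-seq coverage spills from transcription units
(TUs) into the downstream intergenic regions (IGRs). `termseqr`
implements the complete desk-side analysis of such an experiment:

- **Primary TTS calling.** A position p (the "−1 site") within the
  200 nt downstream of a TU's stop codon is a candidate termination
  site when, in *every* replicate, the read ratio of the −1 site to the
  +1 site (1 nt downstream) exceeds 1.1 **and** the −1 minus +1 count
  difference exceeds 5. The primary TTS maximizes the summed difference
  across replicates; ties go to the site closest to the stop codon.
- **Terminator motif.** Sense-strand windows around called TTSs are
  tabulated into a position frequency matrix and a per-position U (=
  sense-strand T) fraction — the U-rich intrinsic terminator signature.
  A genome-wide scan counts maximal U5/U6/U7 tracts in 200 nt windows
  flanking stop codons and tests downstream enrichment with an exact
  binomial test.
- **Metaplot.** Average 3′-end signal at positions −21…−1, +1…+20
  around all primary TTSs, normalized to the −21 value; the −2/+2
  decrease `1 − normalized[+2]/normalized[−2]` quantifies termination
  (values > 0.5 indicate efficient termination, near 0 read-through).
- **Transcription read-through (TRT) index.** With FPKMs of each TU and
  its downstream same-strand IGR in a wild-type (wt) and a depleted
  (dep) condition,

  ```
  TRT_index = (FPKM_IGR,dep / FPKM_IGR,wt) / (FPKM_TU,dep / FPKM_TU,wt)
  ```

  read-through is declared at index > 1 (strong at > 2), and each event
  is classified by where the depleted-condition coverage span downstream
  of the TTS ends up: an opposite-strand TU (type I, antisense), the
  tandem same-strand TU (type II), only the IGR (type III), or — for a
  non-coding source — the downstream TU (type IV).
- **Assay math.** mRNA half-life regression (linear 50%-crossing or
  log-linear exponential fit), bulk half-life with stable-RNA count
  subtraction, and ChIP-qPCR enrichment folds `2^(−ΔΔCt)`.
- **Synthetic data.** A fully seeded generator produces a genome with
  planted U-tract terminators, TU annotation, replicate Term-seq tracks
  with configurable termination efficiency, and coverage tracks with
  condition-dependent read-through — with a ground-truth table, so every
  stage is testable without external data.

All coordinates are 0-based half-open on the forward genomic axis.
Standard formats are used throughout: FASTA, GFF3/BED6, paired
plus/minus bedGraph, FASTQ (Phred+33).

## Worked example

```r
library(termseqr)

# a 200-TU genome with efficient wild-type termination (eff 0.9) and
# leaky depleted termination (eff 0.3)
cfg <- sim_config(seed = 42, n_tus = 200)
sim <- simulate_genome(cfg)

wt  <- lapply(1:2, function(r) simulate_termseq(sim$genome, sim$tus, sim$truth, "wt",  r, cfg))
dep <- lapply(1:2, function(r) simulate_termseq(sim$genome, sim$tus, sim$truth, "dep", r, cfg))

calls <- call_primary_tts(wt, sim$tus, window = 200, ratio_min = 1.1, diff_min = 5)
nrow(calls)
#> [1] 200
mean(abs(calls$tts_pos - sim$truth$true_tts[match(calls$tu_id, sim$truth$tu_id)]) <= 1)
#> [1] 1

tts_decrease(metaplot(wt[[1]], calls))   # efficient termination: deep drop
#> [1] 0.9285515
```

All 200 planted termination sites are recovered exactly, and the
wild-type metaplot loses ~93% of its signal across the TTS; rerunning
the metaplot on the depleted tracks gives a negative decrease
(read-through). The TRT side:

```r
cov_wt  <- simulate_coverage(sim$genome, sim$tus, sim$truth, "wt",  cfg)
cov_dep <- simulate_coverage(sim$genome, sim$tus, sim$truth, "dep", cfg)
# ... quantify TUs and IGRs, then:
# median TRT index ~3.2, IGR fold ~4.0, body fold ~1.24 (configured: 4.0 / 1.2)
```

`run_termseq_pipeline()` chains every stage from a `run_config()` (or a
YAML file) and writes the TSV/BED result tables plus a JSON run report;
`autoplot()` methods draw the metaplot and the terminator U profile.

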