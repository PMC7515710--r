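#' Sequence windows flanking stop codons
#'
#' For each gene/TU with an annotated stop codon, extracts `flank` nt of
#' sequence on each side in transcription sense: the upstream window
#' ends at the stop codon's last base (the stop codon belongs to the
#' upstream, gene-body side) and the downstream window begins
#' immediately after it. Minus-strand windows are reverse-complemented.
#' Windows are truncated at contig edges and flagged; genes without a
#' stop codon are skipped and counted in attribute `n_skipped`.
#'
#' @param tus TU tibble with `stop_codon_end`.
#' @param genome a `DNAStringSet`.
#' @param flank window length in nt (default 200).
#' @return tibble with `tu_id`, `strand`, `upstream_seq`,
#'   `downstream_seq`, `up_truncated`, `down_truncated`.
#' @export
flank_windows <- function(tus, genome, flank = 200L) {
  lengths <- genome_lengths(genome)
  n_skipped <- 0L
  rows <- list()
  slice <- function(chrom, s, e, strand, len) {
    s2 <- max(s, 0L); e2 <- min(e, len - 1L)
    if (s2 > e2) return(list(seq = "", trunc = TRUE))
    sq <- as.character(Biostrings::subseq(genome[[chrom]], s2 + 1L, e2 + 1L))
    if (strand == "-") {
      sq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sq)))
    }
    list(seq = sq, trunc = s2 != s || e2 != e)
  }
  for (i in seq_len(nrow(tus))) {
    stop <- tus$stop_codon_end[i]
    if (is.na(stop)) {
      n_skipped <- n_skipped + 1L
      next
    }
    chrom <- tus$chrom[i]
    strand <- tus$strand[i]
    len <- lengths[[chrom]]
    if (strand == "+") {
      up <- slice(chrom, stop - flank + 1L, stop, strand, len)
      down <- slice(chrom, stop + 1L, stop + flank, strand, len)
    } else {
      up <- slice(chrom, stop, stop + flank - 1L, strand, len)
      down <- slice(chrom, stop - flank, stop - 1L, strand, len)
    }
    rows[[length(rows) + 1]] <- tibble(
      tu_id = tus$tu_id[i], strand = strand,
      upstream_seq = up$seq, downstream_seq = down$seq,
      up_truncated = up$trunc, down_truncated = down$trunc
    )
  }
  out <- if (length(rows) == 0) {
    tibble(tu_id = character(), strand = character(),
           upstream_seq = character(), downstream_seq = character(),
           up_truncated = logical(), down_truncated = logical())
  } else {
    bind_rows(rows)
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Count maximal T runs of a minimal length
#'
#' Counts maximal runs of consecutive `T` (uridine in the transcript) of
#' length at least `n`. A run is counted once whatever its length, so a
#' 7-T run contributes one count to each of n = 5, 6 and 7 -- it is not
#' decomposed into overlapping k-mers. `N` (or any non-T character)
#' breaks a run.
#'
#' @param seq character vector of A/C/G/T/N sequences.
#' @param n minimal run length (>= 1).
#' @return integer vector of counts, one per input sequence.
#' @export
count_max_u_runs <- function(seq, n) {
  if (n < 1) abort("n must be >= 1")
  vapply(seq, function(s) {
    if (nchar(s) == 0) return(0L)
    r <- rle(strsplit(toupper(s), "")[[1]] == "T")
    sum(r$values & r$lengths >= n)
  }, integer(1), USE.NAMES = FALSE)
}

#' U-tract enrichment downstream versus upstream of stop codons
#'
#' Counts maximal T runs of length >= 5, 6 and 7 (U5/U6/U7) in the
#' `flank` nt windows on each side of every stop codon and tests, per
#' run class, whether runs are enriched on the downstream (intergenic)
#' side with a two-sided exact binomial test of the downstream count
#' against a null proportion of 0.5 of the pooled count.
#'
#' @inheritParams flank_windows
#' @param n_values run-length classes to tabulate.
#' @return tibble with `n`, `up_count`, `down_count`,
#'   `enrichment_ratio` (`down/up`; `NA` when the upstream count is 0),
#'   and `p_value`; attributes `n_genes` and `n_skipped`.
#' @export
u_tract_enrichment <- function(tus, genome, flank = 200L, n_values = c(5L, 6L, 7L)) {
  win <- flank_windows(tus, genome, flank = flank)
  if (nrow(win) == 0) abort("no gene has both flanking windows")
  rows <- lapply(n_values, function(n) {
    up <- sum(count_max_u_runs(win$upstream_seq, n))
    down <- sum(count_max_u_runs(win$downstream_seq, n))
    p <- if (up + down == 0) NA_real_ else {
      binom.test(down, up + down, p = 0.5, alternative = "two.sided")$p.value
    }
    tibble(n = n, up_count = up, down_count = down,
           enrichment_ratio = if (up > 0) down / up else NA_real_,
           p_value = p)
  })
  out <- bind_rows(rows)
  attr(out, "n_genes") <- nrow(win)
  attr(out, "n_skipped") <- attr(win, "n_skipped")
  out
}
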