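# Fixture builders shared across the suite. Everything is generated in
# code; no binary files.

toy_genome <- function(seqs) {
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- names(seqs)
  g
}

# A TU row with the invariants (tss at the strand-appropriate edge)
# filled in automatically.
make_tu <- function(tu_id, chrom, strand, start, end,
                    stop_codon_end = NA_integer_, tts = NA_integer_,
                    is_noncoding = FALSE) {
  tibble::tibble(
    tu_id = tu_id, chrom = chrom, strand = strand,
    start = as.integer(start), end = as.integer(end),
    tss = as.integer(if (strand == "+") start else end - 1L),
    stop_codon_end = as.integer(stop_codon_end),
    tts = as.integer(tts), is_noncoding = is_noncoding
  )
}

# Empty track over the genome with counts poked in at given positions.
make_track <- function(genome, kind = "three_prime_end") {
  termseqr::stranded_track(termseqr::genome_lengths(genome), kind = kind)
}

poke <- function(track, chrom, strand, pos, values) {
  v <- termseqr::track_values(track, chrom, strand)
  v[pos + 1L] <- values
  termseqr:::set_track_values(track, chrom, strand, v)
}

fill_range <- function(track, chrom, strand, start, end, value) {
  v <- termseqr::track_values(track, chrom, strand)
  v[(start + 1L):end] <- value
  termseqr:::set_track_values(track, chrom, strand, v)
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Write a FASTQ records list (id, seq, qual strings) to a temp file.
write_fastq <- function(records, path = tempfile(fileext = ".fastq")) {
  lines <- unlist(lapply(records, function(r) {
    c(paste0("@", r$id), r$seq, "+", r$qual)
  }))
  writeLines(lines, path)
  path
}

# Eight read-through geometries (2 strands x 4 types), each on its own
# chromosome. Returns tus, trt records (is_trt TRUE), the depleted
# coverage track, and the expected labels.
classification_fixture <- function() {
  chroms <- paste0("g", 1:8)
  genome <- toy_genome(stats::setNames(
    replicate(8, paste(rep("A", 6000), collapse = "")), chroms
  ))
  cov <- make_track(genome, kind = "coverage")
  tus <- list()
  expected <- character(0)
  add_case <- function(chrom, src_strand, type) {
    if (src_strand == "+") {
      src <- make_tu(paste0(chrom, "_src"), chrom, "+", 100, 1100,
                     stop_codon_end = 1000, tts = 1099,
                     is_noncoding = (type == "IV"))
      tgt_strand <- if (type %in% c("II", "IV")) "+" else "-"
      tgt <- make_tu(paste0(chrom, "_tgt"), chrom, tgt_strand, 1300, 2300,
                     stop_codon_end = 2200)
      cov <<- fill_range(cov, chrom, "+", 100, 1100, 100)
      span_end <- if (type == "III") 1200 else 1700
      cov <<- fill_range(cov, chrom, "+", 1100, span_end, 50)
    } else {
      src <- make_tu(paste0(chrom, "_src"), chrom, "-", 4900, 5900,
                     stop_codon_end = 5000, tts = 4900,
                     is_noncoding = (type == "IV"))
      tgt_strand <- if (type %in% c("II", "IV")) "-" else "+"
      tgt <- make_tu(paste0(chrom, "_tgt"), chrom, tgt_strand, 3700, 4700,
                     stop_codon_end = 3800)
      cov <<- fill_range(cov, chrom, "-", 4900, 5900, 100)
      span_start <- if (type == "III") 4800 else 4300
      cov <<- fill_range(cov, chrom, "-", span_start, 4900, 50)
    }
    tus[[length(tus) + 1]] <<- src
    tus[[length(tus) + 1]] <<- tgt
    expected <<- c(expected, stats::setNames(type, src$tu_id))
  }
  types <- rep(c("I", "II", "III", "IV"), 2)
  strands <- rep(c("+", "-"), each = 4)
  for (k in 1:8) add_case(chroms[k], strands[k], types[k])
  tus <- dplyr::bind_rows(tus)
  records <- tibble::tibble(
    tu_id = names(expected),
    fpkm_tu_wt = 10, fpkm_tu_dep = 12, fpkm_igr_wt = 1, fpkm_igr_dep = 5
  )
  records <- termseqr::compute_trt_index(records)
  list(genome = genome, tus = tus, cov = cov,
       records = records, expected = expected)
}
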