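test_that("FASTA reading uppercases, validates the alphabet, and rejects duplicates", {
  path <- tempfile(fileext = ".fa")
  writeLines(c(">chr1 some description", "acgtACGT", ">chr2", "NNNNAAAA"), path)
  g <- read_genome_fasta(path)
  expect_named(g, c("chr1", "chr2"))
  expect_equal(as.character(g[["chr1"]]), "ACGTACGT")
  expect_equal(unname(genome_lengths(g)), c(8L, 8L))

  writeLines(c(">chr1", "ACGTX"), path)
  expect_error(read_genome_fasta(path), "line 2")

  writeLines(c(">chr1", "ACGT", ">chr1", "GGGG"), path)
  expect_error(read_genome_fasta(path), "duplicate")

  writeLines(c("ACGT"), path)
  expect_error(read_genome_fasta(path), "line 1")
})

test_that("annotation coordinates follow the 0-based half-open convention", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\ttranscript\t101\t200\t.\t+\t.\tID=tuA;stop_codon_end=181",
    "chr1\tsrc\ttranscript\t301\t400\t.\t-\t.\tID=tuB;stop_codon_end=321"
  ), gff)
  tus <- read_tu_annotation(gff, "gff3")
  expect_equal(tus$start, c(100L, 300L))
  expect_equal(tus$end, c(200L, 400L))
  expect_equal(tus$tss, c(100L, 399L))
  expect_equal(tus$stop_codon_end, c(180L, 320L))

  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200\ttuA\t0\t+", bed)
  tus_bed <- read_tu_annotation(bed, "bed")
  expect_equal(tus_bed$start, 100L)
  expect_equal(tus_bed$end, 200L)
  expect_true(is.na(tus_bed$stop_codon_end))

  writeLines("chr1\t100\t200\ttuA\t0\t.", bed)
  expect_error(read_tu_annotation(bed, "bed"), "strand")
})

test_that("TU GFF3 writing round-trips coordinates and attributes", {
  tus <- dplyr::bind_rows(
    make_tu("tu1", "chr1", "+", 100, 500, stop_codon_end = 450, tts = 480),
    make_tu("tu2", "chr1", "-", 700, 900, stop_codon_end = 750,
            is_noncoding = TRUE)
  )
  path <- tempfile(fileext = ".gff3")
  write_tu_gff3(tus, path)
  back <- read_tu_annotation(path, "gff3")
  expect_equal(back$start, tus$start)
  expect_equal(back$end, tus$end)
  expect_equal(back$stop_codon_end, tus$stop_codon_end)
  expect_equal(back$tts, tus$tts)
  expect_equal(back$is_noncoding, tus$is_noncoding)
})

test_that("bedGraph intervals expand per base, with zeros elsewhere", {
  genome <- toy_genome(c(chr1 = paste(rep("A", 10), collapse = "")))
  plus <- tempfile(fileext = ".bedgraph")
  minus <- tempfile(fileext = ".bedgraph")
  writeLines("chr1\t0\t3\t5", plus)
  writeLines(character(0), minus)
  tr <- read_stranded_bedgraph(plus, minus, genome)
  expect_equal(track_values(tr, "chr1", "+"), c(5, 5, 5, rep(0, 7)))
  expect_equal(track_values(tr, "chr1", "-"), rep(0, 10))

  writeLines("chr1\t5\t12\t1", plus)
  expect_error(read_stranded_bedgraph(plus, minus, genome), "past chromosome end")

  writeLines(c("chr1\t0\t4\t2", "chr1\t2\t6\t3"), plus)
  expect_error(read_stranded_bedgraph(plus, minus, genome), "conflicting")
})

test_that("bedGraph write/read round-trip reproduces per-base values exactly", {
  genome <- toy_genome(c(c1 = random_seq(300), c2 = random_seq(120)))
  tr <- make_track(genome)
  set.seed(11)
  for (chrom in c("c1", "c2")) {
    for (s in c("+", "-")) {
      n <- genome_lengths(genome)[[chrom]]
      v <- rpois(n, 0.5) + ifelse(runif(n) < 0.1, pi, 0)
      tr <- termseqr:::set_track_values(tr, chrom, s, v)
    }
  }
  p <- tempfile(); m <- tempfile()
  write_stranded_bedgraph(tr, p, m)
  back <- read_stranded_bedgraph(p, m, genome)
  for (chrom in c("c1", "c2")) {
    for (s in c("+", "-")) {
      expect_identical(track_values(back, chrom, s), track_values(tr, chrom, s))
    }
  }
})

test_that("IGRs span TTS-to-next-TSS on the same strand only", {
  tus <- dplyr::bind_rows(
    make_tu("A", "chr1", "+", 0, 1000, tts = 999),
    make_tu("C", "chr1", "-", 1050, 1150, tts = 1050), # convergent, ignored
    make_tu("B", "chr1", "+", 1200, 2000, tts = 1999)
  )
  igrs <- derive_igrs(tus)
  expect_equal(nrow(igrs), 1L)
  expect_equal(igrs$start, 1000L)
  expect_equal(igrs$end, 1200L)
  expect_equal(igrs$length, 200L)
  expect_equal(igrs$igr_id, "A|B")

  # overlapping tandem pair produces no IGR but is counted
  tus_ov <- dplyr::bind_rows(
    make_tu("A", "chr1", "+", 0, 1000, tts = 999),
    make_tu("B", "chr1", "+", 900, 2000, tts = 1999)
  )
  igrs_ov <- derive_igrs(tus_ov)
  expect_equal(nrow(igrs_ov), 0L)
  expect_equal(attr(igrs_ov, "n_skipped"), 1L)
})

test_that("IGR derivation is mirrored on the minus strand", {
  tus <- dplyr::bind_rows(
    make_tu("B", "chr1", "-", 100, 900, tts = 100),   # downstream of A
    make_tu("A", "chr1", "-", 1100, 2000, tts = 1100) # transcribes leftward
  )
  igrs <- derive_igrs(tus)
  expect_equal(nrow(igrs), 1L)
  expect_equal(igrs$upstream_tu_id, "A")
  expect_equal(igrs$downstream_tu_id, "B")
  # region strictly between A's TTS (1100) and B's TSS (899)
  expect_equal(igrs$start, 900L)
  expect_equal(igrs$end, 1100L)
  expect_equal(igrs$length, 200L)
})

test_that("n same-strand non-overlapping TUs yield exactly n-1 IGRs with gap lengths", {
  set.seed(3)
  for (strand in c("+", "-")) {
    n <- 6
    starts <- cumsum(sample(300:500, n))
    ends <- starts + sample(100:200, n)
    tus <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
      make_tu(paste0("tu", i), "chr1", strand, starts[i], ends[i],
              tts = if (strand == "+") ends[i] - 1L else starts[i])
    }))
    igrs <- derive_igrs(tus)
    expect_equal(nrow(igrs), n - 1L)
    gaps <- starts[-1] - ends[-n]
    if (strand == "-") gaps <- rev(gaps)
    expect_equal(igrs$length, as.integer(gaps))
  }
})

test_that("read QC applies the three discard rules in order and accounts for every read", {
  q40 <- function(n) paste(rep("I", n), collapse = "") # Q40
  q0 <- function(n) paste(rep("!", n), collapse = "")  # Q0 (<= 5)
  recs <- list(
    list(id = "keep1", seq = random_seq(100), qual = q40(100)),
    list(id = "trunc", seq = random_seq(50), qual = q40(50)),          # 50 <= 150/3
    list(id = "many_n", seq = paste0(strrep("N", 10), random_seq(90)),
         qual = q40(100)),                                            # 10% N
    list(id = "low_q", seq = random_seq(100),
         qual = paste0(q0(50), q40(50))),                             # 50% Q<=5
    list(id = "keep2", seq = random_seq(100),
         qual = paste0(q0(49), q40(51)))                              # 49% Q<=5 kept
  )
  path <- write_fastq(recs)
  out <- tempfile(fileext = ".fastq")
  res <- qc_filter_reads(path, original_length = 150, out_path = out)
  rep <- res$report
  expect_equal(rep$n_input, 5L)
  expect_equal(rep$n_kept, 2L)
  expect_equal(rep$n_discarded_truncated, 1L)
  expect_equal(rep$n_discarded_n_fraction, 1L)
  expect_equal(rep$n_discarded_low_quality, 1L)
  expect_equal(rep$n_input,
               rep$n_kept + rep$n_discarded_truncated +
                 rep$n_discarded_n_fraction + rep$n_discarded_low_quality)
  kept <- Biostrings::readDNAStringSet(out, format = "fastq")
  expect_equal(sub("\\s.*", "", names(kept)), c("keep1", "keep2"))
})
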