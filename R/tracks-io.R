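#' Read a genome FASTA
#'
#' Loads a (multi-)FASTA into a `DNAStringSet`, uppercases all sequence,
#' and enforces a strict A/C/G/T/N alphabet. Ambiguity codes other than
#' `N` are rejected rather than silently remapped, so downstream
#' homopolymer counting never sees IUPAC wildcards.
#'
#' @param path path to a FASTA file.
#' @return a named [Biostrings::DNAStringSet]; `names()` are chromosome
#'   ids (first whitespace-delimited token of each header).
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0) abort(sprintf("empty FASTA file: %s", path))
  if (!startsWith(trimws(lines[nonempty[1]]), ">")) {
    abort(sprintf("malformed FASTA %s: line %d does not start with '>'",
                  path, nonempty[1]))
  }
  seq_lines <- !startsWith(trimws(lines), ">") & nzchar(trimws(lines))
  bad <- which(seq_lines & grepl("[^ACGTNacgtn]", lines))
  if (length(bad) > 0) {
    abort(sprintf(
      "malformed FASTA %s: line %d contains characters outside A/C/G/T/N",
      path, bad[1]
    ))
  }
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate FASTA record id: %s", ids[duplicated(ids)][1]))
  }
  names(seqs) <- ids
  toupper_dss(seqs)
}

toupper_dss <- function(seqs) {
  Biostrings::DNAStringSet(toupper(as.character(seqs)))
}

#' Chromosome lengths of a genome
#'
#' @param genome a named `DNAStringSet` as returned by [read_genome_fasta()].
#' @return named integer vector of lengths in bp.
#' @export
genome_lengths <- function(genome) {
  setNames(Biostrings::width(genome), names(genome))
}

tu_columns <- c(
  "tu_id", "chrom", "strand", "start", "end",
  "tss", "stop_codon_end", "tts", "is_noncoding"
)

#' Validate a transcription-unit table
#'
#' A TU table is a tibble with one row per transcription unit and columns
#' `tu_id`, `chrom`, `strand`, `start`, `end` (0-based half-open forward
#' axis), `tss`, `stop_codon_end`, `tts` (0-based positions; `tts` may be
#' `NA` until called), and `is_noncoding`. The TSS must be the first
#' transcribed base: `start` on `+`, `end - 1` on `-`.
#'
#' @param tus a TU tibble.
#' @return the validated tibble, invisibly usable in a pipe.
#' @export
validate_tus <- function(tus) {
  missing <- setdiff(tu_columns, names(tus))
  if (length(missing) > 0) {
    abort(paste("TU table is missing columns:", paste(missing, collapse = ", ")))
  }
  check_strand(tus$strand)
  if (any(tus$start >= tus$end)) {
    abort(sprintf("TU %s has start >= end", tus$tu_id[which(tus$start >= tus$end)[1]]))
  }
  expected_tss <- ifelse(tus$strand == "+", tus$start, tus$end - 1L)
  if (any(tus$tss != expected_tss)) {
    abort(sprintf("TU %s: tss does not match the strand-appropriate TU edge",
                  tus$tu_id[which(tus$tss != expected_tss)[1]]))
  }
  bad_stop <- !is.na(tus$stop_codon_end) &
    (tus$stop_codon_end < tus$start | tus$stop_codon_end >= tus$end)
  if (any(bad_stop)) {
    abort(sprintf("TU %s: stop_codon_end outside [start, end)",
                  tus$tu_id[which(bad_stop)[1]]))
  }
  invisible(tus)
}

#' Read a TU annotation (GFF3 or BED6)
#'
#' GFF3 coordinates (1-based closed) are converted to the internal
#' 0-based half-open convention; BED6 is already 0-based half-open and
#' passes through. GFF3 attributes `stop_codon_end` and `tts` (1-based
#' genomic positions, as written by [write_tu_gff3()]) and the flag
#' `is_noncoding` are picked up when present; BED carries none of them,
#' so those columns come back `NA`/`FALSE`.
#'
#' @param path annotation file.
#' @param format `"gff3"` or `"bed"`.
#' @return a TU tibble (see [validate_tus()]).
#' @export
read_tu_annotation <- function(path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("annotation file not found: %s", path))
  gr <- rtracklayer::import(path, format = if (format == "gff3") "gff3" else "bed")
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-"))) {
    abort(sprintf(
      "annotation record %d has no strand ('%s'); stranded TUs are required",
      which(!strand %in% c("+", "-"))[1], strand[!strand %in% c("+", "-")][1]
    ))
  }
  mc <- S4Vectors::mcols(gr)
  ids <- if (format == "gff3") {
    mc$ID %||% mc$Name %||% paste0("TU", seq_along(gr))
  } else {
    mc$name %||% paste0("TU", seq_along(gr))
  }
  start0 <- GenomicRanges::start(gr) - 1L # GFF/BED import is 1-based closed
  end0 <- GenomicRanges::end(gr)
  if (any(end0 <= start0)) {
    abort(sprintf("annotation record %s has end <= start", ids[which(end0 <= start0)[1]]))
  }
  num_attr <- function(field) {
    if (is.null(mc[[field]])) return(rep(NA_integer_, length(gr)))
    suppressWarnings(as.integer(as.character(mc[[field]])) - 1L)
  }
  noncoding <- if (is.null(mc$is_noncoding)) {
    rep(FALSE, length(gr))
  } else {
    as.character(mc$is_noncoding) %in% c("1", "TRUE", "true", "yes")
  }
  tus <- tibble(
    tu_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = strand,
    start = start0,
    end = end0,
    tss = ifelse(strand == "+", start0, end0 - 1L),
    stop_codon_end = num_attr("stop_codon_end"),
    tts = num_attr("tts"),
    is_noncoding = noncoding
  )
  validate_tus(tus)
  tus
}

#' Write a TU table as GFF3
#'
#' Inverse of [read_tu_annotation()]: internal 0-based half-open
#' intervals become 1-based closed GFF3 lines with `stop_codon_end`,
#' `tts` and `is_noncoding` carried as attributes (1-based positions).
#'
#' @param tus a TU tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tu_gff3 <- function(tus, path) {
  validate_tus(tus)
  attr_str <- function(i) {
    parts <- c(sprintf("ID=%s", tus$tu_id[i]))
    if (!is.na(tus$stop_codon_end[i])) {
      parts <- c(parts, sprintf("stop_codon_end=%d", tus$stop_codon_end[i] + 1L))
    }
    if (!is.na(tus$tts[i])) {
      parts <- c(parts, sprintf("tts=%d", tus$tts[i] + 1L))
    }
    if (isTRUE(tus$is_noncoding[i])) parts <- c(parts, "is_noncoding=true")
    paste(parts, collapse = ";")
  }
  lines <- vapply(seq_len(nrow(tus)), function(i) {
    paste(tus$chrom[i], "termseqr", "transcript",
          tus$start[i] + 1L, tus$end[i], ".", tus$strand[i], ".",
          attr_str(i), sep = "\t")
  }, character(1))
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Construct an empty stranded per-base track
#'
#' A `stranded_track` stores one non-negative numeric value per genomic
#' base, per chromosome and per strand, on the forward genomic axis
#' (minus-strand values are *not* reversed). `kind` records whether the
#' values are exact 3'-end counts or fragment coverage.
#'
#' @param lengths named integer vector of chromosome lengths (see
#'   [genome_lengths()]).
#' @param kind `"three_prime_end"` or `"coverage"`.
#' @param label free-text condition/replicate label.
#' @return an object of class `stranded_track`.
#' @export
stranded_track <- function(lengths, kind = c("three_prime_end", "coverage"),
                           label = "") {
  kind <- match.arg(kind)
  values <- lapply(lengths, function(n) {
    list("+" = numeric(n), "-" = numeric(n))
  })
  structure(list(values = values, kind = kind, label = label),
            class = "stranded_track")
}

#' @export
print.stranded_track <- function(x, ...) {
  total <- sum(vapply(x$values, function(v) sum(v[["+"]]) + sum(v[["-"]]), numeric(1)))
  cat(sprintf("<stranded_track> kind=%s label='%s' chroms=%d total_signal=%g\n",
              x$kind, x$label, length(x$values), total))
  invisible(x)
}

#' Per-base values of one chromosome/strand of a track
#'
#' @param track a `stranded_track`.
#' @param chrom chromosome id.
#' @param strand `"+"` or `"-"`.
#' @return numeric vector, one value per base (forward axis).
#' @export
track_values <- function(track, chrom, strand) {
  check_strand(strand)
  v <- track$values[[chrom]]
  if (is.null(v)) abort(sprintf("track has no chromosome '%s'", chrom))
  v[[strand]]
}

set_track_values <- function(track, chrom, strand, values) {
  stopifnot(length(values) == length(track$values[[chrom]][[strand]]))
  track$values[[chrom]][[strand]] <- values
  track
}

expand_bedgraph <- function(path, lengths) {
  out <- lapply(lengths, numeric)
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) == 0) return(out)
  chroms <- as.character(GenomicRanges::seqnames(gr))
  unknown <- setdiff(unique(chroms), names(lengths))
  if (length(unknown) > 0) {
    abort(sprintf("%s: bedGraph chromosome '%s' not in genome", path, unknown[1]))
  }
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  score <- S4Vectors::mcols(gr)$score
  over <- end0 > lengths[chroms]
  if (any(over)) {
    i <- which(over)[1]
    abort(sprintf("%s: interval %s:%d-%d extends past chromosome end (%d bp)",
                  path, chroms[i], start0[i], end0[i], lengths[chroms[i]]))
  }
  for (chrom in unique(chroms)) {
    sel <- chroms == chrom
    s <- start0[sel]; e <- end0[sel]; v <- score[sel]
    o <- order(s, e)
    s <- s[o]; e <- e[o]; v <- v[o]
    vec <- numeric(lengths[[chrom]])
    seen <- logical(lengths[[chrom]])
    for (i in seq_along(s)) {
      idx <- (s[i] + 1L):e[i]
      clash <- seen[idx] & vec[idx] != v[i]
      if (any(clash)) {
        abort(sprintf(
          "%s: overlapping intervals with conflicting values at %s:%d",
          path, chrom, idx[which(clash)[1]] - 1L
        ))
      }
      vec[idx] <- v[i]
      seen[idx] <- TRUE
    }
    out[[chrom]] <- vec
  }
  out
}

#' Read a paired plus/minus bedGraph into a stranded track
#'
#' bedGraph carries no strand, so the package convention is a pair of
#' files, one per strand, both on forward-axis coordinates. Uncovered
#' bases become 0; intervals beyond the chromosome end, or overlapping
#' intervals that disagree on the value, are errors.
#'
#' @param plus_path,minus_path bedGraph files for the two strands.
#' @param genome a `DNAStringSet` (or a named length vector) defining
#'   chromosome bounds.
#' @inheritParams stranded_track
#' @return a `stranded_track`.
#' @export
read_stranded_bedgraph <- function(plus_path, minus_path, genome,
                                   kind = c("three_prime_end", "coverage"),
                                   label = "") {
  kind <- match.arg(kind)
  lengths <- if (is.numeric(genome)) genome else genome_lengths(genome)
  track <- stranded_track(lengths, kind = kind, label = label)
  plus <- expand_bedgraph(plus_path, lengths)
  minus <- expand_bedgraph(minus_path, lengths)
  for (chrom in names(lengths)) {
    track$values[[chrom]][["+"]] <- plus[[chrom]]
    track$values[[chrom]][["-"]] <- minus[[chrom]]
  }
  track
}

#' Write a stranded track as a pair of bedGraph files
#'
#' Zero runs are omitted (the reader restores them); nonzero runs are
#' emitted with full double precision so a read/write cycle reproduces
#' per-base values exactly.
#'
#' @param track a `stranded_track`.
#' @param plus_path,minus_path output paths.
#' @return invisibly, a character vector of the two paths.
#' @export
write_stranded_bedgraph <- function(track, plus_path, minus_path) {
  write_one <- function(strand, path) {
    con <- file(path, "w")
    on.exit(close(con))
    for (chrom in names(track$values)) {
      v <- track$values[[chrom]][[strand]]
      r <- rle(v)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths
      keep <- r$values != 0
      if (any(keep)) {
        writeLines(sprintf("%s\t%d\t%d\t%.17g", chrom,
                           starts[keep], ends[keep], r$values[keep]), con)
      }
    }
  }
  write_one("+", plus_path)
  write_one("-", minus_path)
  invisible(c(plus_path, minus_path))
}

#' Derive intergenic regions from annotated or called TTSs
#'
#' An IGR is the strand-specific region between the TTS of a TU and the
#' TSS of the next tandem (same-strand) TU on the same chromosome.
#' Opposite-strand neighbours never define an IGR, and tandem pairs
#' whose gap is < 1 bp (overlapping or abutting TUs) are skipped; the
#' number skipped is attached as attribute `n_skipped`.
#'
#' @param tus a TU tibble with `tts` set for every row used.
#' @return a tibble with `igr_id`, `chrom`, `strand`, `start`, `end`,
#'   `upstream_tu_id`, `downstream_tu_id`, `length`; attribute
#'   `n_skipped` counts degenerate pairs.
#' @export
derive_igrs <- function(tus) {
  validate_tus(tus)
  tus <- filter(tus, !is.na(.data$tts))
  n_skipped <- 0L
  rows <- list()
  for (key in unique(paste(tus$chrom, tus$strand))) {
    grp <- tus[paste(tus$chrom, tus$strand) == key, ]
    # order along transcription direction
    grp <- if (grp$strand[1] == "+") arrange(grp, .data$start) else arrange(grp, -.data$end)
    if (nrow(grp) < 2) next
    for (i in seq_len(nrow(grp) - 1)) {
      up <- grp[i, ]; down <- grp[i + 1, ]
      if (up$strand == "+") {
        s <- up$tts + 1L
        e <- down$tss
      } else {
        s <- down$tss + 1L
        e <- up$tts
      }
      if (e - s < 1L) {
        n_skipped <- n_skipped + 1L
        next
      }
      rows[[length(rows) + 1]] <- tibble(
        igr_id = paste0(up$tu_id, "|", down$tu_id),
        chrom = up$chrom, strand = up$strand,
        start = s, end = e,
        upstream_tu_id = up$tu_id, downstream_tu_id = down$tu_id,
        length = e - s
      )
    }
  }
  out <- if (length(rows) == 0) {
    tibble(igr_id = character(), chrom = character(), strand = character(),
           start = integer(), end = integer(), upstream_tu_id = character(),
           downstream_tu_id = character(), length = integer())
  } else {
    bind_rows(rows)
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write IGRs as BED6
#'
#' @param igrs tibble from [derive_igrs()].
#' @param path output path. The BED name column is
#'   `upstreamTU|downstreamTU`.
#' @return `path`, invisibly.
#' @export
write_igr_bed <- function(igrs, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   igrs$chrom, igrs$start, igrs$end, igrs$igr_id,
                   0L, igrs$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Quality-filter raw reads
#'
#' Applies the three read-level QC rules used for the sequencing
#' libraries, in order: (1) truncated reads whose length is at most one
#' third of the original read length; (2) reads with >= 10% uncalled
#' bases (N); (3) reads with >= 50% of bases at PHRED quality <= 5
#' (Phred+33 encoding assumed). A read is charged to the first rule it
#' violates. FASTQ does not record the original library read length, so
#' it is supplied explicitly (default 150 bp).
#'
#' @param fastq_path input FASTQ (Phred+33).
#' @param original_length original (pre-trimming) read length in bp.
#' @param out_path optional path for the filtered FASTQ; omit to skip
#'   writing.
#' @return a list with `report` (one-row tibble: `n_input`, `n_kept`,
#'   `n_discarded_truncated`, `n_discarded_n_fraction`,
#'   `n_discarded_low_quality`), `keep` (logical vector), and
#'   `out_path`.
#' @export
qc_filter_reads <- function(fastq_path, original_length = 150, out_path = NULL) {
  raw <- Biostrings::readDNAStringSet(fastq_path, format = "fastq",
                                      with.qualities = TRUE)
  quals <- Biostrings::PhredQuality(S4Vectors::mcols(raw)$qualities)
  S4Vectors::mcols(raw) <- NULL
  reads <- Biostrings::QualityScaledDNAStringSet(raw, quals)
  widths <- Biostrings::width(reads)
  qwidths <- Biostrings::width(Biostrings::quality(reads))
  if (any(widths != qwidths)) {
    abort(sprintf("FASTQ record %d: sequence and quality lengths differ",
                  which(widths != qwidths)[1]))
  }
  n_frac <- as.vector(Biostrings::letterFrequency(reads, "N")) / widths
  qual_ints <- as(Biostrings::quality(reads), "IntegerList")
  low_frac <- vapply(qual_ints, function(q) mean(q <= 5), numeric(1))

  truncated <- widths <= original_length / 3
  n_heavy <- !truncated & n_frac >= 0.10
  low_qual <- !truncated & !n_heavy & low_frac >= 0.50
  keep <- !(truncated | n_heavy | low_qual)

  if (!is.null(out_path)) {
    kept <- reads[keep]
    S4Vectors::mcols(kept) <- NULL
    Biostrings::writeQualityScaledXStringSet(kept, out_path)
  }
  report <- tibble(
    n_input = length(reads),
    n_kept = sum(keep),
    n_discarded_truncated = sum(truncated),
    n_discarded_n_fraction = sum(n_heavy),
    n_discarded_low_quality = sum(low_qual)
  )
  list(report = report, keep = keep, out_path = out_path)
}
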