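#' Call primary transcription termination sites from 3'-end tracks
#'
#' Applies four criteria to replicate Term-seq 3'-end count tracks. A
#' position p (the "-1 site", candidate TTS) in the search window -- the
#' `window` nt immediately downstream of each TU's stop codon, in
#' transcription sense -- is a candidate when, in **every** replicate,
#' (ii) the read ratio of the -1 site to the +1 site (1 nt downstream)
#' exceeds `ratio_min` and (iii) the -1 minus +1 read difference exceeds
#' `diff_min`. Among candidates the primary TTS (iv) maximizes the
#' summed -1 minus +1 difference across replicates; ties go to the
#' candidate closest to the stop codon, then to the smallest forward
#' coordinate. A +1 count of zero gives an infinite ratio (passes (ii)):
#' no pseudocount is added, so the absolute threshold (iii) is exactly
#' the configured value.
#'
#' @param end_tracks list of at least two replicate `stranded_track`s of
#'   kind `"three_prime_end"`, all on the same genome.
#' @param tus TU tibble with `stop_codon_end` set (rows with `NA` are
#'   skipped).
#' @param window search-window length in nt downstream of the stop codon
#'   (the stop codon's own bases are excluded; distances are 1-based).
#' @param ratio_min strict lower bound for the -1/+1 ratio, per replicate.
#' @param diff_min strict lower bound for the -1 minus +1 count
#'   difference, per replicate.
#' @return a tibble with one row per called TU: `tu_id`, `chrom`,
#'   `strand`, `tts_pos` (0-based genomic position of the -1 site),
#'   `dist_to_stop` (1-based nt downstream of the stop codon), `score`
#'   (summed difference across replicates), `truncated` (window clipped
#'   at a contig edge), and per-replicate evidence columns
#'   `minus1_rep<k>`, `plus1_rep<k>`, `ratio_rep<k>`, `diff_rep<k>`.
#' @export
call_primary_tts <- function(end_tracks, tus, window = 200L,
                             ratio_min = 1.1, diff_min = 5) {
  if (length(end_tracks) < 2) {
    abort("TTS calling requires at least 2 replicate 3'-end tracks")
  }
  validate_tus(tus)
  n_rep <- length(end_tracks)
  rows <- list()
  for (i in seq_len(nrow(tus))) {
    if (is.na(tus$stop_codon_end[i])) next
    chrom <- tus$chrom[i]
    strand <- tus$strand[i]
    len <- length(track_values(end_tracks[[1]], chrom, strand))
    d <- seq_len(window)
    pos <- downstream_pos(tus$stop_codon_end[i], strand, d)
    in_bounds <- pos >= 0 & pos < len
    truncated <- any(!in_bounds)
    d <- d[in_bounds]
    pos <- pos[in_bounds]
    if (length(pos) == 0) next
    pos1 <- downstream_pos(pos, strand, 1L)
    ok1 <- pos1 >= 0 & pos1 < len

    m1 <- matrix(0, nrow = n_rep, ncol = length(pos))
    p1 <- matrix(0, nrow = n_rep, ncol = length(pos))
    for (r in seq_len(n_rep)) {
      v <- track_values(end_tracks[[r]], chrom, strand)
      m1[r, ] <- v[pos + 1L]
      p1[r, ok1] <- v[pos1[ok1] + 1L]
    }
    ratio <- ifelse(p1 == 0, ifelse(m1 > 0, Inf, NaN), m1 / p1)
    diff <- m1 - p1
    cand <- colSums(ratio > ratio_min & diff > diff_min) == n_rep
    if (!any(cand)) next
    score <- colSums(diff)
    score[!cand] <- -Inf
    best <- which(score == max(score))
    if (length(best) > 1) best <- best[order(d[best], pos[best])][1]

    evid <- as.list(c(m1[, best], p1[, best], ratio[, best], diff[, best]))
    names(evid) <- c(paste0("minus1_rep", seq_len(n_rep)),
                     paste0("plus1_rep", seq_len(n_rep)),
                     paste0("ratio_rep", seq_len(n_rep)),
                     paste0("diff_rep", seq_len(n_rep)))
    rows[[length(rows) + 1]] <- tibble(
      tu_id = tus$tu_id[i], chrom = chrom, strand = strand,
      tts_pos = pos[best], dist_to_stop = d[best],
      score = max(score), truncated = truncated, !!!evid
    )
  }
  if (length(rows) == 0) {
    return(tibble(tu_id = character(), chrom = character(),
                  strand = character(), tts_pos = integer(),
                  dist_to_stop = integer(), score = numeric(),
                  truncated = logical()))
  }
  bind_rows(rows)
}

#' Position frequency matrix of terminator windows
#'
#' Extracts, in transcription sense, the sequence from `upstream` nt
#' before to `downstream` nt after each called TTS (the TTS itself is
#' position -1; there is no position 0) and tabulates base counts per
#' position. Windows clipped by a contig edge, or containing a base
#' outside A/C/G/T, are excluded and counted. The per-position T
#' fraction of the sense strand is the uridine profile of the
#' transcript's 3' end, the signature of the intrinsic terminator.
#'
#' @param tts_calls tibble from [call_primary_tts()] (columns `chrom`,
#'   `strand`, `tts_pos`).
#' @param genome a `DNAStringSet`.
#' @param upstream,downstream window extent in nt on each side of the
#'   TTS; the default (-30..+10) spans the described ~23 nt U tract.
#' @return an object of class `terminator_pfm`: list with `counts`
#'   (4 x n matrix, rows A/C/G/T), `positions` (labels -upstream..-1,
#'   +1..+downstream), `n_sequences`, `n_excluded`, and `t_fraction`.
#' @export
extract_terminator_pfm <- function(tts_calls, genome, upstream = 30L,
                                   downstream = 10L) {
  lengths <- genome_lengths(genome)
  seqs <- character(0)
  n_excluded <- 0L
  for (i in seq_len(nrow(tts_calls))) {
    t <- tts_calls$tts_pos[i]
    chrom <- tts_calls$chrom[i]
    strand <- tts_calls$strand[i]
    len <- lengths[[chrom]]
    if (strand == "+") {
      s <- t - upstream + 1L; e <- t + downstream
    } else {
      s <- t - downstream; e <- t + upstream - 1L
    }
    if (s < 0 || e >= len) {
      n_excluded <- n_excluded + 1L
      next
    }
    sq <- as.character(Biostrings::subseq(genome[[chrom]], s + 1L, e + 1L))
    if (strand == "-") {
      sq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sq)))
    }
    if (grepl("[^ACGT]", sq)) {
      n_excluded <- n_excluded + 1L
      next
    }
    seqs <- c(seqs, sq)
  }
  if (length(seqs) == 0) abort("no usable terminator windows")
  mat <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(seqs))
  counts <- mat[c("A", "C", "G", "T"), , drop = FALSE]
  positions <- c(seq(-upstream, -1L), seq(1L, downstream))
  colnames(counts) <- positions
  structure(list(
    counts = counts, positions = positions,
    n_sequences = length(seqs), n_excluded = n_excluded,
    t_fraction = unname(counts["T", ] / length(seqs))
  ), class = "terminator_pfm")
}

#' @export
print.terminator_pfm <- function(x, ...) {
  cat(sprintf("<terminator_pfm> %d sequences (%d excluded), positions %d..%d\n",
              x$n_sequences, x$n_excluded, min(x$positions), max(x$positions)))
  cat("max T fraction:", round(max(x$t_fraction), 3),
      "at position", x$positions[which.max(x$t_fraction)], "\n")
  invisible(x)
}

metaplot_offsets <- function() {
  r <- c(seq(-21L, -1L), seq(1L, 20L))
  tibble(position = r, offset = ifelse(r < 0, r + 1L, r))
}

#' TTS metaplot: average 3'-end signal around called sites
#'
#' Averages per-base 3'-end counts over all calls at each transcription
#' sense position from -21 to +20 relative to the TTS (-1 is the TTS
#' itself; there is no position 0) and normalizes by the value at -21.
#' Positions falling off a contig for a given call are dropped from that
#' position's average.
#'
#' @param end_track a `stranded_track` of 3'-end counts.
#' @param tts_calls tibble with `chrom`, `strand`, `tts_pos`.
#' @return a tibble of class `metaplot_profile` with `position`
#'   (-21..-1, +1..+20), `mean_raw`, and `normalized` (`mean_raw`
#'   divided by its value at -21, which is therefore exactly 1).
#' @export
metaplot <- function(end_track, tts_calls) {
  if (nrow(tts_calls) == 0) abort("metaplot requires at least one TTS call")
  off <- metaplot_offsets()
  sums <- numeric(nrow(off))
  ns <- integer(nrow(off))
  for (i in seq_len(nrow(tts_calls))) {
    chrom <- tts_calls$chrom[i]
    strand <- tts_calls$strand[i]
    v <- track_values(end_track, chrom, strand)
    pos <- downstream_pos(tts_calls$tts_pos[i], strand, off$offset)
    ok <- pos >= 0 & pos < length(v)
    sums[ok] <- sums[ok] + v[pos[ok] + 1L]
    ns <- ns + ok
  }
  mean_raw <- ifelse(ns > 0, sums / ns, NA_real_)
  anchor <- mean_raw[off$position == -21L]
  if (is.na(anchor) || anchor == 0) {
    abort("cannot normalize metaplot: mean signal at position -21 is zero")
  }
  out <- tibble(position = off$position, mean_raw = mean_raw,
                normalized = mean_raw / anchor)
  class(out) <- c("metaplot_profile", class(out))
  out
}

#' Fractional signal decrease across the TTS
#'
#' The drop in normalized metaplot signal between positions -2 and +2
#' flanking the TTS: `1 - normalized[+2] / normalized[-2]`. Values above
#' 0.5 indicate efficient termination; values near zero (or negative)
#' indicate read-through.
#'
#' @param profile a `metaplot_profile`.
#' @return a single number in (-Inf, 1].
#' @export
tts_decrease <- function(profile) {
  m2 <- profile$normalized[profile$position == -2L]
  p2 <- profile$normalized[profile$position == 2L]
  if (length(m2) != 1 || length(p2) != 1) {
    abort("profile must contain positions -2 and +2")
  }
  if (is.na(m2) || m2 == 0) abort("normalized signal at -2 is zero; decrease undefined")
  1 - p2 / m2
}

#' Write TTS calls as BED6 plus an evidence TSV
#'
#' @param tts_calls tibble from [call_primary_tts()].
#' @param bed_path,tsv_path output paths (either may be `NULL` to skip).
#' @return invisibly, the paths written.
#' @export
write_tts_calls <- function(tts_calls, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                     tts_calls$chrom, tts_calls$tts_pos, tts_calls$tts_pos + 1L,
                     tts_calls$tu_id, round(tts_calls$score), tts_calls$strand)
    writeLines(lines, bed_path)
  }
  if (!is.null(tsv_path)) {
    utils::write.table(tts_calls, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(bed_path, tsv_path))
}

#' Write a PFM as TSV (rows A/C/G/T, columns TTS-relative positions)
#'
#' @param pfm a `terminator_pfm`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pfm_tsv <- function(pfm, path) {
  df <- data.frame(base = rownames(pfm$counts), pfm$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
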