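#' Transcription-sense coordinate arithmetic
#'
#' All interval coordinates in termseqr are 0-based half-open on the
#' forward genomic axis. `downstream_pos()` is the single place where
#' "downstream" is translated into forward-axis arithmetic: an offset of
#' +1 moves one base 3' of `pos` in the direction of transcription
#' (increasing coordinate on `+`, decreasing on `-`); negative offsets
#' move upstream.
#'
#' @param pos integer vector of 0-based genomic positions.
#' @param strand `"+"` or `"-"` (recycled against `pos`).
#' @param offset integer vector of transcription-sense offsets.
#' @return integer vector of genomic positions (may fall outside the
#'   contig; callers clip or flag).
#' @examples
#' downstream_pos(100, "+", 5) # 105
#' downstream_pos(100, "-", 5) # 95
#' @export
downstream_pos <- function(pos, strand, offset) {
  check_strand(strand)
  n <- max(length(pos), length(strand), length(offset))
  pos <- rep_len(pos, n)
  strand <- rep_len(strand, n)
  offset <- rep_len(offset, n)
  ifelse(strand == "+", pos + offset, pos - offset)
}

check_strand <- function(strand, arg = "strand") {
  bad <- !strand %in% c("+", "-")
  if (any(bad)) {
    abort(sprintf(
      "%s must be '+' or '-' (got %s)", arg,
      paste(unique(strand[bad]), collapse = ", ")
    ))
  }
  invisible(strand)
}

# Transcription-sense distance from `from` to `to` (positive = `to` is
# downstream of `from`).
sense_distance <- function(from, to, strand) {
  n <- max(length(from), length(to), length(strand))
  from <- rep_len(from, n)
  to <- rep_len(to, n)
  strand <- rep_len(strand, n)
  ifelse(strand == "+", to - from, from - to)
}
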