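#' Fragments per kilobase per million mapped fragments
#'
#' `fpkm = fragments / (length_nt / 1000) / (total / 1e6)`.
#'
#' @param fragments fragment count(s) mapped to the feature.
#' @param length_nt feature length in nt (>= 1).
#' @param total_mapped_fragments library total of mapped fragments (>= 1).
#' @return numeric FPKM value(s).
#' @export
compute_fpkm <- function(fragments, length_nt, total_mapped_fragments) {
  if (any(length_nt < 1)) abort("length_nt must be >= 1")
  if (any(total_mapped_fragments < 1)) abort("total_mapped_fragments must be >= 1")
  fragments / (length_nt / 1000) / (total_mapped_fragments / 1e6)
}

#' Fragment count of an interval from a coverage track
#'
#' Coverage summed over the interval divided by the read length: the
#' desk-scale stand-in for a transcript quantifier run on aligned reads.
#'
#' @param track a `stranded_track` of kind `"coverage"`.
#' @param chrom,strand,start,end interval (0-based half-open, forward
#'   axis).
#' @param read_length nominal read length in bp.
#' @return estimated fragment count (numeric).
#' @export
fragments_from_coverage <- function(track, chrom, strand, start, end,
                                    read_length) {
  if (read_length < 1) abort("read_length must be >= 1")
  v <- track_values(track, chrom, strand)
  if (start < 0 || end > length(v) || start >= end) {
    abort(sprintf("interval %s:%d-%d outside contig (length %d)",
                  chrom, start, end, length(v)))
  }
  sum(v[(start + 1L):end]) / read_length
}

track_total_fragments <- function(track, read_length) {
  total <- sum(vapply(track$values,
                      function(v) sum(v[["+"]]) + sum(v[["-"]]), numeric(1)))
  total / read_length
}

#' FPKM quantification of TUs and IGRs from a coverage track
#'
#' @param features tibble of features (`tu_id` or `igr_id` as
#'   `feature_id` via `id_col`, plus `chrom`, `strand`, `start`, `end`).
#' @param track a coverage `stranded_track`.
#' @param read_length nominal read length in bp.
#' @param feature_kind `"TU"` or `"IGR"` label for the output.
#' @param condition,replicate labels carried into the output.
#' @param id_col name of the id column in `features`.
#' @return tibble with `feature_id`, `feature_kind`, `length`,
#'   `fragments`, `fpkm`, `condition`, `replicate`.
#' @export
quantify_features <- function(features, track, read_length,
                              feature_kind = c("TU", "IGR"),
                              condition = "", replicate = 1L,
                              id_col = "tu_id") {
  feature_kind <- match.arg(feature_kind)
  total <- max(track_total_fragments(track, read_length), 1)
  frags <- vapply(seq_len(nrow(features)), function(i) {
    fragments_from_coverage(track, features$chrom[i], features$strand[i],
                            features$start[i], features$end[i], read_length)
  }, numeric(1))
  len <- features$end - features$start
  tibble(
    feature_id = features[[id_col]], feature_kind = feature_kind,
    length = len, fragments = frags,
    fpkm = compute_fpkm(frags, len, total),
    condition = condition, replicate = replicate
  )
}

#' Transcription read-through index
#'
#' For each TU paired with its downstream IGR, the TRT index is the
#' ratio of the IGR's depleted/wild-type FPKM fold change to the TU
#' body's fold change:
#' `(fpkm_igr_dep / fpkm_igr_wt) / (fpkm_tu_dep / fpkm_tu_wt)`.
#' A TU shows read-through (`is_trt`) when the index exceeds 1, and
#' strong read-through (`is_strong`) when it exceeds 2 (both strict).
#' When any of the three denominators (`fpkm_igr_wt`, `fpkm_tu_wt`,
#' `fpkm_tu_dep`) is zero the index is `NA` with a `na_reason` -- no
#' pseudocounts, so reported values are exactly the defining formula.
#' Replicate FPKMs are expected to be averaged per condition beforehand.
#'
#' @param trt_input data frame with columns `fpkm_tu_wt`, `fpkm_tu_dep`,
#'   `fpkm_igr_wt`, `fpkm_igr_dep` (plus any id columns, carried
#'   through).
#' @return the input tibble with `trt_index`, `is_trt`, `is_strong`,
#'   `na_reason` appended.
#' @export
compute_trt_index <- function(trt_input) {
  req <- c("fpkm_tu_wt", "fpkm_tu_dep", "fpkm_igr_wt", "fpkm_igr_dep")
  missing <- setdiff(req, names(trt_input))
  if (length(missing) > 0) {
    abort(paste("trt_input is missing columns:", paste(missing, collapse = ", ")))
  }
  out <- as_tibble(trt_input)
  na_reason <- rep(NA_character_, nrow(out))
  na_reason[out$fpkm_igr_wt == 0] <- "fpkm_igr_wt=0"
  na_reason[out$fpkm_tu_wt == 0] <- "fpkm_tu_wt=0"
  na_reason[out$fpkm_tu_dep == 0] <- "fpkm_tu_dep=0"
  idx <- ifelse(is.na(na_reason),
                (out$fpkm_igr_dep / out$fpkm_igr_wt) /
                  (out$fpkm_tu_dep / out$fpkm_tu_wt),
                NA_real_)
  mutate(out,
         trt_index = idx,
         is_trt = !is.na(idx) & idx > 1,
         is_strong = !is.na(idx) & idx > 2,
         na_reason = na_reason)
}

# Centered moving average with partial windows at the vector edges;
# counting-noise dips must not truncate a read-through span.
smooth_coverage <- function(v, w) {
  if (w <= 1) return(v)
  half <- w %/% 2
  cs <- cumsum(c(0, v))
  n <- length(v)
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Maximal contiguous downstream run with (smoothed) coverage >=
# alpha * body mean. Returns the span length in nt (0 when the first
# downstream base is already below threshold).
readthrough_span <- function(cov_values, tts, strand, threshold) {
  len <- length(cov_values)
  span <- 0L
  repeat {
    pos <- downstream_pos(tts, strand, span + 1L)
    if (pos < 0 || pos >= len) break
    if (cov_values[pos + 1L] < threshold) break
    span <- span + 1L
  }
  span
}

#' Classify read-through events into types I-IV
#'
#' For every TRT-positive record, the read-through span is the maximal
#' contiguous run downstream of the source TU's TTS (transcription
#' sense) whose depleted-condition coverage -- smoothed with a centered
#' `smooth_bp` moving average so isolated counting-noise dips do not
#' truncate the span -- stays at or above `alpha` times the source TU's
#' mean body coverage. The span is then classified
#' by the first annotated TU it reaches with at least `min_overlap` bp
#' of overlap: an opposite-strand TU gives type I (antisense
#' read-through), a same-strand TU type II (read-through into the
#' tandem downstream TU), no TU reached gives type III (read-through
#' confined to the IGR); when the source TU is non-coding and its span
#' reaches a downstream TU the event is type IV. Records with `is_trt`
#' `FALSE` are labelled `"none"`; records whose TU has no TTS are `NA`.
#'
#' @param trt_records tibble from [compute_trt_index()] with a `tu_id`
#'   column.
#' @param tus TU tibble with `tts` set (called or annotated).
#' @param igrs IGR tibble from [derive_igrs()] (reserved for reporting;
#'   classification itself needs only the TUs).
#' @param depleted_coverage coverage `stranded_track` of the depleted
#'   condition.
#' @param alpha span threshold as a fraction of mean body coverage.
#' @param min_overlap minimal span/feature overlap in bp.
#' @param smooth_bp width of the centered moving average applied to the
#'   depleted coverage before span detection (1 disables smoothing).
#' @return `trt_records` with `trt_type` (`"I"`, `"II"`, `"III"`,
#'   `"IV"`, `"none"`, or `NA`), `span_length`, and
#'   `target_feature_id` appended.
#' @export
classify_trt <- function(trt_records, tus, igrs, depleted_coverage,
                         alpha = 0.2, min_overlap = 25L, smooth_bp = 50L) {
  validate_tus(tus)
  smoothed <- list() # per chrom/strand cache
  tu_idx <- match(trt_records$tu_id, tus$tu_id)
  if (anyNA(tu_idx)) {
    abort(sprintf("trt_records refer to unknown TU '%s'",
                  trt_records$tu_id[which(is.na(tu_idx))[1]]))
  }
  types <- rep(NA_character_, nrow(trt_records))
  spans <- rep(NA_integer_, nrow(trt_records))
  targets <- rep(NA_character_, nrow(trt_records))
  for (i in seq_len(nrow(trt_records))) {
    tu <- tus[tu_idx[i], ]
    if (isFALSE(trt_records$is_trt[i])) {
      types[i] <- "none"
      next
    }
    if (is.na(tu$tts) || is.na(trt_records$is_trt[i])) next
    v <- track_values(depleted_coverage, tu$chrom, tu$strand)
    key <- paste(tu$chrom, tu$strand)
    if (is.null(smoothed[[key]])) {
      smoothed[[key]] <- smooth_coverage(v, smooth_bp)
    }
    body_mean <- mean(v[(tu$start + 1L):tu$end])
    span <- readthrough_span(smoothed[[key]], tu$tts, tu$strand,
                             alpha * body_mean)
    spans[i] <- span
    if (span > 0) {
      if (tu$strand == "+") {
        span_start <- tu$tts + 1L
        span_end <- tu$tts + span + 1L # half-open
      } else {
        span_start <- tu$tts - span
        span_end <- tu$tts
      }
      others <- tus[tus$chrom == tu$chrom & tus$tu_id != tu$tu_id, ]
      ov <- pmin(others$end, span_end) - pmax(others$start, span_start)
      hit <- which(ov >= min_overlap)
      if (length(hit) > 0) {
        # the first feature reached along the span decides
        entry <- ifelse(tu$strand == "+", others$start[hit], others$end[hit] - 1L)
        dist <- sense_distance(tu$tts, entry, tu$strand)
        first <- hit[which.min(dist)]
        targets[i] <- others$tu_id[first]
        types[i] <- if (isTRUE(tu$is_noncoding)) {
          "IV"
        } else if (others$strand[first] != tu$strand) {
          "I"
        } else {
          "II"
        }
        next
      }
    }
    types[i] <- "III"
  }
  mutate(trt_records, trt_type = types, span_length = spans,
         target_feature_id = targets)
}

#' Expression rank bins
#'
#' Assigns each FPKM to one of five expression ranks after rounding to
#' the nearest integer: rank 1 <= 42, rank 2 43-103, rank 3 104-214,
#' rank 4 215-573, rank 5 > 573 (inclusive integer bins, so every
#' non-negative value receives exactly one rank).
#'
#' @param fpkm_values non-negative numeric vector.
#' @return integer vector of ranks in 1..5.
#' @export
expression_rank_bins <- function(fpkm_values) {
  if (any(fpkm_values < 0, na.rm = TRUE)) abort("fpkm values must be >= 0")
  x <- round(fpkm_values)
  findInterval(x, c(-Inf, 43, 104, 215, 574))
}

#' Summarize read-through across a TU set
#'
#' Computes the counts and percentages of TRT-positive (`index > 1`) and
#' strong (`index > 2`) TUs, median depleted/wild-type FPKM fold changes
#' for IGRs and TU bodies, the median fold change of type II target
#' (downstream) TUs when `expressions` is supplied, and the percentage
#' of each read-through type over both denominators (all TUs, and
#' TRT-positive TUs).
#'
#' @param trt_records tibble from [compute_trt_index()], optionally
#'   after [classify_trt()].
#' @param expressions optional tibble of per-feature FPKMs (columns
#'   `feature_id`, `condition` in `c("wt", "dep")`, `fpkm`; replicates
#'   averaged) used for the type II downstream-TU fold change.
#' @return a one-row tibble (`n_tus`, `n_trt`, `pct_trt`, `n_strong`,
#'   `pct_strong`, `n_na`, `median_igr_fold`, `median_body_fold`,
#'   `median_downstream_fold`, and `pct_type_<T>_of_tus` /
#'   `pct_type_<T>_of_trt` for T in I..IV).
#' @export
summarize_trt <- function(trt_records, expressions = NULL) {
  if (nrow(trt_records) == 0) abort("summarize_trt requires at least one record")
  n_tus <- nrow(trt_records)
  n_trt <- sum(trt_records$is_trt, na.rm = TRUE)
  n_strong <- sum(trt_records$is_strong, na.rm = TRUE)
  igr_fold <- trt_records$fpkm_igr_dep / trt_records$fpkm_igr_wt
  body_fold <- trt_records$fpkm_tu_dep / trt_records$fpkm_tu_wt
  med <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) == 0) NA_real_ else median(x)
  }
  down_fold <- NA_real_
  if (!is.null(expressions) && "trt_type" %in% names(trt_records)) {
    ii <- filter(trt_records, .data$trt_type %in% "II", !is.na(.data$target_feature_id))
    if (nrow(ii) > 0) {
      wide <- tidyr::pivot_wider(
        select(expressions, "feature_id", "condition", "fpkm"),
        names_from = "condition", values_from = "fpkm"
      )
      m <- left_join(ii, wide, by = c(target_feature_id = "feature_id"))
      down_fold <- med(m$dep / m$wt)
    }
  }
  out <- tibble(
    n_tus = n_tus, n_trt = n_trt, pct_trt = 100 * n_trt / n_tus,
    n_strong = n_strong, pct_strong = 100 * n_strong / n_tus,
    n_na = sum(is.na(trt_records$trt_index)),
    median_igr_fold = med(igr_fold),
    median_body_fold = med(body_fold),
    median_downstream_fold = down_fold
  )
  for (type in c("I", "II", "III", "IV")) {
    n_type <- if ("trt_type" %in% names(trt_records)) {
      sum(trt_records$trt_type %in% type)
    } else {
      0L
    }
    out[[paste0("pct_type_", type, "_of_tus")]] <- 100 * n_type / n_tus
    out[[paste0("pct_type_", type, "_of_trt")]] <-
      if (n_trt > 0) 100 * n_type / n_trt else 0
  }
  out
}
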