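#' Fit an RNA decay half-life
#'
#' Fits percent-RNA-remaining against time and reports the half-life.
#' The default `"linear"` method regresses percent on time directly and
#' takes the half-life as the time at which the fitted line crosses 50%
#' (`t_half = (50 - intercept) / slope`). The `"log_linear"` method
#' regresses `ln(percent)` on time, the exponential-decay model, with
#' `t_half = -ln(2) / slope`; zero percents cannot be logged and are
#' excluded with a flag. A non-negative slope (no decay) yields an `NA`
#' half-life with reason `"non-decaying"`.
#'
#' @param decay_data data frame with columns `time` (minutes) and
#'   `percent` (percent RNA remaining, >= 0).
#' @param method `"linear"` or `"log_linear"`.
#' @return an object of class `decay_fit`: list with `method`, `slope`,
#'   `intercept`, `t_half` (minutes or `NA`), `r_squared`, `n_points`,
#'   `n_excluded_zero`, `reason`.
#' @export
fit_half_life <- function(decay_data, method = c("linear", "log_linear")) {
  method <- match.arg(method)
  if (!all(c("time", "percent") %in% names(decay_data))) {
    abort("decay_data needs columns 'time' and 'percent'")
  }
  times <- decay_data$time
  percents <- decay_data$percent
  if (any(percents < 0)) abort("percents must be >= 0")
  n_excluded <- 0L
  if (method == "log_linear") {
    keep <- percents > 0
    n_excluded <- sum(!keep)
    times <- times[keep]
    percents <- percents[keep]
  }
  if (length(unique(times)) < 2) {
    abort("need at least 2 distinct time points")
  }
  y <- if (method == "linear") percents else log(percents)
  fit <- lm(y ~ times)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(stats::residuals(fit)^2) / tss
  t_half <- NA_real_
  reason <- NA_character_
  if (slope >= 0) {
    reason <- "non-decaying"
  } else {
    t_half <- if (method == "linear") (50 - intercept) / slope else -log(2) / slope
    if (t_half <= 0) {
      t_half <- NA_real_
      reason <- "non-positive half-life"
    }
  }
  structure(list(
    method = method, slope = slope, intercept = intercept,
    t_half = t_half, r_squared = r2, n_points = length(times),
    n_excluded_zero = n_excluded, reason = reason
  ), class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> method=%s t_half=%s min (R^2=%.4f, n=%d)\n",
              x$method,
              if (is.na(x$t_half)) paste0("NA [", x$reason, "]")
              else sprintf("%.3g", x$t_half),
              x$r_squared, x$n_points))
  invisible(x)
}

#' Bulk mRNA half-life from isotope count time series
#'
#' Subtracts the stable-RNA counts (measured long after transcription
#' arrest) from the total counts at each time point, rescales so the
#' 0-minute labile signal is 100%, and fits the half-life with
#' [fit_half_life()].
#'
#' @param count_data data frame with columns `time` (minutes, must
#'   include 0) and `total_counts`.
#' @param stable_counts stable-RNA count level to subtract.
#' @inheritParams fit_half_life
#' @return a `decay_fit`; the derived percent series is attached as
#'   attribute `"percent_data"`.
#' @export
bulk_half_life <- function(count_data, stable_counts,
                           method = c("linear", "log_linear")) {
  if (!all(c("time", "total_counts") %in% names(count_data))) {
    abort("count_data needs columns 'time' and 'total_counts'")
  }
  if (!any(count_data$time == 0)) abort("count_data must include time 0")
  mrna <- count_data$total_counts - stable_counts
  m0 <- mrna[count_data$time == 0][1]
  if (m0 <= 0) abort("no labile signal: total counts at time 0 do not exceed stable counts")
  percent_data <- tibble(time = count_data$time,
                         percent = pmax(100 * mrna / m0, 0))
  fit <- fit_half_life(percent_data, method = method)
  attr(fit, "percent_data") <- percent_data
  fit
}

#' qPCR enrichment folds from cycle thresholds
#'
#' Computes, per row, `delta_ct = ct_sample - adj_ct_input` for the
#' experimental and mock immunoprecipitations, their difference
#' `delta_delta_ct`, and the enrichment fold `2^(-delta_delta_ct)`.
#'
#' @param ct_data data frame with columns `ct_sample`,
#'   `adj_ct_input_sample`, `ct_mock`, `adj_ct_input_mock`; any other
#'   columns (e.g. a target id) are carried through.
#' @return the input as a tibble with `delta_ct_experimental`,
#'   `delta_ct_mock`, `delta_delta_ct` and `fold` appended.
#' @export
chip_qpcr_enrichment <- function(ct_data) {
  req <- c("ct_sample", "adj_ct_input_sample", "ct_mock", "adj_ct_input_mock")
  missing <- setdiff(req, names(ct_data))
  if (length(missing) > 0) {
    abort(paste("ct_data is missing columns:", paste(missing, collapse = ", ")))
  }
  if (!all(is.finite(as.matrix(ct_data[req])))) {
    abort("all Ct values must be finite")
  }
  mutate(as_tibble(ct_data),
         delta_ct_experimental = .data$ct_sample - .data$adj_ct_input_sample,
         delta_ct_mock = .data$ct_mock - .data$adj_ct_input_mock,
         delta_delta_ct = .data$delta_ct_experimental - .data$delta_ct_mock,
         fold = 2^(-.data$delta_delta_ct))
}

#' Dilution-adjust an input Ct value
#'
#' Standard correction for a diluted input sample:
#' `adjusted = ct_input - log2(dilution_factor)`.
#'
#' @param ct_input raw input Ct value(s).
#' @param dilution_factor fold dilution of the input relative to the IP
#'   sample (> 0).
#' @return adjusted Ct value(s).
#' @export
adjust_input_ct <- function(ct_input, dilution_factor) {
  if (any(dilution_factor <= 0)) abort("dilution_factor must be > 0")
  ct_input - log2(dilution_factor)
}
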