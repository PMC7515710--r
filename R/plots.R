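#' Plot a TTS metaplot profile
#'
#' Normalized average 3'-end signal against the TTS-relative position;
#' the vertical guide marks the -1/+1 boundary (the termination site).
#'
#' @param object a `metaplot_profile` from [metaplot()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot metaplot_profile
#' @export
autoplot.metaplot_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$normalized)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "position relative to TTS (nt)",
                  y = "normalized mean 3'-end signal") +
    ggplot2::theme_minimal()
}

#' Plot the uridine profile of a terminator PFM
#'
#' Per-position T (uridine) fraction of the sense-strand windows around
#' called TTSs; U-rich intrinsic terminators show a sharp peak in the
#' positions just upstream of -1.
#'
#' @param object a `terminator_pfm` from [extract_terminator_pfm()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot terminator_pfm
#' @export
autoplot.terminator_pfm <- function(object, ...) {
  df <- tibble(position = object$positions, t_fraction = object$t_fraction)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$t_fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "position relative to TTS (nt)", y = "T (U) fraction") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Histogram of TRT index values
#'
#' @param trt_records tibble from [compute_trt_index()].
#' @param bins histogram bin count.
#' @return a ggplot object (log2 index scale; the dashed lines mark the
#'   read-through cut at index 1 and the strong cut at index 2).
#' @export
plot_trt_index <- function(trt_records, bins = 40) {
  df <- filter(trt_records, is.finite(.data$trt_index), .data$trt_index > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = log2(.data$trt_index))) +
    ggplot2::geom_histogram(bins = bins, fill = "grey40") +
    ggplot2::geom_vline(xintercept = c(0, 1), linetype = "dashed",
                        colour = c("firebrick", "darkorange")) +
    ggplot2::labs(x = "log2 TRT index", y = "TUs") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
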