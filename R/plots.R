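#' Plot the null distribution of a resampling test
#'
#' Histogram of the replicate statistics with the observed value marked.
#'
#' @param object A `resampling_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot resampling_result
#' @export
autoplot.resampling_result <- function(object, ...) {
  df <- tibble::tibble(replicate = object$replicates)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$replicate)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70",
                            colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed_statistic,
                        colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(
      x = object$statistic, y = "replicates",
      title = sprintf("Null distribution (empirical p = %.2g)",
                      object$empirical_p)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a pipeline funnel
#'
#' Surviving-candidate counts after each detection stage.
#'
#' @param object An `hgt_pipeline_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hgt_pipeline_result
#' @export
autoplot.hgt_pipeline_result <- function(object, ...) {
  df <- dplyr::mutate(object$funnel,
                      stage = factor(.data$stage, levels = .data$stage))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4,
                       size = 3) +
    ggplot2::labs(x = NULL, y = "surviving candidates",
                  title = "Detection funnel") +
    ggplot2::theme_minimal()
}

#' GC amelioration dot plot
#'
#' Per-type recipient GC against predicted-donor GC; centralization of the
#' recipient values relative to the donors is the amelioration signal.
#'
#' @param recipient_gc Named (or bare) numeric vector of per-type recipient
#'   GC values.
#' @param donor_gc Numeric vector of donor GC values.
#' @return A ggplot.
#' @export
plot_gc_amelioration <- function(recipient_gc, donor_gc) {
  df <- dplyr::bind_rows(
    tibble::tibble(gc = recipient_gc, set = "recipient (transferred genes)"),
    tibble::tibble(gc = donor_gc, set = "predicted donors")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$set, y = .data$gc)) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.3,
                          colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "GC content",
                  title = "GC amelioration") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
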