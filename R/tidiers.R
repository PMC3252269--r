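#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a resampling test result
#'
#' @param x A `resampling_result`.
#' @param ... Unused.
#' @return A one-row tibble with the observed statistic, null mean/SD,
#'   extreme-replicate count, empirical p-value (and exact p-value where
#'   defined).
#' @method tidy resampling_result
#' @export
tidy.resampling_result <- function(x, ...) {
  out <- tibble::tibble(
    statistic = x$statistic,
    observed = x$observed_statistic,
    null_mean = x$null_mean,
    null_sd = x$null_sd,
    n_extreme = x$n_extreme,
    empirical_p = x$empirical_p
  )
  if (!is.null(x$exact_p)) out$exact_p <- x$exact_p
  out
}

#' @rdname tidy.resampling_result
#' @method glance resampling_result
#' @export
glance.resampling_result <- function(x, ...) {
  tibble::tibble(
    n_replicates = x$n_replicates,
    seed = x$seed,
    empirical_p = x$empirical_p
  )
}

#' Tidy a pipeline result into its per-gene call table
#'
#' @param x An `hgt_pipeline_result`.
#' @param ... Unused.
#' @return The complete per-gene call tibble.
#' @method tidy hgt_pipeline_result
#' @export
tidy.hgt_pipeline_result <- function(x, ...) x$calls

#' @rdname tidy.hgt_pipeline_result
#' @method glance hgt_pipeline_result
#' @export
glance.hgt_pipeline_result <- function(x, ...) {
  tibble::tibble(
    n_input = x$funnel$n[x$funnel$stage == "input"],
    n_hgt = sum(x$calls$final_call == "hgt"),
    n_contaminant = sum(x$calls$final_call == "contaminant"),
    n_types = dplyr::n_distinct(stats::na.omit(x$calls$type_group)),
    seed = x$config$seed
  )
}
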