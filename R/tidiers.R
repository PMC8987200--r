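#' Tidy a trajectory into its morphology time series
#'
#' @param x A `cpm_trajectory`.
#' @param ... Unused.
#' @return The per-snapshot morphology report tibble.
#' @method tidy cpm_trajectory
#' @export
tidy.cpm_trajectory <- function(x, ...) x$reports

#' One-row summary of a trajectory
#'
#' Classification label and metrics plus the run's headline numbers.
#'
#' @param x A `cpm_trajectory`.
#' @param thresholds See [classification_thresholds()].
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance cpm_trajectory
#' @export
glance.cpm_trajectory <- function(x, thresholds = classification_thresholds(),
                                  ...) {
  cls <- classify_trajectory(x, thresholds = thresholds)
  fin <- x$reports[nrow(x$reports), ]
  dplyr::bind_cols(
    cls,
    tibble::tibble(n_cells = fin$n_cells, n_basal = fin$n_basal,
                   n_suprabasal = fin$n_suprabasal,
                   n_divisions = nrow(x$events),
                   completed_mcs = x$completed_mcs,
                   steady_mcs = x$steady_mcs,
                   seed = x$params$seed %||% NA_integer_))
}
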