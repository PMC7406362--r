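#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a connected-classifier fit
#'
#' One row per (age, term) with the fitted coefficient on the standardized
#' feature scale.
#'
#' @param x A `cc_model`.
#' @param ... Unused.
#' @return Tibble `age, term, estimate`.
#' @export
tidy.cc_model <- function(x, ...) {
  tibble::tibble(
    age = rep(x$ages, times = ncol(x$coeff)),
    term = rep(colnames(x$coeff), each = nrow(x$coeff)),
    estimate = as.vector(x$coeff)) |>
    dplyr::arrange(.data$age, .data$term)
}

#' @export
tidy.cc_pooled <- function(x, ...) {
  tibble::tibble(term = names(x$coeff), estimate = unname(x$coeff))
}

#' One-line summary of a connected-classifier fit
#'
#' @param x A `cc_model`.
#' @param ... Unused.
#' @return One-row tibble with the penalty, dimensions, objective
#'   decomposition and optimizer diagnostics.
#' @export
glance.cc_model <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, n_ages = length(x$ages),
                 n_features = length(x$feature_names),
                 objective = as.numeric(x$diagnostics$objective),
                 data_term = as.numeric(x$diagnostics$data_term),
                 penalty_term = as.numeric(x$diagnostics$penalty_term),
                 iterations = as.integer(x$diagnostics$iterations),
                 converged = isTRUE(x$diagnostics$converged))
}

#' @export
tidy.experiment_report <- function(x, ...) x$metrics

#' @export
glance.experiment_report <- function(x, ...) {
  x$summary |>
    tidyr::pivot_wider(id_cols = "classifier", names_from = "age",
                       values_from = "mean_accuracy", names_prefix = "t")
}
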