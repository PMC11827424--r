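# broom-style tidiers for correlation and ranking results.

#' @export
tidy.tls_correlations <- function(x, ...) {
  tibble::as_tibble(x)[, c("level", "x_variable", "y_variable", "n_points",
                           "rho", "p_value", "method", "insufficient")]
}

#' @export
tidy.tls_correlation <- tidy.tls_correlations

#' @export
glance.tls_correlations <- function(x, ...) {
  usable <- !x$insufficient
  tibble::tibble(
    n_tests = nrow(x),
    n_insufficient = sum(x$insufficient),
    min_rho = if (any(usable)) min(x$rho[usable]) else NA_real_,
    max_rho = if (any(usable)) max(x$rho[usable]) else NA_real_,
    max_p = if (any(usable)) max(x$p_value[usable]) else NA_real_
  )
}

#' @export
tidy.tls_ranking <- function(x, ...) {
  tibble::as_tibble(x)[, c("rank", "patient_id", "measure", "method")]
}

#' @export
glance.tls_ranking <- function(x, ...) {
  tibble::tibble(
    n_patients = nrow(x),
    method = x$method[1],
    measure_range = diff(range(x$measure, na.rm = TRUE))
  )
}
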