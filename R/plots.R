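# ggplot2 figures for compositions, correlations and rankings.

#' Stacked composition bars per patient
#'
#' Percentage of lymphocytes in each of the eight lymphocyte classes,
#' pooled per patient and ordered by the pooled B-cell Ki-67 fraction
#' (most proliferative first).
#'
#' @param domains qualified domain tibble.
#' @return a ggplot object.
#' @export
plot_domain_composition <- function(domains) {
  ranking <- rank_patients(domains, "pooled")
  pooled <- pool_domains(domains, by = "patient_id") |>
    composition_fractions()
  long <- pooled |>
    tidyr::pivot_longer(dplyr::starts_with("frac_"),
                        names_to = "class", values_to = "fraction") |>
    dplyr::mutate(
      class = factor(sub("^frac_", "", .data$class),
                     levels = setdiff(PHENOTYPES, "undefined")),
      patient_id = factor(.data$patient_id, levels = ranking$patient_id)
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$patient_id,
                                     y = 100 * .data$fraction,
                                     fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of lymphocytes",
                  fill = "phenotype") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Ki-67 cross-subset scatterplot
#'
#' Per-domain Ki-67 fractions of two subsets on log10 axes (display only;
#' correlations are computed on the raw fractions). Zero fractions are drawn
#' at half the smallest positive value rather than dropped.
#'
#' @param domains filtered domain tibble.
#' @param x_subset,y_subset subsets to plot.
#' @return a ggplot object.
#' @export
plot_ki67_scatter <- function(domains, x_subset = "CD4Tconv",
                              y_subset = "B") {
  fr <- ki67_fractions(domains)
  x <- fr[[paste0("ki67_frac_", x_subset)]]
  y <- fr[[paste0("ki67_frac_", y_subset)]]
  half_min <- function(v) {
    pos <- v[v > 0 & is.finite(v)]
    off <- if (length(pos)) min(pos) / 2 else 1e-3
    ifelse(is.finite(v) & v == 0, off, v)
  }
  df <- tibble::tibble(x = half_min(x), y = half_min(y))
  df <- df[is.finite(df$x) & is.finite(df$y), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = paste0(x_subset, " Ki-67+ fraction"),
                  y = paste0(y_subset, " Ki-67+ fraction")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.tls_correlations <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$pair <- paste(df$x_variable, "vs", df$y_variable)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rho, y = .data$pair)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~level) +
    ggplot2::xlim(-1, 1) +
    ggplot2::labs(x = "Spearman rho", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.tls_ranking <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$patient_id <- factor(df$patient_id,
                          levels = df$patient_id[order(df$rank)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$patient_id,
                                   y = 100 * .data$measure)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "B-cell Ki-67+ %",
                  title = paste("ranking:", df$method[1])) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' TLS count and area fraction per section
#'
#' @param summaries output of [summarize_sections()].
#' @return a ggplot object.
#' @export
plot_section_summary <- function(summaries) {
  long <- summaries |>
    dplyr::transmute(
      .data$section_id,
      `TLS domain count` = as.numeric(.data$n_domains),
      `TLS area fraction (%)` = 100 * .data$tls_area_fraction
    ) |>
    tidyr::pivot_longer(-"section_id")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$section_id,
                                     y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~name, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
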