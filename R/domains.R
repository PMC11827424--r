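# Composition of aggregates and qualification as TLS domains.

#' Compose aggregates: count every cell inside each boundary
#'
#' For each polygonized cluster, counts all cells of that section —
#' lymphocyte or undefined, clustered or not — whose centroid falls inside or
#' on the cluster boundary, tabulated over the nine phenotype classes.
#'
#' @param clusters output of [polygonize_clusters()].
#' @param cells phenotyped cell tibble for the same sections.
#' @return `clusters` with the nine count columns, `n_total` and `n_lymph`
#'   appended (all zero for degenerate boundaries).
#' @export
compose_domains <- function(clusters, cells) {
  if (nrow(clusters) == 0) {
    return(dplyr::bind_cols(clusters, phenotype_counts(factor(
      character(), levels = PHENOTYPES
    ))[0, ]))
  }
  idx_by_sec <- split(seq_len(nrow(cells)), cells$section_id)
  comp <- purrr::map2_dfr(
    clusters$section_id, clusters$shape,
    function(sec, shp) {
      idx <- idx_by_sec[[sec]]
      bb <- shape_bbox(shp)
      cand <- idx[cells$x[idx] >= bb[1] & cells$x[idx] <= bb[3] &
                    cells$y[idx] >= bb[2] & cells$y[idx] <= bb[4]]
      inside <- points_in_shape(shp, cells$x[cand], cells$y[cand])
      phenotype_counts(cells$phenotype[cand][inside])
    }
  )
  out <- dplyr::bind_cols(clusters, comp)
  if ("patient_id" %in% names(cells) && !"patient_id" %in% names(out)) {
    out <- dplyr::left_join(
      out, dplyr::distinct(cells[, c("section_id", "patient_id")]),
      by = "section_id"
    ) |>
      dplyr::relocate("patient_id", .after = "section_id")
  }
  out
}

#' Qualify aggregates as TLS domains
#'
#' Applies the inclusion criteria: an aggregate is a TLS domain when it holds
#' at least `min_cells` cells in total and more than `min_lymph_frac` of them
#' (strictly) are lymphocytes (B- and/or T-cells). Rejected aggregates carry
#' a machine-readable reason.
#'
#' @param domains output of [compose_domains()].
#' @param min_cells minimum total cells (default 250).
#' @param min_lymph_frac strict lower bound on the lymphocyte fraction
#'   (default 0.5).
#' @return `domains` with `qualified`, `rejection_reason` and `domain_id`
#'   columns.
#' @export
qualify_domains <- function(domains, min_cells = 250, min_lymph_frac = 0.5) {
  stopifnot(min_cells > 0, min_lymph_frac >= 0, min_lymph_frac < 1)
  size_ok <- domains$n_total >= min_cells
  frac_ok <- domains$n_total > 0 &
    domains$n_lymph / pmax(domains$n_total, 1) > min_lymph_frac
  reason <- dplyr::case_when(
    !size_ok & !frac_ok ~ "too_few_cells;low_lymphocyte_fraction",
    !size_ok ~ "too_few_cells",
    !frac_ok ~ "low_lymphocyte_fraction",
    TRUE ~ NA_character_
  )
  domains$qualified <- size_ok & frac_ok
  domains$rejection_reason <- reason
  domains$domain_id <- sprintf("%s_d%03d", domains$section_id,
                               domains$cluster_id)
  domains
}
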