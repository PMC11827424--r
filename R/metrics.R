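# Per-domain and whole-section metrics: Ki-67 fractions, composition
# fractions, pooling, areas and section summaries.

#' Per-subset Ki-67 fraction
#'
#' Fraction of a lymphocyte subset's cells that are Ki-67+, computed from
#' composition counts. Returns NA (missing sentinel, never an error) where
#' the subset is absent.
#'
#' @param composition tibble with the nine count columns.
#' @param subset one of "B", "CD8T", "CD4Tconv", "CD4Treg".
#' @return numeric vector of fractions in \[0, 1\] (NA where denominator 0).
#' @export
ki67_fraction <- function(composition, subset) {
  subset <- match.arg(subset, SUBSETS)
  pos <- composition[[paste0("n_", subset, "_ki67pos")]]
  tot <- pos + composition[[paste0("n_", subset, "_ki67neg")]]
  ifelse(tot > 0, pos / tot, NA_real_)
}

#' Append per-subset Ki-67 fraction columns
#'
#' @param composition tibble with the nine count columns.
#' @return the tibble with `ki67_frac_B`, `ki67_frac_CD8T`,
#'   `ki67_frac_CD4Tconv`, `ki67_frac_CD4Treg` appended.
#' @export
ki67_fractions <- function(composition) {
  for (s in SUBSETS) {
    composition[[paste0("ki67_frac_", s)]] <- ki67_fraction(composition, s)
  }
  composition
}

#' Composition fractions over the eight lymphocyte classes
#'
#' Each class count divided by `n_lymph`; the undefined class is excluded
#' from the denominator, so the eight fractions sum to 1. All fractions NA
#' when a composition has no lymphocytes.
#'
#' @param composition tibble with the nine count columns and `n_lymph`.
#' @return the tibble with `frac_<class>` columns appended.
#' @export
composition_fractions <- function(composition) {
  lymph_classes <- setdiff(PHENOTYPES, "undefined")
  for (cl in lymph_classes) {
    composition[[paste0("frac_", cl)]] <- ifelse(
      composition$n_lymph > 0,
      composition[[paste0("n_", cl)]] / composition$n_lymph,
      NA_real_
    )
  }
  composition
}

#' Pool domain compositions
#'
#' Element-wise integer sum of the nine phenotype counts over qualified
#' domains, grouped by the given identifier columns. A pooled Ki-67 fraction
#' therefore equals the count-weighted mean of the per-domain fractions.
#'
#' @param domains composed (and usually qualified) domain tibble.
#' @param by grouping columns (default section).
#' @return tibble with one row per group and summed counts.
#' @export
pool_domains <- function(domains, by = "section_id") {
  if ("qualified" %in% names(domains)) {
    domains <- dplyr::filter(domains, .data$qualified)
  }
  domains |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n_domains = dplyr::n(),
      dplyr::across(dplyr::all_of(c(count_cols(), "n_total", "n_lymph")),
                    sum),
      .groups = "drop"
    )
}

# tissue area estimate from grid occupancy: a tile is tissue when it holds
# at least one cell
tissue_area_from_cells <- function(x, y, tile_um = 50) {
  if (length(x) == 0) return(NA_real_)
  tiles <- unique(cbind(floor(x / tile_um), floor(y / tile_um)))
  nrow(tiles) * tile_um^2
}

# area of polygons clipped to a tissue mask by grid sampling
clipped_polygon_area <- function(polys, tissue_polys = NULL, grid_um = 10) {
  if (length(polys) == 0) return(0)
  total <- 0
  for (poly in polys) {
    if (is.null(tissue_polys)) {
      total <- total + polygon_area(poly)
      next
    }
    bb <- apply(poly$outer, 2, range)
    gx <- seq(bb[1, 1] + grid_um / 2, bb[2, 1], by = grid_um)
    gy <- seq(bb[1, 2] + grid_um / 2, bb[2, 2], by = grid_um)
    if (length(gx) == 0 || length(gy) == 0) next
    pts <- expand.grid(x = gx, y = gy)
    inside <- points_in_polygon(poly, pts$x, pts$y)
    in_tissue <- rep(FALSE, nrow(pts))
    for (tp in tissue_polys) {
      in_tissue <- in_tissue | points_in_polygon(tp, pts$x, pts$y)
    }
    total <- total + sum(inside & in_tissue) * grid_um^2
  }
  total
}

#' Per-section areas
#'
#' Total TLS area is the union of qualified domain boundaries (overlaps not
#' double-counted), clipped to tissue extent when tissue polygons are
#' supplied. Tissue area comes from supplied polygons, or failing that from
#' 50 µm grid occupancy of the cell point pattern. Tumour area is the union
#' of tumour polygons clipped to tissue.
#'
#' @param domains qualified domain tibble (with `shape` list-column).
#' @param cells cell tibble (used for the occupancy estimate).
#' @param tissue_regions,tumour_regions optional polygon lists from
#'   [read_regions()].
#' @param tile_um occupancy tile size (µm).
#' @return tibble: `section_id`, `total_tls_area`, `tissue_area`,
#'   `tumour_area`, `tls_area_fraction`, `tumour_area_fraction`.
#' @export
section_areas <- function(domains, cells, tissue_regions = NULL,
                          tumour_regions = NULL, tile_um = 50) {
  secs <- unique(cells$section_id)
  purrr::map_dfr(secs, function(sec) {
    dom <- domains[domains$section_id == sec & domains$qualified, ]
    tls_area <- union_area(dom$shape)
    tissue_area <- if (!is.null(tissue_regions)) {
      sum(vapply(tissue_regions, polygon_area, numeric(1)))
    } else {
      sel <- cells$section_id == sec
      tissue_area_from_cells(cells$x[sel], cells$y[sel], tile_um)
    }
    tumour_area <- if (!is.null(tumour_regions)) {
      clipped_polygon_area(tumour_regions, tissue_regions)
    } else {
      NA_real_
    }
    tls_area <- min(tls_area, tissue_area, na.rm = TRUE)
    tibble::tibble(
      section_id = sec,
      total_tls_area = tls_area,
      tissue_area = tissue_area,
      tumour_area = tumour_area,
      tls_area_fraction = ifelse(is.na(tissue_area), NA_real_,
                                 tls_area / tissue_area),
      tumour_area_fraction = tumour_area / tissue_area
    )
  })
}

#' Summarize sections
#'
#' Rolls qualified domains up to one row per section: domain count, areas
#' and fractions, pooled composition counts, and the unweighted mean over
#' domains of each subset's per-domain Ki-67 fraction (each domain one
#' vote).
#'
#' @inheritParams section_areas
#' @return tibble with one row per section.
#' @export
summarize_sections <- function(domains, cells, tissue_regions = NULL,
                               tumour_regions = NULL, tile_um = 50) {
  areas <- section_areas(domains, cells, tissue_regions, tumour_regions,
                         tile_um)
  qual <- domains[domains$qualified, , drop = FALSE]
  pooled <- pool_domains(qual, by = "section_id")
  per_dom <- ki67_fractions(qual) |>
    dplyr::group_by(.data$section_id) |>
    dplyr::summarise(
      dplyr::across(dplyr::starts_with("ki67_frac_"),
                    ~ mean(.x, na.rm = TRUE),
                    .names = "mean_per_domain_{.col}"),
      .groups = "drop"
    )
  pat <- dplyr::distinct(cells[, c("section_id", "patient_id")])
  out <- areas |>
    dplyr::left_join(pat, by = "section_id") |>
    dplyr::left_join(pooled, by = "section_id") |>
    dplyr::left_join(per_dom, by = "section_id")
  out$n_domains[is.na(out$n_domains)] <- 0L
  for (cc in c(count_cols(), "n_total", "n_lymph")) {
    out[[cc]][is.na(out[[cc]])] <- 0L
  }
  out$total_tls_area[out$n_domains == 0] <- 0
  out$tls_area_fraction[out$n_domains == 0 & !is.na(out$tissue_area)] <- 0
  dplyr::relocate(out, "section_id", "patient_id", "n_domains")
}
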