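# Density-based detection of lymphoid aggregates over lymphocyte centroids,
# strand-aware merging, and alpha-shape polygonization.

#' Parameters for aggregate detection and merging
#'
#' Defaults reflect lymphocyte packing inside follicles (about 0.01
#' cells/µm²): a core cell has at least `min_neighbours` lymphocytes
#' (itself included) within `neighbour_radius_um`; aggregates whose
#' connecting strand of lymphocytes has consecutive gaps at most
#' `strand_link_radius_um` and at least `strand_min_path_cells` cells are
#' treated as one aggregate; `hull_alpha_um` controls how tightly the domain
#' boundary follows concavities.
#'
#' @param neighbour_radius_um core-neighbourhood radius (µm).
#' @param min_neighbours lymphocytes (self included) required in the
#'   neighbourhood for a core cell.
#' @param strand_link_radius_um maximum consecutive gap along a linking
#'   strand (µm); must be >= `neighbour_radius_um`.
#' @param strand_min_path_cells minimum cells in a linking chain.
#' @param hull_alpha_um alpha-shape circumradius threshold (µm).
#' @return list of class `tls_clustering_params`.
#' @export
clustering_params <- function(neighbour_radius_um = 30,
                              min_neighbours = 10,
                              strand_link_radius_um = 40,
                              strand_min_path_cells = 5,
                              hull_alpha_um = 50) {
  p <- list(
    neighbour_radius_um = neighbour_radius_um,
    min_neighbours = min_neighbours,
    strand_link_radius_um = strand_link_radius_um,
    strand_min_path_cells = strand_min_path_cells,
    hull_alpha_um = hull_alpha_um
  )
  stopifnot(
    all(vapply(p, function(v) is.numeric(v) && v > 0, logical(1))),
    strand_link_radius_um >= neighbour_radius_um
  )
  class(p) <- "tls_clustering_params"
  p
}

# density clustering of one section's lymphocytes; returns integer cluster
# ids (NA = noise) aligned with the input rows, deterministic in cell order
dbscan_section <- function(x, y, cell_id, params) {
  n <- length(x)
  lab <- rep(NA_integer_, n)
  if (n == 0) return(lab)
  ord <- order(cell_id)
  x <- x[ord]; y <- y[ord]
  pr <- cpp_radius_pairs(x, y, params$neighbour_radius_um)
  deg <- tabulate(c(pr$i, pr$j), nbins = n) + 1L # self included
  core <- deg >= params$min_neighbours
  lab_ord <- rep(NA_integer_, n)
  if (any(core)) {
    cc <- pr$i[core[pr$i] & core[pr$j]]
    dd <- pr$j[core[pr$i] & core[pr$j]]
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(cc), to = as.character(dd)),
      directed = FALSE,
      vertices = data.frame(name = as.character(which(core)))
    )
    comp <- igraph::components(g)$membership
    lab_ord[as.integer(names(comp))] <- as.integer(comp)
    # border cells join the cluster of their lowest-cell_id core neighbour
    bi <- c(pr$i, pr$j)
    bj <- c(pr$j, pr$i)
    sel <- !core[bi] & core[bj]
    if (any(sel)) {
      border <- bi[sel]
      core_nb <- bj[sel]
      o <- order(border, core_nb) # core_nb ascending = ascending cell_id
      border <- border[o]; core_nb <- core_nb[o]
      first <- !duplicated(border)
      lab_ord[border[first]] <- lab_ord[core_nb[first]]
    }
    # renumber clusters by their smallest member cell_id
    present <- !is.na(lab_ord)
    if (any(present)) {
      firsts <- tapply(seq_len(n)[present], lab_ord[present], min)
      remap <- integer(max(lab_ord, na.rm = TRUE))
      remap[as.integer(names(firsts))] <- as.integer(rank(firsts))
      lab_ord[present] <- remap[lab_ord[present]]
    }
  }
  lab[ord] <- lab_ord
  lab
}

#' Detect lymphoid aggregates
#'
#' Density-based clustering of lymphocytes (cells whose `subset` is one of
#' B, CD8T, CD4Tconv, CD4Treg): a core cell has at least `min_neighbours`
#' lymphocytes (itself included) within `neighbour_radius_um`; clusters are
#' the connected components of core cells at that radius, plus border cells
#' (non-core lymphocytes within the radius of a core cell, assigned to the
#' cluster of their lowest-`cell_id` core neighbour). All other cells are
#' noise. Result is independent of row order.
#'
#' @param cells phenotyped cell tibble (from [classify_cells()]).
#' @param params [clustering_params()].
#' @return the input tibble with an integer `cluster_id` column (NA for
#'   noise and non-lymphocytes), clusters numbered per section.
#' @export
detect_aggregates <- function(cells, params = clustering_params()) {
  if (!"subset" %in% names(cells)) {
    stop("cells must be phenotyped first (see classify_cells())")
  }
  cells$cluster_id <- NA_integer_
  lymph_idx <- which(is_lymphocyte(cells$subset))
  by_sec <- split(lymph_idx, cells$section_id[lymph_idx])
  for (sec in names(by_sec)) {
    sel <- by_sec[[sec]]
    if (length(sel) == 0) next
    cells$cluster_id[sel] <- dbscan_section(
      cells$x[sel], cells$y[sel], cells$cell_id[sel], params
    )
  }
  cells
}

#' Merge strand-connected aggregates
#'
#' Two aggregates are considered cross-sections of the same structure when a
#' chain of lymphocytes (cluster members or noise) links them with
#' consecutive gaps at most `strand_link_radius_um` and the linking connected
#' set holds at least `strand_min_path_cells` cells; merging is transitive.
#' Merged clusters keep exactly the union of their member cells (bridge
#' cells remain noise), so the total clustered-cell count is conserved.
#'
#' @param cells output of [detect_aggregates()].
#' @param params [clustering_params()].
#' @return the tibble with `cluster_id` rewritten to merged ids.
#' @export
merge_connected <- function(cells, params = clustering_params()) {
  if (!"cluster_id" %in% names(cells)) {
    stop("run detect_aggregates() first")
  }
  lymph_idx <- which(is_lymphocyte(cells$subset))
  by_sec <- split(lymph_idx, cells$section_id[lymph_idx])
  for (sec in names(by_sec)) {
    sel <- by_sec[[sec]]
    if (length(sel) == 0) next
    lab <- cells$cluster_id[sel]
    if (length(unique(stats::na.omit(lab))) < 2) next
    ord <- order(cells$cell_id[sel])
    x <- cells$x[sel][ord]; y <- cells$y[sel][ord]
    lab_ord <- lab[ord]
    pr <- cpp_radius_pairs(x, y, params$strand_link_radius_um)
    g <- igraph::graph_from_data_frame(
      data.frame(from = pr$i, to = pr$j), directed = FALSE,
      vertices = data.frame(name = seq_along(x))
    )
    cmp <- igraph::components(g)
    comp <- cmp$membership[as.character(seq_along(x))]
    big <- cmp$csize >= params$strand_min_path_cells
    # group cluster ids that share a sufficiently large linking component
    all_clusters <- sort(unique(lab_ord[!is.na(lab_ord)]))
    grp_tbl <- unique(data.frame(comp = comp[!is.na(lab_ord)],
                                 cluster = lab_ord[!is.na(lab_ord)]))
    grp_tbl <- grp_tbl[big[grp_tbl$comp], , drop = FALSE]
    map <- setNames(paste0("solo", all_clusters), all_clusters)
    if (nrow(grp_tbl) > 0) {
      cg <- igraph::graph_from_data_frame(
        data.frame(from = paste0("comp", grp_tbl$comp),
                   to = paste0("clu", grp_tbl$cluster)),
        directed = FALSE
      )
      mem <- igraph::components(cg)$membership
      linked <- sort(unique(grp_tbl$cluster))
      map[as.character(linked)] <- paste0("grp", mem[paste0("clu", linked)])
    }
    merged <- match(unname(map[as.character(lab_ord)]), unique(unname(map)))
    merged[is.na(lab_ord)] <- NA_integer_
    # renumber merged clusters by smallest member cell_id
    present <- !is.na(merged)
    firsts <- tapply(seq_along(merged)[present], merged[present], min)
    remap <- setNames(as.integer(rank(firsts)), names(firsts))
    merged[present] <- remap[as.character(merged[present])]
    lab[ord] <- as.integer(merged)
    cells$cluster_id[sel] <- lab
  }
  cells
}

#' Polygonize clusters into boundary shapes
#'
#' Computes the alpha-shape boundary and area of each cluster's member
#' cells. Clusters of fewer than 3 distinct non-collinear cells are flagged
#' degenerate with area 0.
#'
#' @param cells output of [detect_aggregates()]/[merge_connected()].
#' @param params [clustering_params()] (uses `hull_alpha_um`).
#' @return tibble: `section_id`, `cluster_id`, `n_cells`, `centroid_x`,
#'   `centroid_y`, `area_um2`, `degenerate`, and a `shape` list-column of
#'   [alpha_shape()] results.
#' @export
polygonize_clusters <- function(cells, params = clustering_params()) {
  clustered <- dplyr::filter(cells, !is.na(.data$cluster_id))
  if (nrow(clustered) == 0) {
    return(tibble::tibble(
      section_id = character(), cluster_id = integer(), n_cells = integer(),
      centroid_x = numeric(), centroid_y = numeric(), area_um2 = numeric(),
      degenerate = logical(), shape = list()
    ))
  }
  clustered |>
    dplyr::group_by(.data$section_id, .data$cluster_id) |>
    dplyr::group_modify(function(df, key) {
      shp <- alpha_shape(df$x, df$y, params$hull_alpha_um)
      tibble::tibble(
        n_cells = nrow(df),
        centroid_x = mean(df$x), centroid_y = mean(df$y),
        area_um2 = shp$area, degenerate = shp$degenerate,
        shape = list(shp)
      )
    }) |>
    dplyr::ungroup()
}
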