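# Reading cell-level segmentation exports and region annotations; writing
# the pipeline's tables and manifest.

#' Column-mapping dialect for cell tables
#'
#' Describes how a cell-level export (e.g. an InForm/phenoptr-style CSV) maps
#' onto the fields the pipeline needs. Marker columns may hold 0/1,
#' TRUE/FALSE, or "pos"/"neg"-style values; `true_values`/`false_values`
#' control the coercion. `unit_scale` converts the file's coordinate units to
#' µm (1 for µm exports; e.g. 0.5 for a 0.5 µm/px pixel export).
#'
#' @param x,y,cd20,cd3,cd8,foxp3,ki67 column names in the file.
#' @param cell_id optional id column; when NULL, row numbers are used.
#' @param section_id,patient_id optional columns holding identifiers.
#' @param delim field delimiter; when NULL, inferred from the file extension
#'   (".tsv"/".txt" tab, otherwise comma).
#' @param true_values,false_values accepted spellings of the boolean calls
#'   (case-insensitive).
#' @param unit_scale µm per coordinate unit.
#' @return a list of class `tls_dialect`.
#' @export
cell_dialect <- function(x = "x", y = "y", cd20 = "CD20", cd3 = "CD3",
                         cd8 = "CD8", foxp3 = "FOXP3", ki67 = "KI67",
                         cell_id = NULL, section_id = NULL, patient_id = NULL,
                         delim = NULL,
                         true_values = c("1", "true", "pos", "+", "yes"),
                         false_values = c("0", "false", "neg", "-", "no"),
                         unit_scale = 1) {
  out <- list(
    x = x, y = y, cd20 = cd20, cd3 = cd3, cd8 = cd8, foxp3 = foxp3,
    ki67 = ki67, cell_id = cell_id, section_id = section_id,
    patient_id = patient_id, delim = delim,
    true_values = tolower(true_values), false_values = tolower(false_values),
    unit_scale = unit_scale
  )
  stopifnot(unit_scale > 0)
  class(out) <- "tls_dialect"
  out
}

coerce_marker <- function(v, column, dialect) {
  s <- tolower(trimws(as.character(v)))
  out <- rep(NA, length(s))
  out[s %in% dialect$true_values] <- TRUE
  out[s %in% dialect$false_values] <- FALSE
  bad <- is.na(out) & !is.na(s) & s != ""
  if (any(bad)) {
    stop("column '", column, "' holds values not coercible to boolean: ",
         paste(unique(s[bad])[1:min(3, length(unique(s[bad])))],
               collapse = ", "))
  }
  as.logical(out)
}

#' Read a cell-level table
#'
#' Loads a CSV/TSV segmentation export into the cell-table format used
#' throughout the package: one row per cell with µm coordinates and strictly
#' boolean marker calls (thresholding is assumed to have happened upstream).
#' Rows with missing coordinates are dropped and counted (attribute
#' `n_dropped`); marker conflicts such as CD20+CD3+ are loaded verbatim —
#' resolving them is the phenotyping stage's job.
#'
#' @param path file path.
#' @param dialect a [cell_dialect()].
#' @param section_id,patient_id defaults when the dialect maps no columns for
#'   them (section defaults to the file name).
#' @return tibble with columns `section_id`, `patient_id`, `cell_id`, `x`,
#'   `y` (µm), `cd20`, `cd3`, `cd8`, `foxp3`, `ki67`; attribute `n_dropped`
#'   holds the dropped-row count.
#' @export
read_cell_table <- function(path, dialect = cell_dialect(),
                            section_id = NULL, patient_id = NA_character_) {
  stopifnot(file.exists(path))
  delim <- dialect$delim
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  mapped <- c(x = dialect$x, y = dialect$y, cd20 = dialect$cd20,
              cd3 = dialect$cd3, cd8 = dialect$cd8, foxp3 = dialect$foxp3,
              ki67 = dialect$ki67)
  missing <- mapped[!mapped %in% names(raw)]
  if (length(missing) > 0) {
    stop("mapped column(s) not found in ", path, ": ",
         paste(missing, collapse = ", "))
  }
  if (nrow(raw) == 0) stop("no parseable rows in ", path)

  x <- suppressWarnings(as.numeric(raw[[dialect$x]])) * dialect$unit_scale
  y <- suppressWarnings(as.numeric(raw[[dialect$y]])) * dialect$unit_scale
  keep <- is.finite(x) & is.finite(y)
  n_dropped <- sum(!keep)
  if (sum(keep) == 0) stop("no rows with usable coordinates in ", path)

  cell_id <- if (!is.null(dialect$cell_id)) {
    raw[[dialect$cell_id]]
  } else {
    seq_len(nrow(raw))
  }
  sec <- if (!is.null(dialect$section_id)) {
    raw[[dialect$section_id]]
  } else {
    if (is.null(section_id)) section_id <- basename(path)
    section_id
  }
  pat <- if (!is.null(dialect$patient_id)) raw[[dialect$patient_id]] else
    patient_id

  cells <- tibble::tibble(
    section_id = sec, patient_id = pat, cell_id = cell_id,
    x = x, y = y,
    cd20 = coerce_marker(raw[[dialect$cd20]], dialect$cd20, dialect),
    cd3 = coerce_marker(raw[[dialect$cd3]], dialect$cd3, dialect),
    cd8 = coerce_marker(raw[[dialect$cd8]], dialect$cd8, dialect),
    foxp3 = coerce_marker(raw[[dialect$foxp3]], dialect$foxp3, dialect),
    ki67 = coerce_marker(raw[[dialect$ki67]], dialect$ki67, dialect)
  )[keep, ]
  if (anyDuplicated(paste(cells$section_id, cells$cell_id))) {
    stop("cell_id values are not unique within a section in ", path)
  }
  attr(cells, "n_dropped") <- n_dropped
  cells
}

geojson_rings <- function(coords) {
  lapply(coords, function(ring) {
    m <- do.call(rbind, lapply(ring, function(pt) {
      c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))
    }))
    colnames(m) <- c("x", "y")
    m
  })
}

validate_polygon <- function(rings, idx) {
  rings <- lapply(rings, repair_ring) # one-shot repair, then re-check
  ok <- vapply(rings, ring_is_simple, logical(1))
  if (!all(ok)) {
    stop("feature ", idx, ": polygon ring self-intersects after repair")
  }
  list(outer = rings[[1]], holes = rings[-1])
}

#' Read region annotations from GeoJSON
#'
#' Consumes a QuPath-style FeatureCollection of Polygon/MultiPolygon features
#' in section coordinates (µm). The first ring of each polygon is the outer
#' boundary, further rings are holes (preserved). Rings are repaired once
#' (duplicate consecutive vertices dropped); rings that still self-intersect
#' are rejected.
#'
#' @param path GeoJSON file.
#' @param kind "tissue" or "tumour" (recorded as an attribute).
#' @return list of polygons, each `list(outer = matrix, holes = list)`.
#' @export
read_regions <- function(path, kind = c("tissue", "tumour")) {
  kind <- match.arg(kind)
  gj <- jsonlite::read_json(path)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("not a GeoJSON FeatureCollection: ", path)
  }
  polys <- list()
  for (i in seq_along(gj$features)) {
    geom <- gj$features[[i]]$geometry
    if (is.null(geom$type)) stop("feature ", i, " has no geometry")
    if (geom$type == "Polygon") {
      polys[[length(polys) + 1]] <-
        validate_polygon(geojson_rings(geom$coordinates), i)
    } else if (geom$type == "MultiPolygon") {
      for (part in geom$coordinates) {
        polys[[length(polys) + 1]] <-
          validate_polygon(geojson_rings(part), i)
      }
    } else {
      stop("feature ", i, " has non-polygon geometry '", geom$type, "'")
    }
  }
  attr(polys, "kind") <- kind
  polys
}

#' Write pipeline outputs
#'
#' Writes the per-domain table, per-section summary, correlation and ranking
#' tables as UTF-8/LF TSV with fixed column order, and a JSON manifest
#' recording the parameters (including the qualification thresholds and gate
#' order) and package version. Output is deterministic: identical inputs give
#' byte-identical files.
#'
#' @param results list as returned by [run_pipeline()] (any subset of
#'   `domains`, `summaries`, `correlations`, `rankings`, `concordance`,
#'   `params` is honoured).
#' @param out_dir output directory (created if absent).
#' @return invisibly, a tibble manifest of written files.
#' @export
write_outputs <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()

  write_tbl <- function(tbl, file, cols = NULL) {
    path <- file.path(out_dir, file)
    tbl <- tibble::as_tibble(tbl)
    drop <- intersect("shape", names(tbl))
    if (length(drop)) tbl <- tbl[, setdiff(names(tbl), drop)]
    if (!is.null(cols)) tbl <- tbl[, intersect(cols, names(tbl))]
    readr::write_tsv(tbl, path, progress = FALSE)
    written <<- c(written, path)
  }

  if (!is.null(results$domains)) {
    write_tbl(results$domains, "domains.tsv",
              c("domain_id", "section_id", "patient_id", "cluster_id",
                count_cols(), "n_total", "n_lymph", "area_um2",
                "qualified", "rejection_reason"))
  }
  if (!is.null(results$summaries)) write_tbl(results$summaries, "sections.tsv")
  if (!is.null(results$correlations)) {
    write_tbl(results$correlations, "correlations.tsv")
  }
  if (!is.null(results$rankings)) write_tbl(results$rankings, "rankings.tsv")
  if (!is.null(results$concordance)) {
    jsonlite::write_json(results$concordance,
                         file.path(out_dir, "concordance.json"),
                         auto_unbox = TRUE, digits = NA)
    written <- c(written, file.path(out_dir, "concordance.json"))
  }

  manifest <- list(
    package = "tlsquant",
    version = as.character(utils::packageVersion("tlsquant")),
    params = results$params,
    coordinate_units = "um (origin top-left, y increasing downward)",
    gate_order = "CD3+CD8+ > CD3+CD8-Foxp3+ > CD3+CD8-Foxp3- > CD20+CD3- > undefined",
    caveat = "per-domain correlations ignore patient-level clustering",
    files = basename(written)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(tibble::tibble(file = c(basename(written), "manifest.json"),
                           path = c(written,
                                    file.path(out_dir, "manifest.json"))))
}

#' Export domain boundaries as GeoJSON
#'
#' @param domains qualified-domain tibble carrying a `shape` list-column.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_domain_geojson <- function(domains, path) {
  features <- purrr::pmap(
    list(domains$domain_id, domains$shape, domains$area_um2),
    function(id, shape, area) {
      rings <- lapply(shape$rings, function(r) {
        if (!all(r[1, ] == r[nrow(r), ])) r <- rbind(r, r[1, , drop = FALSE])
        lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
      })
      list(
        type = "Feature",
        properties = list(domain_id = id, area_um2 = area),
        geometry = list(type = "Polygon", coordinates = rings)
      )
    }
  )
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
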