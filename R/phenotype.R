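# Phenotype gating: five boolean marker calls -> one of nine classes.

#' Gate marker calls into lymphocyte subsets
#'
#' Applies the gating used throughout the package: B cells are CD20+CD3-;
#' CD8 T-cells CD3+CD8+ (Foxp3 ignored); conventional CD4 T-cells
#' CD3+CD8-Foxp3-; Foxp3+ CD4 T-cells CD3+CD8-Foxp3+; everything else is
#' "undefined". CD20+CD3+ cells fall through to the T-cell gates, because the
#' B gate requires CD3-. The function is total: every one of the 32 marker
#' combinations maps to exactly one subset.
#'
#' @param cd20,cd3,cd8,foxp3,ki67 logical vectors of equal length.
#' @return tibble with columns `subset` (factor: B, CD8T, CD4Tconv, CD4Treg,
#'   undefined), `ki67` (logical; always FALSE for undefined cells, which
#'   carry no Ki-67 sub-classification) and `phenotype` (one of the nine
#'   class labels).
#' @examples
#' classify_markers(TRUE, FALSE, FALSE, FALSE, FALSE) # B, Ki-67-
#' @export
classify_markers <- function(cd20, cd3, cd8, foxp3, ki67) {
  subset <- dplyr::case_when(
    cd3 & cd8 ~ "CD8T",
    cd3 & !cd8 & foxp3 ~ "CD4Treg",
    cd3 & !cd8 & !foxp3 ~ "CD4Tconv",
    cd20 & !cd3 ~ "B",
    TRUE ~ "undefined"
  )
  k <- ki67 & subset != "undefined"
  tibble::tibble(
    subset = factor(subset, levels = c(SUBSETS, "undefined")),
    ki67 = k,
    phenotype = factor(
      ifelse(subset == "undefined", "undefined",
             paste0(subset, ifelse(k, "_ki67pos", "_ki67neg"))),
      levels = PHENOTYPES
    )
  )
}

#' Phenotype every cell in a section table
#'
#' Appends `subset`, `ki67` and `phenotype` columns to a cell table holding
#' boolean marker columns `cd20`, `cd3`, `cd8`, `foxp3`, `ki67` (the raw
#' marker call column is preserved as `ki67_marker`). Per-class counts always
#' sum to the number of input rows.
#'
#' @param cells tibble of cells, e.g. from [read_cell_table()] or
#'   [simulate_cohort()].
#' @return the input tibble with phenotype columns appended.
#' @export
classify_cells <- function(cells) {
  need <- c("cd20", "cd3", "cd8", "foxp3", "ki67")
  missing <- setdiff(need, names(cells))
  if (length(missing) > 0) {
    stop("cell table lacks marker column(s): ", paste(missing, collapse = ", "))
  }
  lab <- classify_markers(cells$cd20, cells$cd3, cells$cd8,
                          cells$foxp3, cells$ki67)
  cells$ki67_marker <- cells$ki67
  cells$subset <- lab$subset
  cells$ki67 <- lab$ki67
  cells$phenotype <- lab$phenotype
  cells
}

is_lymphocyte <- function(subset) subset %in% SUBSETS

# tabulate phenotype labels into one row of the nine count columns
phenotype_counts <- function(phenotype) {
  counts <- table(factor(phenotype, levels = PHENOTYPES))
  out <- tibble::as_tibble(as.list(as.integer(counts)), .name_repair = "minimal")
  names(out) <- count_cols()
  out$n_total <- length(phenotype)
  out$n_lymph <- out$n_total - out$n_undefined
  out
}
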