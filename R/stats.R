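# Cross-subset Ki-67 rank correlations, the non-proliferating Foxp3+
# presence analysis, patient rankings and ranking concordance.

#' Filter domains for correlation analyses
#'
#' Removes TLS domains with fewer than `min_cells` cells of the assessed
#' phenotypes (the eight lymphocyte classes, i.e. `n_lymph`), so every
#' correlation point rests on a robust sample. Applied only on correlation
#' paths — rankings and area metrics use all qualified domains.
#'
#' @param domains qualified domain tibble.
#' @param min_cells minimum lymphocyte count (default 50).
#' @return the filtered tibble.
#' @export
filter_domains_for_correlation <- function(domains, min_cells = 50) {
  if ("qualified" %in% names(domains)) {
    domains <- dplyr::filter(domains, .data$qualified)
  }
  dplyr::filter(domains, .data$n_lymph >= min_cells)
}

# average ranks (ties averaged), the transform under which Spearman's rho is
# Pearson's r
avg_rank <- function(v) rank(v, ties.method = "average")

# all permutations of 1..n as a matrix (n <= 9)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1))
  }))
}

#' Spearman rank correlation with explicit p-value policy
#'
#' rho is Pearson's correlation of average ranks (so it is invariant under
#' strictly monotone transforms of either variable — identical before and
#' after log10 display scaling). Two-sided p-values use the t approximation
#' for n >= 10 and the exact permutation distribution below that. Pairs with
#' missing values are dropped; `n_points` reflects the drops.
#'
#' @param x,y numeric vectors.
#' @param x_variable,y_variable descriptions for reporting.
#' @return one-row tibble of class `tls_correlation`: `x_variable`,
#'   `y_variable`, `n_points`, `rho`, `p_value`, `method`, `scale_note`,
#'   `insufficient`.
#' @export
spearman_cor <- function(x, y, x_variable = "x", y_variable = "y") {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  out <- tibble::tibble(
    x_variable = x_variable, y_variable = y_variable, n_points = n,
    rho = NA_real_, p_value = NA_real_, method = NA_character_,
    scale_note = "log10 scaling is display-only; rho/p unaffected",
    insufficient = TRUE
  )
  class(out) <- c("tls_correlation", class(out))
  if (n < 3) return(out)
  if (sd(x) == 0 || sd(y) == 0) return(out) # rho undefined sentinel
  rx <- avg_rank(x); ry <- avg_rank(y)
  rho <- stats::cor(rx, ry)
  if (n >= 10) {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    method <- "t-approximation"
  } else {
    perms <- all_perms(n)
    s <- as.vector(matrix(ry[perms], nrow(perms), n) %*% rx)
    rho_null <- (s - n * mean(rx) * mean(ry)) / ((n - 1) * sd(rx) * sd(ry))
    p <- mean(abs(rho_null) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  }
  out$rho <- rho
  out$p_value <- p
  out$method <- method
  out$insufficient <- FALSE
  out
}

#' Pairwise Ki-67 correlations among lymphocyte subsets
#'
#' All pairwise Spearman correlations among the per-unit Ki-67 fractions of
#' B, CD8T, CD4Tconv and CD4Treg cells. At domain level each filtered TLS
#' domain is one point; at section level each section's pooled composition
#' is one point (pooling first averages within-patient noise). Results with
#' fewer than 3 usable points are flagged `insufficient`.
#'
#' @param compositions domain tibble (already passed through
#'   [filter_domains_for_correlation()] for domain level) or pooled section
#'   tibble from [pool_domains()].
#' @param level "domain" or "section" (recorded in the output).
#' @return tibble of class `tls_correlations`, one row per subset pair.
#' @export
ki67_correlation_suite <- function(compositions,
                                   level = c("domain", "section")) {
  level <- match.arg(level)
  fr <- ki67_fractions(compositions)
  pairs <- utils::combn(SUBSETS, 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    spearman_cor(
      fr[[paste0("ki67_frac_", a)]], fr[[paste0("ki67_frac_", b)]],
      x_variable = paste0(a, "_ki67_frac"),
      y_variable = paste0(b, "_ki67_frac")
    )
  })
  out$level <- level
  class(out) <- c("tls_correlations", class(tibble::tibble()))
  out
}

#' Non-proliferating Foxp3+ CD4 presence analysis
#'
#' Correlates the per-domain presence of non-proliferating (Ki-67-) Foxp3+
#' CD4 T-cells — their count as a fraction of all lymphocytes in the domain,
#' so x lies in \[0, 1\] by construction — against the Ki-67 fraction of
#' B-cells, conventional CD4 T-cells and CD8 T-cells.
#'
#' @param domains filtered domain tibble.
#' @return tibble of class `tls_correlations` with three rows.
#' @export
treg_presence_analysis <- function(domains) {
  x <- ifelse(domains$n_lymph > 0,
              domains$n_CD4Treg_ki67neg / domains$n_lymph, NA_real_)
  fr <- ki67_fractions(domains)
  out <- purrr::map_dfr(c("B", "CD4Tconv", "CD8T"), function(s) {
    spearman_cor(x, fr[[paste0("ki67_frac_", s)]],
                 x_variable = "CD4Treg_ki67neg_presence",
                 y_variable = paste0(s, "_ki67_frac"))
  })
  out$level <- "domain"
  class(out) <- c("tls_correlations", class(tibble::tibble()))
  out
}

#' Rank patients by B-cell proliferation
#'
#' Two methods: `per_domain_mean` averages the per-domain B-cell Ki-67
#' fraction over all of a patient's qualified TLS domains (each domain one
#' vote); `pooled` pools all of the patient's domain counts first and takes
#' the pooled B-cell Ki-67 fraction. Patients are ordered descending; ties
#' broken by patient id.
#'
#' @param domains qualified domain tibble (with `patient_id`).
#' @param method "per_domain_mean" or "pooled".
#' @return tibble of class `tls_ranking`: `rank`, `patient_id`, `measure`,
#'   `method`.
#' @export
rank_patients <- function(domains,
                          method = c("per_domain_mean", "pooled")) {
  method <- match.arg(method)
  if ("qualified" %in% names(domains)) {
    domains <- dplyr::filter(domains, .data$qualified)
  }
  measure <- if (method == "per_domain_mean") {
    ki67_fractions(domains) |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(measure = mean(.data$ki67_frac_B, na.rm = TRUE),
                       .groups = "drop")
  } else {
    pool_domains(domains, by = "patient_id") |>
      dplyr::mutate(measure = ki67_fraction(dplyr::pick(dplyr::everything()),
                                            "B")) |>
      dplyr::select("patient_id", "measure")
  }
  out <- measure |>
    dplyr::arrange(dplyr::desc(.data$measure), .data$patient_id) |>
    dplyr::mutate(rank = dplyr::row_number(), method = method) |>
    dplyr::relocate("rank")
  class(out) <- c("tls_ranking", class(tibble::tibble()))
  out
}

#' Compare two patient rankings
#'
#' Concordance between rankings of the same patient set: Spearman's rho on
#' rank positions, Spearman's footrule (sum of absolute rank differences)
#' and the size of the top-k overlap.
#'
#' @param a,b `tls_ranking` tibbles over the same patients.
#' @param k top-k size (default 8).
#' @return list: `rank_rho`, `rank_p`, `footrule`, `top_k`, `top_k_overlap`,
#'   `n_patients`, `methods`.
#' @export
compare_rankings <- function(a, b, k = 8) {
  if (!setequal(a$patient_id, b$patient_id)) {
    only_a <- setdiff(a$patient_id, b$patient_id)
    only_b <- setdiff(b$patient_id, a$patient_id)
    stop("rankings cover different patients; only in a: ",
         paste(only_a, collapse = ", "), "; only in b: ",
         paste(only_b, collapse = ", "))
  }
  ra <- a$rank[match(sort(a$patient_id), a$patient_id)]
  rb <- b$rank[match(sort(a$patient_id), b$patient_id)]
  cr <- spearman_cor(ra, rb, "rank_a", "rank_b")
  k <- min(k, nrow(a))
  top_a <- a$patient_id[a$rank <= k]
  top_b <- b$patient_id[b$rank <= k]
  list(
    rank_rho = cr$rho,
    rank_p = cr$p_value,
    footrule = sum(abs(ra - rb)),
    top_k = k,
    top_k_overlap = length(intersect(top_a, top_b)),
    n_patients = nrow(a),
    methods = c(a$method[1], b$method[1])
  )
}
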