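# Synthetic tissue-section generator: plants multi-lobular lymphoid
# aggregates with B-cell cores, optional germinal-centre-like Ki-67 hotspots
# and strand bridges into a background of scattered lymphocytes and
# marker-negative cells, with full ground-truth bookkeeping.

#' Configuration for a synthetic cohort
#'
#' Defaults describe a 22-patient colorectal-cancer-like cohort: one
#' 9x9 mm section per patient; per-section TLS counts drawn log-uniformly on
#' 4..100 (right-skewed, mean ~28); primary follicle radii 50-100 µm with on
#' average ~1.5 lobes per structure, lobes either overlapping or bridged by
#' lymphocyte strands; lymphocyte packing 0.01 cells/µm² inside domains; a
#' per-patient latent activation (sd 1.5 on the logit scale) shifts Ki-67
#' probability jointly in all subsets, and germinal-centre-like hotspots boost
#' B-cell Ki-67 locally so per-domain B-cell Ki-67 spans roughly 0-94% across
#' the cohort.
#'
#' @param n_patients number of patients.
#' @param sections_per_patient sections per patient.
#' @param domain_count_range integer range for TLS structures per section;
#'   counts are drawn log-uniformly over the range.
#' @param domain_radius_range range of the primary-lobe radius (µm).
#' @param lobularity expected number of lobes per structure (>= 1).
#' @param strand_probability chance a secondary lobe is bridged to the
#'   structure by a strand of lymphocytes rather than overlapping it.
#' @param lymphocyte_density_in_domain lymphocytes per µm² inside lobes.
#' @param background_cell_density scattered background cells per µm² over the
#'   whole section (mostly marker-negative; see `background_lymph_fraction`).
#' @param background_lymph_fraction fraction of background cells that are
#'   lymphocytes.
#' @param composition_dirichlet Dirichlet concentration over
#'   (B, CD8T, CD4Tconv, CD4Treg) for per-domain composition.
#' @param latent_activation_sd between-patient sd of latent activation
#'   (logit scale).
#' @param ki67_base_logit named baseline logits per subset.
#' @param gc_probability chance a domain contains a Ki-67 hotspot sub-disc.
#' @param gc_radius_frac hotspot radius as a fraction of the primary radius.
#' @param gc_ki67_boost logit-scale boost to B-cell Ki-67 inside the hotspot.
#' @param suppression_coeff logit-scale decrease of activation (for B,
#'   CD4Tconv and CD8T Ki-67) per unit Foxp3+ CD4 fraction in the domain.
#' @param undefined_fraction_in_domain fraction of in-domain cells that are
#'   marker-negative.
#' @param tissue_size_um section side length (µm).
#' @param min_separation_um guaranteed minimum edge-to-edge distance between
#'   planted structures (µm).
#' @param seed master seed.
#' @return a list of class `tls_cohort_config`.
#' @export
cohort_config <- function(n_patients = 22,
                          sections_per_patient = 1,
                          domain_count_range = c(4, 100),
                          domain_radius_range = c(50, 100),
                          lobularity = 1.5,
                          strand_probability = 0.25,
                          lymphocyte_density_in_domain = 0.01,
                          background_cell_density = 0.002,
                          background_lymph_fraction = 0.025,
                          composition_dirichlet = c(B = 4, CD8T = 1.5,
                                                    CD4Tconv = 2.5,
                                                    CD4Treg = 1),
                          latent_activation_sd = 1.5,
                          ki67_base_logit = c(B = -1.8, CD8T = -2.2,
                                              CD4Tconv = -2.0, CD4Treg = -1.4),
                          gc_probability = 0.5,
                          gc_radius_frac = 0.4,
                          gc_ki67_boost = 2,
                          suppression_coeff = 0,
                          undefined_fraction_in_domain = 0.15,
                          tissue_size_um = 9000,
                          min_separation_um = 250,
                          seed = 1) {
  cfg <- list(
    n_patients = n_patients,
    sections_per_patient = sections_per_patient,
    domain_count_range = domain_count_range,
    domain_radius_range = domain_radius_range,
    lobularity = lobularity,
    strand_probability = strand_probability,
    lymphocyte_density_in_domain = lymphocyte_density_in_domain,
    background_cell_density = background_cell_density,
    background_lymph_fraction = background_lymph_fraction,
    composition_dirichlet = composition_dirichlet,
    latent_activation_sd = latent_activation_sd,
    ki67_base_logit = ki67_base_logit,
    gc_probability = gc_probability,
    gc_radius_frac = gc_radius_frac,
    gc_ki67_boost = gc_ki67_boost,
    suppression_coeff = suppression_coeff,
    undefined_fraction_in_domain = undefined_fraction_in_domain,
    tissue_size_um = tissue_size_um,
    min_separation_um = min_separation_um,
    seed = seed
  )
  stopifnot(
    n_patients >= 1, sections_per_patient >= 1,
    length(domain_count_range) == 2, domain_count_range[1] >= 0,
    diff(domain_count_range) >= 0,
    domain_radius_range[1] > 0, diff(domain_radius_range) >= 0,
    lobularity >= 1,
    strand_probability >= 0, strand_probability <= 1,
    lymphocyte_density_in_domain > 0, background_cell_density >= 0,
    background_lymph_fraction >= 0, background_lymph_fraction <= 1,
    all(composition_dirichlet > 0),
    setequal(names(ki67_base_logit), SUBSETS),
    latent_activation_sd >= 0,
    gc_probability >= 0, gc_probability <= 1,
    undefined_fraction_in_domain >= 0, undefined_fraction_in_domain < 1,
    tissue_size_um > 0, min_separation_um > 0
  )
  class(cfg) <- "tls_cohort_config"
  cfg
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

# uniform points in a disc
runif_disc <- function(n, cx, cy, r) {
  th <- runif(n, 0, 2 * pi)
  rr <- r * sqrt(runif(n))
  cbind(cx + rr * cos(th), cy + rr * sin(th))
}

# right-skewed integer counts on [lo, hi] (log-uniform)
rcount_logunif <- function(n, lo, hi) {
  if (hi == lo) return(rep(as.integer(lo), n))
  pmin(hi, pmax(lo, as.integer(round(exp(runif(n, log(lo), log(hi)))))))
}

# maximum TLS envelope radius under a config (primary + bridged lobe + gap)
tls_envelope <- function(config) {
  2.2 * config$domain_radius_range[2] + 80
}

# sample the lobe geometry of one structure, centred at the origin
sample_lobes <- function(config) {
  r1 <- runif(1, config$domain_radius_range[1], config$domain_radius_range[2])
  k <- 1 + rpois(1, config$lobularity - 1)
  lobes <- tibble::tibble(cx = 0, cy = 0, r = r1, bridged = FALSE,
                          gap = 0, theta = 0)
  env <- tls_envelope(config)
  for (i in seq_len(k - 1)) {
    bridged <- runif(1) < config$strand_probability
    th <- runif(1, 0, 2 * pi)
    if (bridged) {
      ri <- r1 * runif(1, 0.4, 0.6)
      gap <- runif(1, 30, 80)
      d <- r1 + ri + gap
    } else {
      ri <- r1 * runif(1, 0.55, 0.85)
      gap <- 0
      d <- (r1 + ri) * runif(1, 0.55, 0.8)
    }
    if (d + ri > env) next # keep structure inside its envelope
    lobes <- dplyr::bind_rows(lobes, tibble::tibble(
      cx = d * cos(th), cy = d * sin(th), r = ri, bridged = bridged,
      gap = gap, theta = th
    ))
  }
  lobes
}

# area of a union of discs by grid sampling (truth bookkeeping)
lobe_union_area <- function(lobes, grid_um = 4) {
  x0 <- min(lobes$cx - lobes$r); x1 <- max(lobes$cx + lobes$r)
  y0 <- min(lobes$cy - lobes$r); y1 <- max(lobes$cy + lobes$r)
  gx <- seq(x0 + grid_um / 2, x1, by = grid_um)
  gy <- seq(y0 + grid_um / 2, y1, by = grid_um)
  pts <- expand.grid(x = gx, y = gy)
  inside <- rep(FALSE, nrow(pts))
  for (i in seq_len(nrow(lobes))) {
    inside <- inside | ((pts$x - lobes$cx[i])^2 + (pts$y - lobes$cy[i])^2
                        <= lobes$r[i]^2)
  }
  sum(inside) * grid_um^2
}

# marker calls consistent with the phenotyping gates (gates invert exactly);
# T cells occasionally carry aberrant CD20, CD8 T cells occasionally Foxp3
markers_from_labels <- function(subset, ki67) {
  n <- length(subset)
  t_cell <- subset %in% c("CD8T", "CD4Tconv", "CD4Treg")
  tibble::tibble(
    cd20 = subset == "B" | (t_cell & runif(n) < 0.02),
    cd3 = t_cell,
    cd8 = subset == "CD8T",
    foxp3 = subset == "CD4Treg" | (subset == "CD8T" & runif(n) < 0.05),
    ki67 = ifelse(subset == "undefined", runif(n) < 0.1, ki67)
  )
}

#' Generate one synthetic tissue section
#'
#' Plants TLS-like structures on a jittered grid (guaranteeing the configured
#' minimum separation), fills lobes with lymphocytes drawn from a per-domain
#' Dirichlet composition with a B-cell core and peripheral T-cells, assigns
#' Ki-67 from the logistic activation model, adds strand bridges, in-domain
#' marker-negative cells and scattered background, and emits marker calls
#' from which [classify_cells()] recovers the planted labels exactly.
#'
#' @param config a [cohort_config()].
#' @param patient_id,section_id identifiers.
#' @param activation patient latent activation (logit scale).
#' @param seed integer seed for this section's RNG stream.
#' @return list with `cells` (tibble; truth columns `true_subset`,
#'   `true_ki67`, `truth_domain_id` included) and `truth` (per-domain truth
#'   tibble plus Ki-67 expectation bookkeeping).
#' @export
simulate_section <- function(config, patient_id, section_id, activation,
                             seed) {
  withr::with_seed(seed, simulate_section_impl(
    config, patient_id, section_id, activation
  ))
}

simulate_section_impl <- function(config, patient_id, section_id, activation) {
  ts <- config$tissue_size_um
  env <- tls_envelope(config)
  spacing <- 2 * env + config$min_separation_um
  m <- floor(ts / spacing)
  n_nodes <- m * m
  k <- rcount_logunif(1, config$domain_count_range[1],
                      config$domain_count_range[2])
  if (k > n_nodes) {
    stop("degenerate geometry: ", k, " domains cannot be placed in a ",
         ts, " um section at the configured separation (", n_nodes,
         " sites available)")
  }
  jit <- config$min_separation_um / 12
  node_xy <- expand.grid(
    x = spacing / 2 + spacing * (seq_len(m) - 1) + (ts - m * spacing) / 2,
    y = spacing / 2 + spacing * (seq_len(m) - 1) + (ts - m * spacing) / 2
  )
  sel <- sample.int(n_nodes, k)
  centres <- node_xy[sel, , drop = FALSE] +
    matrix(runif(2 * k, -jit, jit), ncol = 2)

  base <- config$ki67_base_logit[SUBSETS]
  cells_list <- vector("list", k + 2)
  truth_list <- vector("list", k)
  exp_sum <- setNames(numeric(4), SUBSETS)   # sum of per-cell Ki-67 probs
  exp_var <- setNames(numeric(4), SUBSETS)   # sum of p(1-p)

  for (d in seq_len(k)) {
    lobes <- sample_lobes(config)
    lobes$cx <- lobes$cx + centres[d, 1]
    lobes$cy <- lobes$cy + centres[d, 2]
    lobe_area <- pi * lobes$r^2
    n_per_lobe <- rpois(nrow(lobes), config$lymphocyte_density_in_domain *
                          lobe_area)
    xy <- do.call(rbind, lapply(seq_len(nrow(lobes)), function(i) {
      runif_disc(n_per_lobe[i], lobes$cx[i], lobes$cy[i], lobes$r[i])
    }))
    n <- sum(n_per_lobe)

    # strand bridges between the primary lobe and bridged lobes
    strand_xy <- NULL
    for (i in which(lobes$bridged)) {
      p0 <- c(lobes$cx[1] + lobes$r[1] * cos(lobes$theta[i]),
              lobes$cy[1] + lobes$r[1] * sin(lobes$theta[i]))
      p1 <- c(lobes$cx[i] - lobes$r[i] * cos(lobes$theta[i]),
              lobes$cy[i] - lobes$r[i] * sin(lobes$theta[i]))
      ns <- max(2, ceiling(lobes$gap[i] / 12))
      tfrac <- seq(0, 1, length.out = ns)
      sx <- p0[1] + tfrac * (p1[1] - p0[1]) + rnorm(ns, 0, 4)
      sy <- p0[2] + tfrac * (p1[2] - p0[2]) + rnorm(ns, 0, 4)
      strand_xy <- rbind(strand_xy, cbind(sx, sy))
    }
    n_strand <- if (is.null(strand_xy)) 0L else nrow(strand_xy)
    if (n_strand > 0) xy <- rbind(xy, strand_xy)
    n_all <- n + n_strand
    if (n_all == 0) next

    # composition and B-core / peripheral-T spatial layout
    w <- rdirichlet1(config$composition_dirichlet[SUBSETS])
    counts <- as.vector(stats::rmultinom(1, n_all, w))
    d_norm <- rep(Inf, n_all)
    for (i in seq_len(nrow(lobes))) {
      d_norm <- pmin(d_norm, sqrt((xy[, 1] - lobes$cx[i])^2 +
                                    (xy[, 2] - lobes$cy[i])^2) / lobes$r[i])
    }
    ord <- order(d_norm + rnorm(n_all, 0, 0.25))
    subset <- character(n_all)
    subset[ord[seq_len(counts[1])]] <- "B"
    rest <- ord[-seq_len(counts[1])]
    subset[rest] <- sample(rep(SUBSETS[-1], counts[-1]))

    treg_frac <- counts[4] / n_all
    act_eff <- activation - config$suppression_coeff * treg_frac
    eta <- setNames(c(base["B"] + act_eff, base["CD8T"] + act_eff,
                      base["CD4Tconv"] + act_eff,
                      base["CD4Treg"] + activation), SUBSETS)

    has_gc <- runif(1) < config$gc_probability
    p_cell <- unname(plogis(eta[subset]))
    in_gc <- rep(FALSE, n_all)
    if (has_gc) {
      gc_r <- config$gc_radius_frac * lobes$r[1]
      in_gc <- (xy[, 1] - lobes$cx[1])^2 + (xy[, 2] - lobes$cy[1])^2 <= gc_r^2
      boost <- in_gc & subset == "B"
      p_cell[boost] <- plogis(eta["B"] + config$gc_ki67_boost)
    }
    ki67 <- runif(n_all) < p_cell
    for (s in SUBSETS) {
      sel_s <- subset == s
      exp_sum[s] <- exp_sum[s] + sum(p_cell[sel_s])
      exp_var[s] <- exp_var[s] + sum(p_cell[sel_s] * (1 - p_cell[sel_s]))
    }

    # in-domain marker-negative cells
    f <- config$undefined_fraction_in_domain
    n_u <- rpois(1, n * f / (1 - f))
    u_lobe <- sample.int(nrow(lobes), n_u, replace = TRUE,
                         prob = lobe_area / sum(lobe_area))
    u_xy <- do.call(rbind, lapply(seq_len(nrow(lobes)), function(i) {
      ni <- sum(u_lobe == i)
      runif_disc(ni, lobes$cx[i], lobes$cy[i], lobes$r[i])
    }))

    sub_all <- c(subset, rep("undefined", n_u))
    ki_all <- c(ki67, rep(FALSE, n_u))
    xy_all <- rbind(xy, u_xy)
    cells_list[[d]] <- tibble::tibble(
      x = xy_all[, 1], y = xy_all[, 2],
      true_subset = sub_all, true_ki67 = ki_all,
      truth_domain_id = d
    )
    truth_list[[d]] <- dplyr::bind_cols(
      tibble::tibble(
        section_id = section_id, patient_id = patient_id,
        truth_domain_id = d,
        centre_x = centres[d, 1], centre_y = centres[d, 2],
        n_lobes = nrow(lobes), has_gc = has_gc,
        area_um2 = lobe_union_area(lobes)
      ),
      phenotype_counts(factor(
        ifelse(sub_all == "undefined", "undefined",
               paste0(sub_all, ifelse(ki_all, "_ki67pos", "_ki67neg"))),
        levels = PHENOTYPES
      ))
    )
  }

  # scattered background: sparse lymphocytes plus marker-negative cells
  area <- ts^2
  n_bg <- rpois(1, config$background_cell_density * area)
  n_bgl <- rbinom(1, n_bg, config$background_lymph_fraction)
  bg_mix <- c(B = 0.15, CD8T = 0.35, CD4Tconv = 0.40, CD4Treg = 0.10)
  bg_sub <- sample(SUBSETS, n_bgl, replace = TRUE, prob = bg_mix)
  p_bg <- unname(plogis(base[bg_sub] + activation))
  bg_ki <- runif(n_bgl) < p_bg
  for (s in SUBSETS) {
    sel_s <- bg_sub == s
    exp_sum[s] <- exp_sum[s] + sum(p_bg[sel_s])
    exp_var[s] <- exp_var[s] + sum(p_bg[sel_s] * (1 - p_bg[sel_s]))
  }
  cells_list[[k + 1]] <- tibble::tibble(
    x = runif(n_bgl, 0, ts), y = runif(n_bgl, 0, ts),
    true_subset = bg_sub, true_ki67 = bg_ki,
    truth_domain_id = NA_integer_
  )
  n_bgu <- n_bg - n_bgl
  cells_list[[k + 2]] <- tibble::tibble(
    x = runif(n_bgu, 0, ts), y = runif(n_bgu, 0, ts),
    true_subset = "undefined", true_ki67 = FALSE,
    truth_domain_id = NA_integer_
  )

  cells <- dplyr::bind_rows(cells_list)
  cells$x <- pmin(pmax(cells$x, 0), ts)
  cells$y <- pmin(pmax(cells$y, 0), ts)
  mk <- markers_from_labels(cells$true_subset, cells$true_ki67)
  cells <- dplyr::bind_cols(
    tibble::tibble(section_id = section_id, patient_id = patient_id,
                   cell_id = seq_len(nrow(cells))),
    cells[, c("x", "y")], mk,
    cells[, c("true_subset", "true_ki67", "truth_domain_id")]
  )

  truth_domains <- if (k > 0) dplyr::bind_rows(truth_list) else
    tibble::tibble()
  obs <- vapply(SUBSETS, function(s) {
    sum(cells$true_ki67[cells$true_subset == s])
  }, numeric(1))
  list(
    cells = cells,
    truth = list(
      domains = truth_domains,
      ki67_expectation = tibble::tibble(
        section_id = section_id, subset = SUBSETS,
        expected = as.numeric(exp_sum), variance = as.numeric(exp_var),
        observed = obs
      ),
      activation = activation
    )
  )
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws a per-patient latent activation from Normal(0, `latent_activation_sd`²)
#' shared by all of that patient's sections and domains — inducing the
#' cross-subset Ki-67 correlations the analysis is designed to detect — then
#' generates each section on its own RNG stream keyed by
#' (master seed, section index), so identical configs reproduce byte-identical
#' cohorts.
#'
#' @param config a [cohort_config()].
#' @return list with `cells` (all sections, one row per cell), and `truth`
#'   (list: `domains`, `ki67_expectation`, `patients`, `config`).
#' @examples
#' cohort <- simulate_cohort(cohort_config(
#'   n_patients = 2, domain_count_range = c(2, 4), tissue_size_um = 3000
#' ))
#' nrow(cohort$truth$domains)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "tls_cohort_config"))
  patients <- sprintf("P%03d", seq_len(config$n_patients))
  activation <- withr::with_seed(
    config$seed,
    rnorm(config$n_patients, 0, config$latent_activation_sd)
  )
  s_idx <- 0L
  cells <- list()
  dom <- list()
  kexp <- list()
  for (p in seq_along(patients)) {
    for (s in seq_len(config$sections_per_patient)) {
      s_idx <- s_idx + 1L
      sec_seed <- (config$seed %% 100000L) * 20011L + s_idx * 7919L
      sec_id <- sprintf("%s_s%d", patients[p], s)
      sec <- simulate_section(config, patients[p], sec_id, activation[p],
                              seed = sec_seed)
      cells[[s_idx]] <- sec$cells
      dom[[s_idx]] <- sec$truth$domains
      kexp[[s_idx]] <- sec$truth$ki67_expectation
    }
  }
  all_cells <- dplyr::bind_rows(cells)
  # cohort-wide unique cell ids
  all_cells$cell_id <- seq_len(nrow(all_cells))
  list(
    cells = all_cells,
    truth = list(
      domains = dplyr::bind_rows(dom),
      ki67_expectation = dplyr::bind_rows(kexp),
      patients = tibble::tibble(patient_id = patients,
                                activation = activation),
      config = config
    )
  )
}

#' Generate per-domain composition tables without spatial placement
#'
#' Samples the same per-patient activation, per-domain Dirichlet composition
#' and logistic Ki-67 model as [simulate_cohort()], but skips cell placement
#' and clustering: it directly emits a qualified-domain-style table. Useful
#' for statistical properties of the correlation and ranking stages, where
#' only compositions matter and many replicate cohorts are needed.
#'
#' @param config a [cohort_config()].
#' @param seed overrides `config$seed` when given.
#' @return tibble with one row per domain: identifiers, the nine phenotype
#'   counts, `n_total`, `n_lymph`, `area_um2` and a `qualified` column set to
#'   TRUE; patient activations in attribute `activation`.
#' @export
simulate_domain_table <- function(config, seed = NULL) {
  stopifnot(inherits(config, "tls_cohort_config"))
  if (is.null(seed)) seed <- config$seed
  withr::with_seed(seed, {
    patients <- sprintf("P%03d", seq_len(config$n_patients))
    activation <- rnorm(config$n_patients, 0, config$latent_activation_sd)
    base <- config$ki67_base_logit[SUBSETS]
    rows <- list()
    for (p in seq_along(patients)) {
      k <- rcount_logunif(1, config$domain_count_range[1],
                          config$domain_count_range[2])
      for (d in seq_len(k)) {
        lobes <- sample_lobes(config)
        area <- sum(pi * lobes$r^2)
        n <- rpois(1, config$lymphocyte_density_in_domain * area)
        if (n == 0) next
        w <- rdirichlet1(config$composition_dirichlet[SUBSETS])
        counts <- as.vector(stats::rmultinom(1, n, w))
        treg_frac <- counts[4] / n
        act_eff <- activation[p] - config$suppression_coeff * treg_frac
        eta <- c(base["B"] + act_eff, base["CD8T"] + act_eff,
                 base["CD4Tconv"] + act_eff, base["CD4Treg"] + activation[p])
        has_gc <- runif(1) < config$gc_probability
        # hotspot: B cells within the sub-disc of the primary lobe
        gc_frac <- if (has_gc) {
          config$gc_radius_frac^2 * pi * lobes$r[1]^2 / area
        } else 0
        n_b_gc <- rbinom(1, counts[1], gc_frac)
        kpos <- c(
          rbinom(1, counts[1] - n_b_gc, plogis(eta[1])) +
            rbinom(1, n_b_gc, plogis(eta[1] + config$gc_ki67_boost)),
          rbinom(1, counts[2], plogis(eta[2])),
          rbinom(1, counts[3], plogis(eta[3])),
          rbinom(1, counts[4], plogis(eta[4]))
        )
        f <- config$undefined_fraction_in_domain
        n_u <- rpois(1, n * f / (1 - f))
        row <- tibble::tibble(
          section_id = sprintf("%s_s1", patients[p]),
          patient_id = patients[p],
          domain_id = sprintf("%s_s1_d%03d", patients[p], d),
          n_B_ki67pos = kpos[1], n_B_ki67neg = counts[1] - kpos[1],
          n_CD8T_ki67pos = kpos[2], n_CD8T_ki67neg = counts[2] - kpos[2],
          n_CD4Tconv_ki67pos = kpos[3],
          n_CD4Tconv_ki67neg = counts[3] - kpos[3],
          n_CD4Treg_ki67pos = kpos[4],
          n_CD4Treg_ki67neg = counts[4] - kpos[4],
          n_undefined = n_u,
          n_total = n + n_u, n_lymph = n,
          area_um2 = area, qualified = TRUE
        )
        rows[[length(rows) + 1]] <- row
      }
    }
    out <- dplyr::bind_rows(rows)
    attr(out, "activation") <- tibble::tibble(patient_id = patients,
                                              activation = activation)
    out
  })
}
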