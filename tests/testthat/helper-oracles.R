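# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles implement the stated definitions directly over a full
# distance matrix / explicit predicates; they never call the package's
# clustering or qualification code paths.

# Brute-force density clustering: cluster memberships are the connected
# components of the explicit eps-neighbourhood graph over core-reachable
# points; a core point has >= min_neighbours points (itself included) within
# eps. Border points join the cluster of their lowest-id core neighbour.
oracle_density_clusters <- function(x, y, eps, min_neighbours) {
  n <- length(x)
  if (n == 0) return(integer(0))
  d <- as.matrix(dist(cbind(x, y)))
  nb <- d <= eps
  core <- rowSums(nb) >= min_neighbours # diagonal TRUE = self included
  lab <- rep(NA_integer_, n)
  nxt <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || !is.na(lab[i])) next
    nxt <- nxt + 1L
    queue <- i
    lab[i] <- nxt
    while (length(queue) > 0) {
      cur <- queue[1]
      queue <- queue[-1]
      reach <- which(nb[cur, ] & core & is.na(lab))
      lab[reach] <- nxt
      queue <- c(queue, reach)
    }
  }
  for (i in which(!core)) {
    cn <- which(nb[i, ] & core)
    if (length(cn) > 0) lab[i] <- lab[min(cn)]
  }
  lab
}

# Bridge-connectivity oracle for strand merging: two clusters fuse iff they
# lie in the same connected component of the eps'-graph over all points and
# that component holds at least min_path cells.
oracle_merge_groups <- function(x, y, lab, eps2, min_path) {
  n <- length(x)
  d <- as.matrix(dist(cbind(x, y)))
  adj <- d <= eps2
  comp <- rep(NA_integer_, n)
  nxt <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    nxt <- nxt + 1L
    queue <- i
    comp[i] <- nxt
    while (length(queue) > 0) {
      cur <- queue[1]; queue <- queue[-1]
      reach <- which(adj[cur, ] & is.na(comp))
      comp[reach] <- nxt
      queue <- c(queue, reach)
    }
  }
  csize <- table(comp)
  # map each original cluster to its merged group
  cl <- sort(unique(lab[!is.na(lab)]))
  grp <- vapply(cl, function(ci) {
    co <- unique(comp[!is.na(lab) & lab == ci])[1]
    if (csize[as.character(co)] >= min_path) paste0("comp", co)
    else paste0("solo", ci)
  }, character(1))
  setNames(grp, cl)
}

# Independently coded qualification predicate
oracle_qualify <- function(n_total, n_lymph, min_cells = 250,
                           min_lymph_frac = 0.5) {
  n_total >= min_cells & (n_lymph / n_total) > min_lymph_frac
}

# uniform points in a disc
disc_points <- function(n, cx, cy, r) {
  th <- runif(n, 0, 2 * pi)
  rr <- r * sqrt(runif(n))
  tibble::tibble(x = cx + rr * cos(th), y = cy + rr * sin(th))
}

# minimal phenotyped cell table from coordinates (all B cells unless stated)
make_cells <- function(xy, subset = "B", section_id = "s1",
                       patient_id = "p1", ki67 = FALSE) {
  n <- nrow(xy)
  tibble::tibble(
    section_id = section_id, patient_id = patient_id, cell_id = seq_len(n),
    x = xy$x, y = xy$y,
    cd20 = subset == "B",
    cd3 = subset %in% c("CD8T", "CD4Tconv", "CD4Treg"),
    cd8 = subset == "CD8T",
    foxp3 = subset == "CD4Treg",
    ki67 = ki67
  )
}

# small fast cohort config for functional tests
small_config <- function(seed = 1, ...) {
  cohort_config(
    n_patients = 3, domain_count_range = c(3, 6), tissue_size_um = 4000,
    background_cell_density = 5e-4, seed = seed, ...
  )
}

# per-planted-domain Jaccard between planted lymphocyte memberships and the
# best-overlapping detected cluster
planted_jaccard <- function(cells) {
  lym <- cells[cells$subset %in% c("B", "CD8T", "CD4Tconv", "CD4Treg"), ]
  planted_key <- paste(lym$section_id, lym$truth_domain_id)
  planted <- split(seq_len(nrow(lym))[!is.na(lym$truth_domain_id)],
                   planted_key[!is.na(lym$truth_domain_id)])
  vapply(planted, function(rows) {
    cl <- lym$cluster_id[rows]
    cl <- cl[!is.na(cl)]
    if (length(cl) == 0) return(0)
    best <- as.integer(names(which.max(table(cl))))
    sec <- lym$section_id[rows][1]
    det <- which(!is.na(lym$cluster_id) & lym$cluster_id == best &
                   lym$section_id == sec)
    length(intersect(rows, det)) / length(union(rows, det))
  }, numeric(1))
}
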