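# Density-based aggregate detection against the brute-force
# eps-neighbourhood-graph oracle, strand merging, polygonization.

params_default <- clustering_params()

test_that("a dense disc plus isolated scatter yields exactly one cluster", {
  withr::local_seed(101)
  dense <- disc_points(500, 1000, 1000, 120) # ~31 neighbours in 30 um

  # scatter placed on a coarse lattice, each point >3x neighbour radius
  # from any other cell
  far <- tibble::tibble(
    x = rep(seq(3000, 16500, by = 1500), 5),
    y = rep(seq(3000, 9000, by = 1500), each = 10)
  )
  far <- far[1:50, ]
  cells <- classify_cells(make_cells(dplyr::bind_rows(dense, far)))
  out <- detect_aggregates(cells, params_default)
  lab <- out$cluster_id
  expect_equal(sum(!is.na(lab)), 500)
  expect_equal(length(unique(na.omit(lab))), 1)
  # matches brute-force oracle exactly
  oracle <- oracle_density_clusters(cells$x, cells$y, 30, 10)
  expect_equal(is.na(lab), is.na(oracle))
})

test_that("two separated discs yield two clusters", {
  withr::local_seed(5)
  a <- disc_points(300, 500, 500, 150)
  b <- disc_points(300, 500 + 10 * 30, 500, 150) # 10x neighbour radius apart
  cells <- classify_cells(make_cells(dplyr::bind_rows(a, b)))
  out <- detect_aggregates(cells, params_default)
  expect_equal(length(unique(na.omit(out$cluster_id))), 2)
})

test_that("two isolated cells form no cluster", {
  cells <- classify_cells(make_cells(tibble::tibble(x = c(0, 1000),
                                                    y = c(0, 0))))
  out <- detect_aggregates(cells, params_default)
  expect_true(all(is.na(out$cluster_id)))
})

test_that("memberships equal the explicit eps-graph components oracle", {
  withr::local_seed(77)
  for (rep in 1:12) {
    n_pts <- sample(50:400, 1)
    pts <- tibble::tibble(x = runif(n_pts, 0, 600),
                          y = runif(n_pts, 0, 600))
    eps <- runif(1, 20, 60)
    minn <- sample(3:8, 1)
    p <- clustering_params(neighbour_radius_um = eps, min_neighbours = minn,
                           strand_link_radius_um = eps + 10)
    cells <- classify_cells(make_cells(pts))
    lab <- detect_aggregates(cells, p)$cluster_id
    oracle <- oracle_density_clusters(pts$x, pts$y, eps, minn)
    expect_equal(is.na(lab), is.na(oracle))
    # same partition up to relabelling: cross-table is a permutation matrix
    both <- !is.na(lab)
    if (any(both)) {
      ct <- table(lab[both], oracle[both]) > 0
      expect_true(all(rowSums(ct) == 1) && all(colSums(ct) == 1))
    }
  }
})

test_that("cluster assignment is invariant under row permutation", {
  withr::local_seed(13)
  pts <- dplyr::bind_rows(disc_points(200, 300, 300, 100),
                          disc_points(150, 900, 300, 80),
                          tibble::tibble(x = runif(60, 0, 1200),
                                         y = runif(60, 0, 1200)))
  cells <- classify_cells(make_cells(pts))
  out1 <- detect_aggregates(cells, params_default)
  perm <- sample(nrow(cells))
  out2 <- detect_aggregates(cells[perm, ], params_default)
  expect_equal(out1$cluster_id,
               out2$cluster_id[match(cells$cell_id, out2$cell_id)])
})

bridge_fixture <- function(spacing = 15) {
  withr::local_seed(31)
  a <- disc_points(300, 0, 0, 100)
  b <- disc_points(300, 400, 0, 100)
  bridge <- tibble::tibble(x = seq(100, 300, by = spacing), y = 0)
  cells <- classify_cells(make_cells(dplyr::bind_rows(a, b, bridge)))
  list(cells = cells, n_bridge = nrow(bridge))
}

test_that("a lymphocyte strand merges two aggregates; removal splits them", {
  fx <- bridge_fixture(15) # spacing below strand_link_radius (40)
  det <- detect_aggregates(fx$cells, params_default)
  expect_gte(length(unique(na.omit(det$cluster_id))), 2)
  merged <- merge_connected(det, params_default)
  expect_equal(length(unique(na.omit(merged$cluster_id))), 1)
  # oracle agreement: eps'-graph connectivity over cluster + bridge cells
  grp <- oracle_merge_groups(fx$cells$x, fx$cells$y, det$cluster_id, 40, 5)
  expect_equal(length(unique(grp)), 1)

  # same discs without the bridge stay separate
  no_bridge <- det[seq_len(600), ]
  merged2 <- merge_connected(no_bridge, params_default)
  expect_equal(length(unique(na.omit(merged2$cluster_id))), 2)
  grp2 <- oracle_merge_groups(no_bridge$x, no_bridge$y,
                              no_bridge$cluster_id, 40, 5)
  expect_equal(length(unique(grp2)), 2)
})

test_that("strand merging is transitive across chained aggregates", {
  withr::local_seed(41)
  discs <- dplyr::bind_rows(
    disc_points(250, 0, 0, 90),
    disc_points(250, 350, 0, 90),
    disc_points(250, 700, 0, 90)
  )
  bridges <- tibble::tibble(
    x = c(seq(95, 255, by = 16), seq(445, 605, by = 16)), y = 0
  )
  cells <- classify_cells(make_cells(dplyr::bind_rows(discs, bridges)))
  det <- detect_aggregates(cells, params_default)
  expect_gte(length(unique(na.omit(det$cluster_id))), 3)
  merged <- merge_connected(det, params_default)
  expect_equal(length(unique(na.omit(merged$cluster_id))), 1)
})

test_that("merging conserves the clustered-cell count and never shrinks clusters", {
  fx <- bridge_fixture(15)
  det <- detect_aggregates(fx$cells, params_default)
  merged <- merge_connected(det, params_default)
  expect_equal(sum(!is.na(merged$cluster_id)), sum(!is.na(det$cluster_id)))
  # each original cluster maps into one merged cluster of >= its size
  for (ci in unique(na.omit(det$cluster_id))) {
    members <- det$cell_id[!is.na(det$cluster_id) & det$cluster_id == ci]
    mlab <- merged$cluster_id[match(members, merged$cell_id)]
    expect_equal(length(unique(mlab)), 1)
    expect_gte(sum(merged$cluster_id == mlab[1], na.rm = TRUE),
               length(members))
  }
})

test_that("polygonized clusters contain their members with positive area", {
  withr::local_seed(55)
  cells <- classify_cells(make_cells(disc_points(400, 500, 500, 120)))
  det <- detect_aggregates(cells, params_default)
  shp <- polygonize_clusters(det, params_default)
  expect_equal(nrow(shp), 1)
  expect_gt(shp$area_um2[1], 0)
  members <- det[!is.na(det$cluster_id), ]
  expect_true(all(points_in_shape(shp$shape[[1]], members$x, members$y)))
})
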