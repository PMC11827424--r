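# Ki-67 fractions, composition fractions, pooling identities, areas and
# section summaries.

test_that("Ki-67 fraction arithmetic and missing sentinels", {
  comp <- tibble::tibble(
    n_B_ki67pos = c(10L, 0L), n_B_ki67neg = c(90L, 0L),
    n_CD8T_ki67pos = c(5L, 1L), n_CD8T_ki67neg = c(5L, 1L),
    n_CD4Tconv_ki67pos = c(0L, 0L), n_CD4Tconv_ki67neg = c(0L, 4L),
    n_CD4Treg_ki67pos = c(0L, 0L), n_CD4Treg_ki67neg = c(0L, 0L),
    n_undefined = c(3L, 7L)
  )
  expect_equal(ki67_fraction(comp, "B"), c(0.10, NA))
  expect_equal(ki67_fraction(comp, "CD8T"), c(0.5, 0.5))
  expect_equal(ki67_fraction(comp, "CD4Treg"), c(NA_real_, NA_real_))
})

test_that("composition fractions exclude undefined and sum to one", {
  comp <- tibble::tibble(
    n_B_ki67pos = 0L, n_B_ki67neg = 50L,
    n_CD8T_ki67pos = 0L, n_CD8T_ki67neg = 50L,
    n_CD4Tconv_ki67pos = 0L, n_CD4Tconv_ki67neg = 0L,
    n_CD4Treg_ki67pos = 0L, n_CD4Treg_ki67neg = 0L,
    n_undefined = 11L, n_lymph = 100L
  )
  fr <- composition_fractions(comp)
  expect_equal(fr$frac_B_ki67neg, 0.5)
  expect_equal(fr$frac_CD8T_ki67neg, 0.5)
  frac_cols <- grep("^frac_", names(fr), value = TRUE)
  expect_equal(sum(unlist(fr[1, frac_cols])), 1, tolerance = 1e-12)
  # undefined count never moves lymphocyte fractions
  comp2 <- comp
  comp2$n_undefined <- 500L
  expect_equal(composition_fractions(comp2)[frac_cols],
               fr[frac_cols])
})

test_that("pooled counts are exact sums and pooled fractions are weighted means", {
  for (seed in 1:20) {
    dt <- simulate_domain_table(
      cohort_config(n_patients = 4, domain_count_range = c(2, 12)),
      seed = seed
    )
    pooled <- pool_domains(dt, by = "section_id")
    manual <- dt |>
      dplyr::group_by(section_id) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(tlsquant:::count_cols()),
                                     sum), .groups = "drop")
    for (cc in tlsquant:::count_cols()) {
      expect_identical(pooled[[cc]], manual[[cc]])
    }
    # pooled fraction == count-weighted mean of per-domain fractions
    fr <- ki67_fractions(dt)
    for (sec in pooled$section_id) {
      rows <- fr[fr$section_id == sec, ]
      nb <- rows$n_B_ki67pos + rows$n_B_ki67neg
      ok <- nb > 0
      if (!any(ok)) next
      weighted <- sum(nb[ok] * rows$ki67_frac_B[ok]) / sum(nb)
      expect_equal(ki67_fraction(pooled[pooled$section_id == sec, ], "B"),
                   weighted, tolerance = 1e-12)
    }
  }
})

test_that("pooling a single domain is the identity", {
  dt <- simulate_domain_table(
    cohort_config(n_patients = 1, domain_count_range = c(1, 1)), seed = 2
  )
  pooled <- pool_domains(dt, by = "section_id")
  for (cc in tlsquant:::count_cols()) {
    expect_identical(as.integer(pooled[[cc]]), as.integer(dt[[cc]]))
  }
})

test_that("tissue occupancy estimates a known covered area", {
  withr::local_seed(90)
  # dense cells covering exactly a 1000x500 rectangle
  x <- runif(20000, 0, 1000)
  y <- runif(20000, 0, 500)
  est <- tlsquant:::tissue_area_from_cells(x, y, tile_um = 50)
  expect_equal(est, 1000 * 500, tolerance = 0.02)
  expect_true(is.na(tlsquant:::tissue_area_from_cells(numeric(), numeric())))
})

test_that("summaries reproduce generator truth on a clean cohort", {
  cfg <- cohort_config(
    n_patients = 3, domain_count_range = c(2, 5), tissue_size_um = 3000,
    background_cell_density = 0, undefined_fraction_in_domain = 0,
    strand_probability = 0, seed = 12
  )
  res <- run_pipeline(run_config(generator = cfg, seed = 12))
  truth <- res$truth$domains
  truth_q <- truth[oracle_qualify(truth$n_total, truth$n_lymph), ]
  summ <- res$summaries
  zero_fill <- function(v) {
    out <- as.numeric(v[summ$section_id])
    out[is.na(out)] <- 0
    out
  }
  truth_counts <- table(truth_q$section_id)
  expect_equal(summ$n_domains, as.integer(zero_fill(truth_counts)))
  # pooled counts equal summed truth counts
  for (cc in tlsquant:::count_cols()) {
    agg <- tapply(truth_q[[cc]], truth_q$section_id, sum)
    expect_equal(summ[[cc]], as.integer(zero_fill(agg)))
  }
  # planted area recovered within the polygonization tolerance
  tls_area_truth <- tapply(truth_q$area_um2, truth_q$section_id, sum)
  has_tls <- summ$n_domains > 0
  expect_equal(summ$total_tls_area[has_tls],
               zero_fill(tls_area_truth)[has_tls],
               tolerance = 0.15)
})

test_that("mean per-domain Ki-67 equals a hand-computed mean", {
  res <- run_pipeline(run_config(generator = small_config(seed = 21),
                                 seed = 21))
  fr <- ki67_fractions(res$domains[res$domains$qualified, ])
  manual <- tapply(fr$ki67_frac_B, fr$section_id,
                   function(v) mean(v, na.rm = TRUE))
  summ <- res$summaries
  expect_equal(summ$mean_per_domain_ki67_frac_B,
               as.numeric(manual[summ$section_id]), ignore_attr = TRUE)
})

test_that("zero qualified domains give a zeroed summary", {
  cells <- classify_cells(make_cells(disc_points(80, 500, 500, 60)))
  det <- merge_connected(detect_aggregates(cells), clustering_params())
  dom <- qualify_domains(
    compose_domains(polygonize_clusters(det, clustering_params()), cells),
    min_cells = 10000
  )
  summ <- summarize_sections(dom, cells)
  expect_equal(summ$n_domains, 0L)
  expect_equal(summ$total_tls_area, 0)
  expect_equal(summ$tls_area_fraction, 0)
  expect_equal(summ$n_total, 0L)
})

test_that("area fractions are scale-free under rigid motion and bounded", {
  res <- run_pipeline(run_config(generator = small_config(seed = 30),
                                 seed = 30))
  summ <- res$summaries
  expect_true(all(summ$tls_area_fraction >= 0 & summ$tls_area_fraction <= 1))
  # translating all coordinates by whole occupancy tiles changes nothing
  cells2 <- res$cells
  cells2$x <- cells2$x + 500
  cells2$y <- cells2$y + 1000
  det2 <- merge_connected(detect_aggregates(cells2), clustering_params())
  dom2 <- qualify_domains(
    compose_domains(polygonize_clusters(det2, clustering_params()), cells2)
  )
  summ2 <- summarize_sections(dom2, cells2)
  expect_equal(summ2$tls_area_fraction[order(summ2$section_id)],
               summ$tls_area_fraction[order(summ$section_id)],
               tolerance = 1e-9)
})

test_that("dropping a domain never increases any summary quantity", {
  res <- run_pipeline(run_config(generator = small_config(seed = 33),
                                 seed = 33))
  dom <- res$domains
  qual_idx <- which(dom$qualified)
  drop_one <- dom[-qual_idx[1], ]
  s_all <- summarize_sections(dom, res$cells)
  s_less <- summarize_sections(drop_one, res$cells)
  sec <- dom$section_id[qual_idx[1]]
  a <- s_all[s_all$section_id == sec, ]
  b <- s_less[s_less$section_id == sec, ]
  expect_lt(b$n_domains, a$n_domains)
  expect_lte(b$total_tls_area, a$total_tls_area)
  expect_lte(b$n_total, a$n_total)
})
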