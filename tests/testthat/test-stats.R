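# Spearman machinery, correlation suites, rankings and concordance.

test_that("rho equals Pearson on average ranks and matches stats::cor", {
  withr::local_seed(71)
  for (rep in 1:10) {
    n <- sample(10:60, 1)
    x <- runif(n)
    y <- x + rnorm(n, 0, 0.5)
    if (rep %% 2 == 0) x[1:3] <- x[4] # inject ties
    got <- spearman_cor(x, y)
    expect_equal(got$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
    expect_equal(got$rho, cor(rank(x), rank(y)), tolerance = 1e-12)
  }
})

test_that("perfect concordance and discordance hit +/-1", {
  x <- c(3, 1, 4, 1.5, 9)
  expect_equal(spearman_cor(x, x)$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)
})

test_that("rho is invariant under strictly monotone transforms", {
  withr::local_seed(72)
  x <- runif(40, 0.01, 1)
  y <- runif(40, 0.01, 1)
  base <- spearman_cor(x, y)
  expect_equal(spearman_cor(log10(x), y)$rho, base$rho)
  expect_equal(spearman_cor(log10(x), log10(y))$rho, base$rho)
  expect_equal(spearman_cor(x^3, exp(y))$rho, base$rho)
})

test_that("small-n p-values match the exact Spearman distribution", {
  withr::local_seed(73)
  for (n in c(5, 6, 7, 8)) {
    x <- runif(n)
    y <- runif(n)
    got <- spearman_cor(x, y)
    ref <- suppressWarnings(cor.test(x, y, method = "spearman",
                                     exact = TRUE))
    expect_equal(got$method, "exact permutation")
    expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("the t approximation tracks cor.test for n >= 10", {
  withr::local_seed(74)
  x <- runif(50)
  y <- x + rnorm(50, 0, 0.8)
  got <- spearman_cor(x, y)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(got$p_value, ref$p.value, tolerance = 0.02)
})

test_that("degenerate inputs give sentinels, not errors", {
  expect_true(spearman_cor(c(1, 2), c(3, 4))$insufficient)
  con <- spearman_cor(rep(1, 10), runif(10))
  expect_true(con$insufficient)
  expect_true(is.na(con$rho))
  # missing pairs are dropped and counted
  got <- spearman_cor(c(1, 2, NA, 4, 5), c(5, 4, 3, NA, 1))
  expect_equal(got$n_points, 3)
})

test_that("the correlation filter keeps exactly the robust domains", {
  dom <- tibble::tibble(
    section_id = "s", cluster_id = 1:3, qualified = TRUE,
    n_lymph = c(49L, 50L, 500L), n_total = c(60L, 60L, 600L)
  )
  kept <- filter_domains_for_correlation(dom)
  expect_equal(kept$n_lymph, c(50L, 500L))
})

test_that("shared latent activation drives positive correlations everywhere", {
  dt <- simulate_domain_table(
    cohort_config(n_patients = 10, domain_count_range = c(6, 12)), seed = 81
  )
  suite <- ki67_correlation_suite(filter_domains_for_correlation(dt),
                                  level = "domain")
  expect_equal(nrow(suite), 6) # all pairs among the four subsets
  expect_true(all(suite$rho > 0))
  expect_true(all(suite$p_value < 0.001))
  g <- glance(suite)
  expect_equal(g$n_tests, 6)
})

test_that("section-level pooling strengthens the correlations", {
  rho_gain <- replicate(10, {
    dt <- simulate_domain_table(
      cohort_config(n_patients = 12, domain_count_range = c(5, 15),
                    latent_activation_sd = 1),
      seed = sample.int(1e6, 1)
    )
    dom_level <- ki67_correlation_suite(
      filter_domains_for_correlation(dt), level = "domain"
    )
    sec_level <- ki67_correlation_suite(
      pool_domains(dt, by = "section_id"), level = "section"
    )
    mean(sec_level$rho) - mean(dom_level$rho)
  })
  expect_gt(mean(rho_gain >= 0), 0.7)
})

test_that("Treg presence is uncorrelated under the null and detected when planted", {
  # independence fixture: no activation spread, so Treg presence varies
  # only with composition while Ki-67 varies only binomially
  dt0 <- simulate_domain_table(
    cohort_config(n_patients = 14, domain_count_range = c(8, 16),
                  suppression_coeff = 0, latent_activation_sd = 0,
                  gc_probability = 0), seed = 91
  )
  null_res <- treg_presence_analysis(filter_domains_for_correlation(dt0))
  expect_equal(nrow(null_res), 3)
  expect_true(all(abs(null_res$rho) < 0.35))
  # planted suppression flips the sign clearly
  dt1 <- simulate_domain_table(
    cohort_config(n_patients = 14, domain_count_range = c(8, 16),
                  suppression_coeff = 15, latent_activation_sd = 0.3),
    seed = 91
  )
  sup_res <- treg_presence_analysis(filter_domains_for_correlation(dt1))
  expect_true(all(sup_res$rho < 0))
})

test_that("ranking methods agree on homogeneous patients and diverge as designed", {
  # identical compositions within each patient: methods coincide
  dom <- tibble::tibble(
    section_id = rep(c("a_s1", "b_s1"), each = 3),
    patient_id = rep(c("a", "b"), each = 3),
    qualified = TRUE,
    n_B_ki67pos = rep(c(20L, 5L), each = 3),
    n_B_ki67neg = rep(c(80L, 95L), each = 3),
    n_CD8T_ki67pos = 0L, n_CD8T_ki67neg = 10L,
    n_CD4Tconv_ki67pos = 0L, n_CD4Tconv_ki67neg = 10L,
    n_CD4Treg_ki67pos = 0L, n_CD4Treg_ki67neg = 10L,
    n_undefined = 0L, n_total = 130L, n_lymph = 130L
  )
  r1 <- rank_patients(dom, "per_domain_mean")
  r2 <- rank_patients(dom, "pooled")
  expect_equal(r1$patient_id, r2$patient_id)
  expect_equal(r1$measure, r2$measure)

  # the worked divergence example: fractions 0.1 (n=1000) and 0.9 (n=10)
  dom2 <- tibble::tibble(
    section_id = "p_s1", patient_id = "p", qualified = TRUE,
    n_B_ki67pos = c(100L, 9L), n_B_ki67neg = c(900L, 1L),
    n_CD8T_ki67pos = 0L, n_CD8T_ki67neg = 0L,
    n_CD4Tconv_ki67pos = 0L, n_CD4Tconv_ki67neg = 0L,
    n_CD4Treg_ki67pos = 0L, n_CD4Treg_ki67neg = 0L,
    n_undefined = 0L, n_total = c(1000L, 10L), n_lymph = c(1000L, 10L)
  )
  expect_equal(rank_patients(dom2, "per_domain_mean")$measure, 0.5)
  expect_equal(rank_patients(dom2, "pooled")$measure, 109 / 1010,
               tolerance = 1e-12)
})

test_that("ranking concordance report behaves on identity and reversal", {
  r <- tibble::tibble(rank = 1:5, patient_id = letters[1:5],
                      measure = seq(0.9, 0.1, length.out = 5),
                      method = "per_domain_mean")
  class(r) <- c("tls_ranking", class(tibble::tibble()))
  same <- compare_rankings(r, r, k = 3)
  expect_equal(same$rank_rho, 1)
  expect_equal(same$top_k_overlap, 3)
  rev <- r
  rev$patient_id <- rev(r$patient_id)
  expect_equal(compare_rankings(r, rev, k = 5)$rank_rho, -1)
  # mismatched patient sets are a hard error naming the difference
  other <- r
  other$patient_id <- letters[3:7]
  expect_error(compare_rankings(r, other), "only in a")
})

test_that("correlation results are invariant to domain order", {
  dt <- simulate_domain_table(
    cohort_config(n_patients = 6, domain_count_range = c(4, 8)), seed = 17
  )
  s1 <- ki67_correlation_suite(dt, "domain")
  s2 <- ki67_correlation_suite(dt[rev(seq_len(nrow(dt))), ], "domain")
  expect_equal(s1$rho, s2$rho)
  expect_equal(s1$p_value, s2$p_value)
})
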