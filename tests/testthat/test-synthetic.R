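test_that("cellmap generator honors theta endpoints and binomial sampling", {
  cfg0 <- histology_config(theta = 0)
  expect_equal(generate_cellmap(cfg0, 1)$true_ki67_fraction, 0)
  cfg1 <- histology_config(theta = 1)
  expect_equal(generate_cellmap(cfg1, 1)$true_ki67_fraction, 1)

  # ~2000 tumor cells at theta = 0.10: realized fraction inside the exact
  # binomial 99% band around 0.10
  cfg <- histology_config(theta = 0.10, tumor_density = 3200,
                          width = 800, height = 800)
  m <- generate_cellmap(cfg, 7)
  n_tum <- sum(m$nuclei$cell_class == "invasive_tumor")
  expect_gt(n_tum, 1500)
  k <- sum(m$nuclei$ki67_positive[m$nuclei$cell_class == "invasive_tumor"])
  expect_gte(k, qbinom(0.005, n_tum, 0.10))
  expect_lte(k, qbinom(0.995, n_tum, 0.10))
})

test_that("generators are bit-reproducible for a fixed seed", {
  cfg <- histology_config()
  expect_identical(generate_cellmap(cfg, 5), generate_cellmap(cfg, 5))
  m <- generate_cellmap(histology_config(width = 120, height = 120), 5)
  expect_identical(render_field(m), render_field(m))
  cc <- cohort_config(n_cases = 50)
  expect_identical(generate_cohort(cc, 9), generate_cohort(cc, 9))
  ps1 <- generate_paired_scores(c(0.1, 0.3), rater_model(), rater_model(), 4)
  ps2 <- generate_paired_scores(c(0.1, 0.3), rater_model(), rater_model(), 4)
  expect_identical(ps1, ps2)
})

test_that("empty tumor compartment is flagged, never silent", {
  m <- generate_cellmap(histology_config(tumor_density = 0), 3)
  expect_true(m$degenerate)
  expect_true(is.na(m$true_ki67_fraction))
})

test_that("mean true fraction is unbiased over replicate maps", {
  # scaled from the 1000-replicate invariant to 300 for runtime; >=500
  # tumor cells per map
  cfg <- histology_config(theta = 0.10, tumor_density = 3300)
  fr <- vapply(1:300, function(s)
    generate_cellmap(cfg, s)$true_ki67_fraction, numeric(1))
  se <- sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - 0.10), 3 * se)
})

test_that("cohort strata respect configured hazards", {
  # fixed follow-up, no dropout: exact expected event probabilities
  cc <- cohort_config(n_cases = 1500, censoring_rate = 0,
                      fu_min = 60, fu_max = 60 + 1e-9)
  co <- classify_pepi(generate_cohort(cc, 13))
  expect_equal(sum(co$relapse_event[co$modified_pepi0]), 0)
  for (grp in list(list(sel = !co$modified_pepi0 & co$ki67_month1 > 10,
                        h = 0.008),
                   list(sel = !co$modified_pepi0 & co$ki67_month1 <= 10,
                        h = 0.002))) {
    n <- sum(grp$sel); k <- sum(co$relapse_event[grp$sel])
    p <- 1 - exp(-grp$h * 60)
    expect_gte(k, qbinom(0.005, n, p))
    expect_lte(k, qbinom(0.995, n, p))
  }
})

test_that("cohort invariants: PEPI logic, ER, censoring extremes", {
  co <- classify_pepi(generate_cohort(cohort_config(n_cases = 400), 2))
  expect_true(all(co$ki67_baseline >= 0 & co$ki67_baseline <= 100))
  expect_true(all(co$rfs_months >= 0))
  expect_true(all(!co$pepi0 | co$modified_pepi0, na.rm = TRUE))
  expect_true(all(co$er_allred[co$modified_pepi0] >= 3))
  co_cens <- generate_cohort(cohort_config(n_cases = 100,
                                           censoring_rate = 1), 2)
  expect_false(any(co_cens$relapse_event))
  expect_error(generate_cohort(cohort_config(n_cases = 0), 1),
               class = "ki67cta_config_error")
})

test_that("paired rater scores: exact endpoints and large-count limit", {
  ps0 <- generate_paired_scores(rep(0, 20), rater_model(), rater_model(), 3)
  expect_true(all(ps0$score_a == 0) && all(ps0$score_b == 0))
  ps <- generate_paired_scores(rep(0.23, 5),
                               rater_model(sigma_field = 0, 1e5),
                               rater_model(sigma_field = 0, 1e5), 3)
  expect_true(all(abs(ps$score_a - 23) < 0.5))
  expect_true(all(abs(ps$score_b - 23) < 0.5))
})

test_that("default rater calibration lands in the Spearman band", {
  # mean over seeds: single-seed Spearman at n=60 has sampling SD ~0.04
  sp <- vapply(1:25, function(s) {
    co <- generate_cohort(cohort_config(n_cases = 60), 500 + s)
    ps <- generate_paired_scores(co$theta_baseline, rater_model(),
                                 rater_model(), s)
    correlations(ps)$spearman
  }, numeric(1))
  expect_gte(mean(sp), 0.85)
  expect_lte(mean(sp), 0.95)
})

test_that("child_seed separates component streams deterministically", {
  expect_identical(child_seed(1, "a"), child_seed(1, "a"))
  expect_false(child_seed(1, "a") == child_seed(1, "b"))
  expect_false(child_seed(1, "a", 1) == child_seed(1, "a", 2))
  s <- vapply(1:1000, function(i) child_seed(42, "x", i), integer(1))
  expect_true(all(s >= 1 & s < 2^31 - 1))
})

test_that("cellmap JSON round trip preserves the map", {
  m <- generate_cellmap(histology_config(width = 150, height = 150), 8)
  f <- tempfile(fileext = ".json")
  write_cellmap_json(m, f)
  m2 <- read_cellmap_json(f)
  expect_equal(m2$true_ki67_fraction, m$true_ki67_fraction)
  expect_equal(nrow(m2$nuclei), nrow(m$nuclei))
  expect_equal(m2$nuclei$x, m$nuclei$x, tolerance = 1e-6)
})
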