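test_that("contingency cross-classification matches the brute-force oracle", {
  p1 <- data.frame(score_a = c(1, 5, 5, 1), score_b = c(1, 5, 5, 1))
  t1 <- contingency(p1, 2.7)
  expect_equal(c(t1$a, t1$b, t1$c, t1$d), c(2, 0, 0, 2))

  t2 <- contingency(data.frame(score_a = 3.0, score_b = 2.0), 2.7)
  expect_equal(t2$b, 1L)  # A above, B at/below

  set.seed(8)
  pr <- data.frame(score_a = runif(100, 0, 30), score_b = runif(100, 0, 30))
  for (cut in c(2.7, 10)) {
    got <- contingency(pr, cut)
    exp <- oracle_contingency(pr, cut)
    expect_equal(c(got$a, got$b, got$c, got$d), unname(exp))
  }
  # missing scores excluded with count logged
  pr$score_a[3] <- NA
  expect_equal(contingency(pr, 10)$n_missing, 1L)
  expect_error(contingency(pr[0, ], 10), class = "ki67cta_config_error")
})

test_that("Clopper-Pearson matches its printed values and the binom.test oracle", {
  expect_equal(unname(round(clopper_pearson(9, 12), 3)), c(0.428, 0.945))
  expect_equal(unname(clopper_pearson(12, 12))[2], 1)
  expect_equal(unname(clopper_pearson(0, 12))[1], 0)
  # computed upper for 14/16 is 0.98449 (prints 98.4; a published 98.5 is a
  # 0.1-point rounding artifact)
  expect_equal(unname(round(clopper_pearson(14, 16), 4)), c(0.6165, 0.9845))

  for (n in c(12, 16, 47)) for (k in c(0, 1, floor(n / 2), n)) {
    got <- clopper_pearson(k, n)
    orc <- stats::binom.test(k, n)$conf.int
    expect_equal(unname(got), as.numeric(orc), tolerance = 1e-10)
  }
  expect_error(clopper_pearson(5, 4), class = "ki67cta_config_error")
})

test_that("PPA/NPA reproduce the validation and training tables", {
  t1 <- contingency_2x2(a = 13, b = 0, c = 3, d = 9)
  pn <- ppa_npa(t1)
  expect_equal(pn$ppa$estimate, 1)                      # 13/13
  expect_equal(pn$npa$estimate, 0.75)                   # 9/12
  expect_equal(round(c(pn$npa$lower, pn$npa$upper), 3), c(0.428, 0.945))

  t2 <- contingency_2x2(a = 29, b = 1, c = 3, d = 23)
  pn2 <- ppa_npa(t2)
  expect_equal(round(100 * pn2$ppa$estimate, 1), 96.7)
  expect_equal(round(100 * pn2$npa$estimate, 1), 88.5)
  expect_equal(round(100 * c(pn2$ppa$lower, pn2$ppa$upper), 1), c(82.8, 99.9))
  # computed lower bound is 69.85 -> 69.8; a published 69.9 is a 0.1-point
  # rounding artifact (see also 14/16)
  expect_equal(round(100 * c(pn2$npa$lower, pn2$npa$upper), 1), c(69.8, 97.6))

  perfect <- contingency_2x2(a = 5, b = 0, c = 0, d = 5)
  pp <- ppa_npa(perfect)
  expect_equal(c(pp$ppa$estimate, pp$npa$estimate), c(1, 1))
  # empty positive margin -> PPA undefined, NPA still reported
  onesided <- ppa_npa(contingency_2x2(a = 0, b = 0, c = 1, d = 9))
  expect_true(is.na(onesided$ppa$estimate))
  expect_equal(onesided$npa$estimate, 0.9)
})

test_that("Cohen's kappa reproduces printed values and degenerate cases", {
  expect_equal(round(cohen_kappa(contingency_2x2(13, 0, 3, 9))$kappa, 4),
               0.7573)
  expect_equal(round(cohen_kappa(contingency_2x2(14, 2, 2, 16))$kappa, 2),
               0.76)
  expect_equal(cohen_kappa(contingency_2x2(7, 0, 0, 3))$kappa, 1)
  # observed agreement equals chance agreement -> kappa 0
  expect_equal(cohen_kappa(contingency_2x2(1, 1, 1, 1))$kappa, 0)
  # degenerate marginals -> undefined
  expect_true(is.na(cohen_kappa(contingency_2x2(10, 0, 0, 0))$kappa))
})

test_that("kappa is invariant under transposing the table", {
  set.seed(5)
  for (i in 1:20) {
    cts <- rmultinom(1, 60, runif(4, 0.05, 1))
    k1 <- cohen_kappa(contingency_2x2(cts[1], cts[2], cts[3], cts[4]))$kappa
    k2 <- cohen_kappa(contingency_2x2(cts[1], cts[3], cts[2], cts[4]))$kappa
    expect_equal(k1, k2, tolerance = 1e-12)
  }
})

test_that("correlations match closed forms and the manual rank oracle", {
  p_id <- data.frame(score_a = c(1, 5, 9, 20), score_b = c(1, 5, 9, 20))
  expect_equal(unlist(correlations(p_id)[c("pearson", "spearman")]),
               c(pearson = 1, spearman = 1))
  p_rev <- data.frame(score_a = c(1, 5, 9), score_b = 100 - c(1, 5, 9))
  expect_equal(unlist(correlations(p_rev)[c("pearson", "spearman")]),
               c(pearson = -1, spearman = -1))

  set.seed(3)
  pr <- data.frame(score_a = round(runif(30, 0, 40), 1),
                   score_b = round(runif(30, 0, 40), 1))
  got <- correlations(pr)
  ra <- rank(pr$score_a); rb <- rank(pr$score_b)   # mid-ranks for ties
  sp_manual <- sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  expect_equal(got$spearman, sp_manual, tolerance = 1e-12)
  expect_warning(correlations(data.frame(score_a = c(1, 1, 1),
                                         score_b = c(1, 2, 3))))
})

test_that("Bland-Altman bias, limits, and unbiased-rater simulation", {
  same <- data.frame(score_a = c(3, 8, 12), score_b = c(3, 8, 12))
  ba <- bland_altman(same)
  expect_equal(c(ba$bias, ba$sd, ba$lower, ba$upper), c(0, 0, 0, 0))

  shift <- data.frame(score_a = c(3, 8, 12), score_b = c(3, 8, 12) + 5)
  bs <- bland_altman(shift)
  expect_equal(bs$bias, -5)     # bias defined as mean(A - B)
  expect_equal(bs$sd, 0)

  co <- generate_cohort(cohort_config(n_cases = 500), 17)
  ps <- generate_paired_scores(co$theta_baseline, rater_model(),
                               rater_model(), 18)
  bu <- bland_altman(ps)
  se <- bu$sd / sqrt(nrow(ps))
  expect_lt(abs(bu$bias), 3 * se)
  expect_error(bland_altman(same[1, ]), class = "ki67cta_config_error")
})
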