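test_that("chi-square association test reproduces published cohort rows", {
  # sex (female/male x AA/No-AA) and multifocality from a 90-patient cohort
  sex <- matrix(c(21, 6, 34, 29), 2)
  expect_equal(round(chi_square_test(sex)$p_value, 3), 0.034)
  multifocality <- matrix(c(19, 8, 59, 4), 2)
  expect_equal(round(chi_square_test(multifocality)$p_value, 3), 0.003)
  # perfectly balanced table: no association
  res <- chi_square_test(matrix(10, 2, 2))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$df, 1)
})

test_that("chi-square test is permutation invariant and validates marginals", {
  m <- matrix(c(8, 4, 19, 59), 2)
  base <- chi_square_test(m)
  expect_equal(chi_square_test(m[2:1, ]), base)
  expect_equal(chi_square_test(m[, 2:1]), base)
  expect_equal(chi_square_test(t(m)), base)
  expect_error(chi_square_test(matrix(c(0, 0, 5, 3), 2)), "marginal")
  expect_error(chi_square_test(matrix(1:3, 1)), "2 x 2")
})

test_that("KM estimator handles censoring-only and tiny closed forms", {
  allc <- tibble::tibble(time = c(3, 7, 9), event = FALSE)
  km <- km_estimate(allc)
  expect_true(all(km$survival == 1))

  two <- tibble::tibble(time = c(1, 2), event = TRUE)
  km2 <- km_estimate(two)
  expect_equal(km2$survival[km2$time == 1], 0.5)
  expect_equal(km2$survival[km2$time == 2], 0)
  expect_equal(km2$survival[km2$time == 0], 1)

  expect_error(km_estimate(tibble::tibble(time = 0, event = TRUE)), "positive")
})

test_that("KM matches a hand-computed product-limit table with censoring", {
  rec <- tibble::tibble(
    time = 1:10,
    event = c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE)
  )
  km <- km_estimate(rec)
  # hand-computed: S drops at event times 1,3,4,6,8,10 by (n-1)/n of those at risk
  hand <- tibble::tibble(time = c(1, 3, 4, 6, 8, 10),
                         survival = c(0.9, 0.7875, 0.675, 0.54, 0.36, 0))
  got <- km[km$time %in% hand$time, c("time", "survival")]
  expect_equal(got$survival, hand$survival, tolerance = 1e-12)
  expect_true(all(diff(km$survival) <= 0))
})

test_that("without censoring the KM estimate is the empirical survival", {
  set.seed(42)
  t <- sort(rexp(40, 0.1))
  km <- km_estimate(tibble::tibble(time = t, event = TRUE))
  emp <- 1 - seq_along(t) / 40
  expect_equal(km$survival[match(t, km$time)], emp)
})

test_that("log-rank test degenerates to p = 1 on identical groups", {
  g <- tibble::tibble(time = c(1, 2, 3, 4), event = c(TRUE, TRUE, FALSE, TRUE))
  rec <- dplyr::bind_rows(dplyr::mutate(g, group = "A"),
                          dplyr::mutate(g, group = "B"))
  res <- logrank_test(rec)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1, tolerance = 1e-12)
})

test_that("log-rank p is invariant to a common time rescaling", {
  rec <- simulate_cohort(30, hazard_ratio = 2, censor_rate = 0.3, seed = 7)
  p1 <- logrank_test(rec)$p_value
  p2 <- logrank_test(dplyr::mutate(rec, time = time * 7.3))$p_value
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("log-rank input validation is informative", {
  rec <- simulate_cohort(10, seed = 1)
  expect_error(logrank_test(dplyr::select(rec, -"group")), "group")
  expect_error(logrank_test(dplyr::filter(rec, group == "AA Sig")), "exactly 2")
  nul <- tibble::tibble(time = c(1, 2), event = FALSE, group = c("A", "B"))
  expect_error(logrank_test(nul), "one event")
})

test_that("table one renders counts with within-subtype percentages", {
  # herb intake counts from a 27 vs 63 subtype split
  counts <- matrix(c(11, 16, 52, 11), 2,
                   dimnames = list(c("Absent", "Present"),
                                   c("AA Sig", "No-AA Sig")))
  cohort <- cohort_from_counts(counts, "aa_intake")
  tab <- build_table_one(cohort)
  present <- tab[tab$level == "Present", ]
  expect_equal(present[["AA Sig"]], "16(59.3)")
  expect_equal(present[["No-AA Sig"]], "11(17.5)")
  expect_equal(tab$p_value[1], "<0.001")
  expect_equal(tab$overall[tab$level == "Absent"], "63(70.0)")
})

test_that("table one handles single-level and single-subtype degenerate cases", {
  single_level <- tibble::tibble(subtype = c("AA Sig", "No-AA Sig"),
                                 stage = "T1")
  tab <- build_table_one(single_level)
  expect_equal(tab$p_value, "")

  single_subtype <- tibble::tibble(subtype = "AA Sig",
                                   sex = c("Female", "Female", "Male"))
  tab2 <- build_table_one(single_subtype)
  expect_equal(tab2[["AA Sig"]], c("2(66.7)", "1(33.3)"))
  expect_equal(tab2$p_value, c("", ""))
})

test_that("Kruskal-Wallis is available for ordered covariates", {
  counts <- matrix(c(6, 9, 12, 32, 29, 2), 3,
                   dimnames = list(c("1~2", "3", "4~5"),
                                   c("AA Sig", "No-AA Sig")))
  cohort <- cohort_from_counts(counts, "ckd")
  tab <- build_table_one(cohort, kruskal = "ckd")
  p <- as.numeric(sub("<", "", tab$p_value[1]))
  ref <- stats::kruskal.test(
    as.integer(factor(cohort$ckd)), factor(cohort$subtype))$p.value
  expect_equal(p, round(max(ref, 0.001), 3), tolerance = 1e-6)
})
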