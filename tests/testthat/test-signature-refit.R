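test_that("signature matrices are validated and reordered on load", {
  sig <- synthetic_signatures()
  m <- aasig:::signature_probs(sig)
  expect_equal(dim(m), c(96, 30))
  expect_true(all(abs(colSums(m) - 1) < 1e-6))
  expect_true(all(m >= 0))
  # the matrix is deterministic across calls
  expect_identical(sig, synthetic_signatures())

  path <- withr::local_tempfile(fileext = ".tsv")
  shuffled <- sig[sample(96), ]
  write_signature_matrix(sig, path)
  readr::write_tsv(shuffled, path)
  expect_identical(read_signature_matrix(path)$context, sbs96_contexts())

  bad <- sig
  bad[["Signature 3"]] <- bad[["Signature 3"]] * 2
  expect_error(aasig:::validate_signatures(bad), "Signature 3")
})

test_that("the active-set NNLS matches an independent solver", {
  skip_if_not_installed("pracma")
  set.seed(71)
  for (i in 1:25) {
    A <- matrix(runif(96 * 30), 96)
    b <- runif(96) * sample(c(1, 1000), 1)
    expect_lt(max(abs(nnls_fit(A, b) - pracma::lsqnonneg(A, b)$x)), 1e-7)
  }
  # duplicated columns still terminate, with the residual of the deduped problem
  A2 <- cbind(A[, 1], A[, 1], A[, 2])
  x <- nnls_fit(A2, b)
  expect_true(all(is.finite(x)) && all(x >= 0))
  ref <- pracma::lsqnonneg(A2[, c(1, 3)], b)$x
  expect_equal(sqrt(sum((A2 %*% x - b)^2)),
               sqrt(sum((A2[, c(1, 3)] %*% ref - b)^2)), tolerance = 1e-8)
})

test_that("an exactly representable catalog is attributed to its signature", {
  sig <- synthetic_signatures()
  probs <- aasig:::signature_probs(sig)
  cat96 <- tibble::tibble(sample_id = "pure", context = sbs96_contexts(),
                          count = 1000 * probs[, "Signature 22"])
  e <- tidy(fit_exposures(cat96, sig))
  expect_equal(e$exposure[e$signature == "Signature 22"], 1000,
               tolerance = 1e-6)
  expect_lt(sum(e$exposure[e$signature != "Signature 22"]), 1000 * 1e-6)
})

test_that("mixture weights are recovered from multinomial catalogs", {
  sig <- synthetic_signatures()
  cat96 <- simulate_catalog(20000, c("Signature 22" = 0.6, "Signature 1" = 0.4),
                            sig, seed = 81)
  aa <- aa_proportion(merge_exposures(fit_exposures(cat96, sig)))
  expect_lt(abs(aa$aa_proportion - 0.6), 0.03)
})

test_that("a catalog orthogonal to a signature's support gets zero exposure", {
  sig <- disjoint_signatures()
  cat96 <- catalog_from_counts(setNames(rep(10L, 16),
                                        grep("C>A", sbs96_contexts(),
                                             fixed = TRUE, value = TRUE)))
  e <- tidy(fit_exposures(cat96, sig))
  expect_equal(e$exposure[e$signature == "sigB"], 0)
  expect_equal(e$exposure[e$signature == "sigA"], 160)
})

test_that("refitting is homogeneous of degree one in the catalog", {
  sig <- synthetic_signatures()
  cat96 <- simulate_catalog(3000, c("Signature 22" = 0.3, "Signature 4" = 0.7),
                            sig, seed = 91)
  scaled <- dplyr::mutate(cat96, count = count * 3L)
  e1 <- tidy(fit_exposures(cat96, sig))$exposure
  e3 <- tidy(fit_exposures(scaled, sig))$exposure
  expect_equal(e3, 3 * e1, tolerance = 1e-8)
})

test_that("noiseless mixtures of three signatures reconstruct nearly exactly", {
  sig <- synthetic_signatures()
  probs <- aasig:::signature_probs(sig)
  mix <- probs[, c("Signature 22", "Signature 1", "Signature 5")] %*%
    c(0.5, 0.3, 0.2)
  cat96 <- tibble::tibble(sample_id = "mix", context = sbs96_contexts(),
                          count = round(20000 * drop(mix)))
  expect_gte(glance(fit_exposures(cat96, sig))$reconstruction_cosine, 0.999)
})

test_that("all-zero catalogs error by default and can return zero exposures", {
  sig <- synthetic_signatures()
  zero <- catalog_from_counts(integer(0))
  expect_error(fit_exposures(zero, sig), "all-zero")
  e <- tidy(fit_exposures(zero, sig, zero_action = "zero"))
  expect_true(all(e$exposure == 0))
})

test_that("etiology merging is additive and conserves totals", {
  fit <- structure(list(
    exposures = tibble::tibble(sample_id = "s",
                               signature = c("Signature 22", "Signature 1",
                                             "Signature 5"),
                               exposure = c(600, 250, 150)),
    stats = tibble::tibble(sample_id = "s"),
    signature_names = c("Signature 22", "Signature 1", "Signature 5"),
    merged = FALSE), class = "signature_fit")

  map3 <- tibble::tibble(signature = c("Signature 22", "Signature 1",
                                       "Signature 5"),
                         group = c("AA", "clock", "clock"))
  merged <- tidy(merge_exposures(fit, map3))
  expect_equal(merged$exposure[merged$signature == "AA"], 600)
  expect_equal(merged$exposure[merged$signature == "clock"], 400)

  ident <- tibble::tibble(signature = fit$signature_names,
                          group = fit$signature_names)
  expect_equal(sort(tidy(merge_exposures(fit, ident))$exposure),
               sort(fit$exposures$exposure))

  one <- tibble::tibble(signature = fit$signature_names, group = "all")
  expect_equal(tidy(merge_exposures(fit, one))$exposure, 1000)

  expect_error(merge_exposures(fit, map3[1:2, ]), "Signature 5")
})

test_that("merging a full fit conserves the fitted total exactly", {
  sig <- synthetic_signatures()
  cat96 <- simulate_catalog(8000, c("Signature 22" = 0.4, "Signature 2" = 0.6),
                            sig, seed = 101)
  fit <- fit_exposures(cat96, sig)
  merged <- merge_exposures(fit)
  expect_equal(sum(tidy(merged)$exposure), sum(tidy(fit)$exposure))
  expect_equal(sort(unique(tidy(merged)$signature)),
               sort(unique(default_merge_map()$group)))
})

test_that("AA proportion is the AA share of the fitted total", {
  ex <- tibble::tibble(sample_id = "s", signature = c("AA", "clock"),
                       exposure = c(600, 400))
  expect_equal(aa_proportion(ex)$aa_proportion, 0.6)
  ex0 <- tibble::tibble(sample_id = "s", signature = c("AA", "clock"),
                        exposure = c(0, 400))
  expect_equal(aa_proportion(ex0)$aa_proportion, 0)
  none <- tibble::tibble(sample_id = "s", signature = "clock", exposure = 1)
  expect_error(aa_proportion(none), "AA")
  zero <- tibble::tibble(sample_id = "s", signature = c("AA", "clock"),
                         exposure = c(0, 0))
  expect_error(aa_proportion(zero), "zero total")

  sig <- synthetic_signatures()
  pure <- simulate_catalog(20000, c("Signature 22" = 1), sig, seed = 111)
  aa <- aa_proportion(merge_exposures(fit_exposures(pure, sig)))
  expect_gt(aa$aa_proportion, 0.97)
})
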