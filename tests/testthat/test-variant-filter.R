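test_that("callset intersection keeps common keys with set_a's annotations", {
  a <- variant_records("chr1", 100L, "A", "T", mapq_median_varreads = 55)
  b <- variant_records(c("chr1", "chr2"), c(100L, 5L), c("A", "C"),
                       c("T", "G"), mapq_median_varreads = 48)
  out <- intersect_callsets(a, b)
  expect_equal(nrow(out), 1)
  expect_equal(out$mapq_median_varreads, 55)  # features come from set_a

  expect_equal(nrow(intersect_callsets(a[0, ], b)), 0)

  five <- variant_records("chr1", (1:5) * 10L, "C", "T")
  expect_equal(intersect_callsets(five, five), five)
})

test_that("duplicate keys within one callset are an error naming the key", {
  dup <- dplyr::bind_rows(variant_records("chr1", 100L, "A", "T"),
                          variant_records("chr1", 100L, "A", "T"))
  ok <- variant_records("chr1", 100L, "A", "T")
  expect_error(intersect_callsets(dup, ok), "chr1:100:A:T")
  expect_error(intersect_callsets(ok, dup), "chr1:100:A:T")
})

# single-violation records per rule, each drawn AT the quoted boundary's
# removing side, paired with the value just on the retaining side
rule_cases <- list(
  rule1 = list(field = "dist_to_end_median", removed = 9.9, retained = 10),
  rule2 = list(field = "dist_to_end_mad", removed = 2.9, retained = 3),
  rule3 = list(field = "frac_low_mapq", removed = 0.11, retained = 0.10),
  rule4 = list(field = "mapq_median_varreads", removed = 39.5, retained = 40),
  rule5 = list(field = "baseq_median_varreads", removed = 19.5, retained = 20),
  rule7 = list(field = "repeat_len_adjacent", removed = 12, retained = 11),
  rule8 = list(field = "nearby_variant_max", removed = 3, retained = 2)
)

test_that("each read-level rule removes exactly at the quoted inequality", {
  for (rule in names(rule_cases)) {
    case <- rule_cases[[rule]]
    for (side in c("removed", "retained")) {
      v <- variant_records("chr1", 100L, "C", "T")
      v[[case$field]] <- case[[side]]
      rep <- apply_read_level_filters(v)
      if (side == "removed") {
        expect_equal(nrow(rep$retained), 0, info = paste(rule, side))
        expect_equal(rep$rejected$rule, rule, info = rule)
      } else {
        expect_equal(nrow(rep$retained), 1, info = paste(rule, side))
      }
    }
  }
})

test_that("strand-bias rule 6 honours the all-reads exception clause", {
  v <- function(sfv, sfa) variant_records("chr1", 100L, "C", "T",
                                          strand_frac_varreads = sfv,
                                          strand_frac_allreads = sfa)
  # var-read bias alone is not enough: all reads share the imbalance
  expect_equal(nrow(apply_read_level_filters(v(0.01, 0.15))$retained), 1)
  # balanced coverage but biased variant reads -> removed
  r <- apply_read_level_filters(v(0.01, 0.25))
  expect_equal(r$rejected$rule, "rule6")
  # the 0.2 cutoff on all reads is inclusive
  expect_equal(nrow(apply_read_level_filters(v(0.01, 0.2))$retained), 0)
  # variant-read fraction at the cutoff is retained (strict <)
  expect_equal(nrow(apply_read_level_filters(v(0.02, 0.25))$retained), 1)
})

test_that("a comfortably passing record is retained and counts partition", {
  v <- variant_records("chr1", 100L, "C", "T", dist_to_end_median = 40,
                       dist_to_end_mad = 10, frac_low_mapq = 0,
                       mapq_median_varreads = 60, baseq_median_varreads = 35,
                       strand_frac_varreads = 0.4, strand_frac_allreads = 0.45,
                       repeat_len_adjacent = 2, nearby_variant_max = 0)
  rep <- apply_read_level_filters(v)
  expect_equal(nrow(rep$retained), 1)
  expect_equal(sum(rep$rule_counts$n), 0)
})

test_that("multi-rule failures are attributed to the lowest-numbered rule", {
  v <- variant_records("chr1", 100L, "C", "T", dist_to_end_median = 5,
                       mapq_median_varreads = 10)
  rep <- apply_read_level_filters(v)
  expect_equal(rep$rejected$rule, "rule1")
  expect_equal(sum(rep$rule_counts$n), 1)  # counted once
})

test_that("missing feature values raise an error naming variant and field", {
  v <- variant_records("chr1", 100L, "C", "T")
  v$dist_to_end_mad <- NA_real_
  expect_error(apply_read_level_filters(v), "chr1:100:C:T.*dist_to_end_mad")
  expect_error(apply_read_level_filters(dplyr::select(v, -"baseq_median_varreads")),
               "baseq_median_varreads")
})

test_that("allele-frequency window is strict on both sides", {
  af <- c(0.50, 0.25, 0.75, 0.80, 0.2501, 0.7499)
  v <- variant_records("chr1", seq_along(af) * 10L, "C", "T", allele_freq = af)
  rep <- apply_af_window(v)
  expect_equal(rep$retained$allele_freq, c(0.50, 0.2501, 0.7499))
  expect_equal(unique(rep$rejected$rule), "af_window")

  bad <- v; bad$allele_freq[1] <- 1.2
  expect_error(apply_af_window(bad), "allele_freq")
})

test_that("low-coverage mode makes the AF window the identity", {
  af <- c(0.05, 0.5, 0.95)
  v <- variant_records("chr1", 1:3 * 10L, "C", "T", allele_freq = af)
  rep <- apply_af_window(v, enabled = FALSE)
  expect_equal(rep$retained, v)
  expect_equal(sum(rep$rule_counts$n), 0)
})

test_that("population filter removes at >= 0.001 with pathogenicity rescue", {
  v <- variant_records(
    "chr1", 1:5 * 10L, "C", "T",
    pop_freqs = list(c(ExAC = 0.01), numeric(0), c(ExAC = 0.0009),
                     c(ExAC = 0.001), c(Kaviar = 0.02)),
    clinvar_pathogenic = c(FALSE, FALSE, FALSE, FALSE, TRUE)
  )
  rep <- apply_population_filter(v)
  expect_equal(rep$retained$pos, c(20L, 30L, 50L))  # absent, rare, rescued
  expect_equal(rep$rescued_count, 1L)
  expect_equal(sum(rep$rule_counts$n), 2L)

  # cosmic urinary annotation rescues too; rescue can be disabled
  v2 <- variant_records("chr1", 10L, "C", "T",
                        pop_freqs = list(c(ExAC = 0.01)), cosmic_urinary = TRUE)
  expect_equal(nrow(apply_population_filter(v2)$retained), 1)
  expect_equal(nrow(apply_population_filter(v2, rescue = FALSE)$retained), 0)

  bad <- variant_records("chr1", 10L, "C", "T", pop_freqs = list(c(x = -0.1)))
  expect_error(apply_population_filter(bad), "non-negative")
})

test_that("full filter is deterministic and partitions the input", {
  v <- simulate_variant_records(n_true = 60, n_artifact = 22, seed = 11)
  rep1 <- filter_variants(v)
  rep2 <- filter_variants(v)
  expect_identical(rep1$rule_counts, rep2$rule_counts)
  expect_identical(rep1$retained, rep2$retained)
  expect_equal(nrow(rep1$retained) + sum(rep1$rule_counts$n), nrow(v))
  expect_equal(nrow(rep1$retained) + nrow(rep1$rejected), nrow(v))
})

test_that("loosening any single threshold never shrinks the retained set", {
  v <- simulate_variant_records(n_true = 40, n_artifact = 33, seed = 5)
  base_keys <- aasig:::variant_key(filter_variants(v)$retained)
  looser <- list(
    filter_thresholds(dist_end_median_min = 5),
    filter_thresholds(dist_end_mad_min = 1),
    filter_thresholds(frac_low_mapq_max = 0.3),
    filter_thresholds(mapq_median_min = 20),
    filter_thresholds(baseq_median_min = 10),
    filter_thresholds(strand_frac_var_min = 0.005),
    filter_thresholds(repeat_len_max = 20),
    filter_thresholds(nearby_variant_max_allowed = 5),
    filter_thresholds(af_low = 0.1, af_high = 0.9),
    filter_thresholds(pop_freq_max = 0.1)
  )
  for (th in looser) {
    keys <- aasig:::variant_key(filter_variants(v, th)$retained)
    expect_true(all(base_keys %in% keys))
  }
})
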