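#' @keywords internal
normalize_weights <- function(weights, signatures) {
  if (is.null(names(weights)) || any(names(weights) == "")) {
    abort("`weights` must be a fully named numeric vector.")
  }
  nm <- names(weights)
  bare <- grepl("^[0-9]+$", nm)
  nm[bare] <- paste("Signature", nm[bare])
  names(weights) <- nm
  sig_names <- setdiff(names(signatures), "context")
  unknown <- setdiff(nm, sig_names)
  if (length(unknown) > 0) {
    abort(paste0("Unknown signature label(s) in weights: ",
                 paste(unknown, collapse = ", ")))
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    abort("Weights must be non-negative and sum to 1 (within 1e-9).")
  }
  weights
}

#' Simulate a mutation catalog from a signature mixture
#'
#' Draws `n_mutations` classes from the multinomial distribution whose class
#' probabilities are the weighted mixture of the reference signature columns.
#' The configured weights are the ground truth that recovery experiments test
#' against.
#'
#' @param n_mutations Number of SNVs (> 0).
#' @param weights Named probabilities summing to 1; names are signature labels
#'   (`"Signature 22"`, or bare `"22"`).
#' @param signatures Signature tibble (default [synthetic_signatures()]).
#' @param seed Integer seed; same seed, same catalog.
#' @param sample_id Sample label.
#' @return A catalog tibble with attribute `"true_weights"`.
#' @examples
#' simulate_catalog(1000, c("Signature 22" = 0.6, "Signature 1" = 0.4), seed = 1)
#' @export
simulate_catalog <- function(n_mutations, weights,
                             signatures = synthetic_signatures(), seed,
                             sample_id = "sim") {
  if (!is.numeric(n_mutations) || length(n_mutations) != 1 || n_mutations < 1) {
    abort("`n_mutations` must be a positive count.")
  }
  weights <- normalize_weights(weights, signatures)
  probs <- signature_probs(signatures)
  p <- drop(probs[, names(weights), drop = FALSE] %*% weights)
  counts <- withr::with_seed(seed, drop(rmultinom(1, n_mutations, p)))
  out <- tibble::tibble(sample_id = sample_id, context = sbs96_contexts(),
                        count = as.integer(counts))
  attr(out, "true_weights") <- weights
  out
}

#' Simulate candidate variant records for the filter engine
#'
#' Generates `n_true` records whose read-level statistics, allele frequency
#' and database annotations all pass the filters comfortably, plus
#' `n_artifact` records each violating exactly its designated rule, with the
#' offending statistic drawn uniformly from a band just beyond the threshold
#' (so strict-versus-inclusive boundary semantics are exercised). Germline-
#' and FFPE-like contamination are available as the `"af_high"` / `"af_low"`
#' artifact classes, population-polymorphism contamination as `"pop"`.
#'
#' @param n_true,n_artifact Record counts (>= 0, not both 0).
#' @param artifact_rules Character vector recycled to `n_artifact`, each one
#'   of `"rule1"`..`"rule8"`, `"af_low"`, `"af_high"`, `"pop"`. Default cycles
#'   through all eleven classes.
#' @param thresholds [filter_thresholds()] the records are generated against.
#' @param seed Integer seed.
#' @return A variant tibble with a ground-truth `truth` column (`"true"` or
#'   the designated artifact class).
#' @examples
#' v <- simulate_variant_records(n_true = 5, n_artifact = 3, seed = 1)
#' table(v$truth)
#' @export
simulate_variant_records <- function(n_true, n_artifact = 0,
                                     artifact_rules = NULL,
                                     thresholds = filter_thresholds(),
                                     seed) {
  if (n_true < 0 || n_artifact < 0 || n_true + n_artifact == 0) {
    abort("Need non-negative counts with n_true + n_artifact > 0.")
  }
  classes <- c(paste0("rule", 1:8), "af_low", "af_high", "pop")
  artifact_rules <- artifact_rules %||% rep_len(classes, n_artifact)
  artifact_rules <- rep_len(artifact_rules, n_artifact)
  bad <- setdiff(artifact_rules, classes)
  if (length(bad) > 0) {
    abort(paste0("Unknown artifact class(es): ", paste(bad, collapse = ", ")))
  }
  th <- thresholds
  n <- n_true + n_artifact
  withr::with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    v <- variant_records(
      chrom = "chr1", pos = seq_len(n) * 1000L, ref = ref, alt = alt,
      dist_to_end_median = runif(n, th$dist_end_median_min + 10,
                                 th$dist_end_median_min + 50),
      dist_to_end_mad = runif(n, th$dist_end_mad_min + 2, th$dist_end_mad_min + 12),
      frac_low_mapq = runif(n, 0, th$frac_low_mapq_max / 2),
      mapq_median_varreads = runif(n, th$mapq_median_min + 10,
                                   th$mapq_median_min + 20),
      baseq_median_varreads = runif(n, th$baseq_median_min + 5,
                                    th$baseq_median_min + 20),
      strand_frac_varreads = runif(n, 0.3, 0.5),
      strand_frac_allreads = runif(n, 0.3, 0.5),
      repeat_len_adjacent = sample(0:(th$repeat_len_max - 4), n, replace = TRUE),
      nearby_variant_max = sample(0:th$nearby_variant_max_allowed, n,
                                  replace = TRUE),
      allele_freq = pmin(pmax(th$af_low + (th$af_high - th$af_low) *
                                rbeta(n, 5, 5),
                              th$af_low + 0.02),
                         th$af_high - 0.02)
    )
    v$truth <- c(rep("true", n_true), artifact_rules)
    for (i in seq_len(n_artifact)) {
      j <- n_true + i
      switch(artifact_rules[i],
        rule1 = { v$dist_to_end_median[j] <- runif(1, th$dist_end_median_min / 2,
                                                   th$dist_end_median_min) },
        rule2 = { v$dist_to_end_mad[j] <- runif(1, 0, th$dist_end_mad_min) },
        rule3 = { v$frac_low_mapq[j] <- runif(1, th$frac_low_mapq_max, 0.4) },
        rule4 = { v$mapq_median_varreads[j] <- runif(1, th$mapq_median_min / 2,
                                                     th$mapq_median_min) },
        rule5 = { v$baseq_median_varreads[j] <- runif(1, th$baseq_median_min / 2,
                                                      th$baseq_median_min) },
        rule6 = {
          v$strand_frac_varreads[j] <- runif(1, 0, th$strand_frac_var_min)
          v$strand_frac_allreads[j] <- runif(1, th$strand_frac_all_min, 0.5)
        },
        rule7 = { v$repeat_len_adjacent[j] <- sample(th$repeat_len_max:(th$repeat_len_max + 8), 1) },
        rule8 = { v$nearby_variant_max[j] <- sample((th$nearby_variant_max_allowed + 1):(th$nearby_variant_max_allowed + 4), 1) },
        af_low = { v$allele_freq[j] <- runif(1, 0.01, th$af_low) },
        af_high = { v$allele_freq[j] <- runif(1, th$af_high, 1) },
        pop = { v$pop_freqs[[j]] <- c(ExAC = runif(1, th$pop_freq_max, 0.05)) }
      )
    }
    # rule3 violations exceed the artifact upper band of frac_low_mapq for
    # true records by construction; keep bands disjoint for ROC sanity
    v
  })
}

#' Simulate a matched tumour / cell-free DNA catalog pair
#'
#' The cfDNA catalog is a binomial thinning of the tumour catalog, emulating
#' the reduced SNV yield of low-coverage sequencing of urinary cell-free DNA;
#' both share the configured ground-truth AA weight.
#'
#' @param n_mutations Tumour catalog size.
#' @param weights Named signature mixture weights (ground truth).
#' @param cfdna_fraction Thinning fraction in (0, 1].
#' @param signatures Signature tibble.
#' @param seed Integer seed governing both draws.
#' @return List with `tumor` and `cfdna` catalog tibbles, each carrying
#'   attribute `"true_weights"`.
#' @examples
#' pair <- simulate_tumor_cfdna_pair(20000, c("Signature 22" = 0.6,
#'                                            "Signature 5" = 0.4),
#'                                   cfdna_fraction = 0.05, seed = 1)
#' sum(pair$cfdna$count)
#' @export
simulate_tumor_cfdna_pair <- function(n_mutations, weights, cfdna_fraction,
                                      signatures = synthetic_signatures(),
                                      seed) {
  if (!is.numeric(cfdna_fraction) || length(cfdna_fraction) != 1 ||
      cfdna_fraction <= 0 || cfdna_fraction > 1) {
    abort("`cfdna_fraction` must lie in (0, 1].")
  }
  weights <- normalize_weights(weights, signatures)
  probs <- signature_probs(signatures)
  p <- drop(probs[, names(weights), drop = FALSE] %*% weights)
  counts <- withr::with_seed(seed, {
    tumor <- drop(rmultinom(1, n_mutations, p))
    cfdna <- rbinom(96, tumor, cfdna_fraction)
    list(tumor = tumor, cfdna = cfdna)
  })
  make <- function(cnt, sid) {
    out <- tibble::tibble(sample_id = sid, context = sbs96_contexts(),
                          count = as.integer(cnt))
    attr(out, "true_weights") <- weights
    out
  }
  list(tumor = make(counts$tumor, "tumor"),
       cfdna = make(counts$cfdna, "cfdna"))
}

#' Simulate a clinical cohort with subtype-dependent covariates and survival
#'
#' Two equal-sized subtype groups (AA Sig / No-AA Sig). Binary covariates are
#' Bernoulli with the given baseline prevalence in the No-AA group and the
#' given odds ratio applied in the AA group. Survival is exponential: the AA
#' group has the baseline event hazard and the No-AA group
#' `hazard_ratio`-fold that hazard (the AA subtype carries the favourable
#' outcome). Censoring is an independent exponential calibrated so the
#' probability of being censored equals `censor_rate` in each group.
#'
#' @param n_per_group Patients per subtype (>= 2).
#' @param covariate_effects Named odds ratios (AA vs No-AA). Defaults emulate
#'   the associations typical of AA-driven disease: female sex, herb intake
#'   and multifocality enriched in the AA group.
#' @param covariate_baseline Named baseline prevalences in the No-AA group;
#'   unnamed covariates default to 0.3.
#' @param hazard_ratio No-AA versus AA event hazard ratio (> 0).
#' @param baseline_hazard AA-group event hazard per month.
#' @param censor_rate Probability a patient is censored, in `[0, 1)`.
#' @param seed Integer seed.
#' @return Tibble with `sample_id`, `group` (= subtype label), `subtype`, one
#'   Present/Absent column per covariate, `time` (months) and `event`
#'   (logical).
#' @examples
#' simulate_cohort(n_per_group = 5, seed = 1)
#' @export
simulate_cohort <- function(n_per_group,
                            covariate_effects = c(female = 3, aa_intake = 7,
                                                  multifocality = 6),
                            covariate_baseline = c(female = 0.54,
                                                   aa_intake = 0.17,
                                                   multifocality = 0.06),
                            hazard_ratio = 3,
                            baseline_hazard = 0.005,
                            censor_rate = 0.7,
                            seed) {
  if (n_per_group < 2) abort("`n_per_group` must be at least 2.")
  if (any(covariate_effects <= 0) || hazard_ratio <= 0 || baseline_hazard <= 0) {
    abort("Odds ratios and hazards must be strictly positive.")
  }
  if (censor_rate < 0 || censor_rate >= 1) {
    abort("`censor_rate` must lie in [0, 1).")
  }
  n <- 2L * n_per_group
  subtype <- rep(c("AA Sig", "No-AA Sig"), each = n_per_group)
  withr::with_seed(seed, {
    out <- tibble::tibble(
      sample_id = sprintf("P%03d", seq_len(n)),
      group = subtype, subtype = subtype
    )
    for (v in names(covariate_effects)) {
      p0 <- unname(covariate_baseline[v])
      if (is.na(p0)) p0 <- 0.3
      odds1 <- covariate_effects[[v]] * p0 / (1 - p0)
      p1 <- odds1 / (1 + odds1)
      p <- ifelse(subtype == "AA Sig", p1, p0)
      out[[v]] <- factor(ifelse(runif(n) < p, "Present", "Absent"),
                         levels = c("Absent", "Present"))
    }
    hazard <- ifelse(subtype == "AA Sig", baseline_hazard,
                     baseline_hazard * hazard_ratio)
    event_time <- rexp(n, hazard)
    if (censor_rate > 0) {
      censor_hazard <- hazard * censor_rate / (1 - censor_rate)
      censor_time <- rexp(n, censor_hazard)
    } else {
      censor_time <- rep(Inf, n)
    }
    out$time <- pmin(event_time, censor_time)
    out$event <- event_time <= censor_time
    out
  })
}
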