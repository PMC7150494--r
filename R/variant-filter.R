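#' @keywords internal
variant_key <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}

read_level_fields <- c(
  rule1 = "dist_to_end_median",
  rule2 = "dist_to_end_mad",
  rule3 = "frac_low_mapq",
  rule4 = "mapq_median_varreads",
  rule5 = "baseq_median_varreads",
  rule6 = "strand_frac_varreads",
  rule6b = "strand_frac_allreads",
  rule7 = "repeat_len_adjacent",
  rule8 = "nearby_variant_max"
)

#' Assemble a tibble of candidate somatic SNVs
#'
#' Validates the per-variant fields the filter engine consumes: coordinates,
#' alleles, read-level summary statistics, allele frequency, population
#' database frequencies and rescue annotations. Strand-bias fields are stored
#' as minority-strand fractions, so they live in `[0, 0.5]`.
#'
#' @param chrom Chromosome names.
#' @param pos 1-based positions.
#' @param ref,alt Single reference/alternate bases (A/C/G/T, unequal).
#' @param dist_to_end_median,dist_to_end_mad Median (and its MAD) over
#'   variant-supporting reads of the shortest distance from the variant to
#'   either aligned read end, in bases.
#' @param frac_low_mapq Fraction of covering reads with mapping quality < 1.
#' @param mapq_median_varreads,baseq_median_varreads Median Phred mapping /
#'   base quality over variant-supporting reads.
#' @param strand_frac_varreads,strand_frac_allreads Minority-strand fraction of
#'   variant-supporting reads / of all covering reads, in `[0, 0.5]`.
#' @param repeat_len_adjacent Length in bases of the adjacent 1-4-mer repeat
#'   tract.
#' @param nearby_variant_max Largest count of other variant positions in any
#'   50-bp window surrounding (excluding) the position.
#' @param allele_freq Variant allele frequency in `[0,1]`.
#' @param pop_freqs List of named numeric vectors, one per variant: database
#'   name -> population allele frequency. `numeric(0)` means absent from all
#'   databases.
#' @param clinvar_pathogenic,cosmic_urinary Logical rescue annotations.
#' @param callers List of character vectors naming the callers that reported
#'   each variant.
#' @return A tibble with one row per candidate SNV.
#' @examples
#' variant_records(chrom = "chr1", pos = 100L, ref = "A", alt = "T")
#' @export
variant_records <- function(chrom, pos, ref, alt,
                            dist_to_end_median = 40,
                            dist_to_end_mad = 10,
                            frac_low_mapq = 0,
                            mapq_median_varreads = 60,
                            baseq_median_varreads = 35,
                            strand_frac_varreads = 0.4,
                            strand_frac_allreads = 0.45,
                            repeat_len_adjacent = 2,
                            nearby_variant_max = 0,
                            allele_freq = 0.5,
                            pop_freqs = NULL,
                            clinvar_pathogenic = FALSE,
                            cosmic_urinary = FALSE,
                            callers = NULL) {
  n <- length(chrom)
  pop_freqs <- pop_freqs %||% rep(list(numeric(0)), n)
  if (!is.list(pop_freqs)) pop_freqs <- list(pop_freqs)
  callers <- callers %||% rep(list(c("varscan2", "vardict")), n)
  if (!is.list(callers)) callers <- list(callers)
  out <- tibble::tibble(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = as.character(ref), alt = as.character(alt),
    dist_to_end_median = dist_to_end_median,
    dist_to_end_mad = dist_to_end_mad,
    frac_low_mapq = frac_low_mapq,
    mapq_median_varreads = mapq_median_varreads,
    baseq_median_varreads = baseq_median_varreads,
    strand_frac_varreads = strand_frac_varreads,
    strand_frac_allreads = strand_frac_allreads,
    repeat_len_adjacent = repeat_len_adjacent,
    nearby_variant_max = nearby_variant_max,
    allele_freq = allele_freq,
    pop_freqs = pop_freqs,
    clinvar_pathogenic = clinvar_pathogenic,
    cosmic_urinary = cosmic_urinary,
    callers = callers
  )
  validate_variant_records(out)
  out
}

#' @keywords internal
validate_variant_records <- function(variants, fields = NULL) {
  stopifnot(is.data.frame(variants))
  base_fields <- c("chrom", "pos", "ref", "alt")
  fields <- unique(c(base_fields, fields))
  missing_cols <- setdiff(fields, names(variants))
  if (length(missing_cols) > 0) {
    abort(paste0("Variant table is missing required fields: ",
                 paste(missing_cols, collapse = ", ")))
  }
  bases <- c("A", "C", "G", "T")
  if (nrow(variants) > 0) {
    if (!all(variants$ref %in% bases) || !all(variants$alt %in% bases)) {
      abort("ref and alt must be single bases in {A, C, G, T}.")
    }
    if (any(variants$ref == variants$alt)) {
      abort("ref must differ from alt for every variant.")
    }
    for (fld in setdiff(fields, c(base_fields, "pop_freqs", "callers"))) {
      miss <- which(is.na(variants[[fld]]))
      if (length(miss) > 0) {
        abort(sprintf("Variant %s: missing value for field '%s'.",
                      variant_key(variants[miss[1], ]), fld))
      }
    }
    for (fld in c("frac_low_mapq", "allele_freq")) {
      if (fld %in% fields && any(variants[[fld]] < 0 | variants[[fld]] > 1)) {
        abort(sprintf("'%s' must lie in [0, 1].", fld))
      }
    }
    for (fld in c("strand_frac_varreads", "strand_frac_allreads")) {
      if (fld %in% fields && any(variants[[fld]] < 0 | variants[[fld]] > 0.5)) {
        abort(sprintf("'%s' is a minority-strand fraction and must lie in [0, 0.5].", fld))
      }
    }
  }
  invisible(variants)
}

new_filter_report <- function(retained, rejected, rule_counts, rescued_count,
                              n_input) {
  structure(
    list(retained = retained, rejected = rejected, rule_counts = rule_counts,
         rescued_count = rescued_count, n_input = n_input),
    class = "filter_report"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("Somatic SNV filter report: %d in, %d retained, %d removed",
              x$n_input, nrow(x$retained), nrow(x$rejected)))
  if (x$rescued_count > 0) cat(sprintf(" (%d rescued)", x$rescued_count))
  cat("\n")
  active <- dplyr::filter(x$rule_counts, .data$n > 0)
  if (nrow(active) > 0) {
    for (i in seq_len(nrow(active))) {
      cat(sprintf("  %-12s %d\n", active$rule[i], active$n[i]))
    }
  }
  invisible(x)
}

#' @describeIn filter_variants Per-rule rejection counts of a filter report as
#'   a tibble.
#' @param x A `filter_report`.
#' @method tidy filter_report
#' @export
tidy.filter_report <- function(x, ...) {
  x$rule_counts
}

#' @describeIn filter_variants One-row summary of a filter report.
#' @export
glance.filter_report <- function(x, ...) {
  tibble::tibble(n_input = x$n_input, n_retained = nrow(x$retained),
                 n_removed = nrow(x$rejected), n_rescued = x$rescued_count)
}

split_report <- function(variants, failed_rule, rescued_count = 0L,
                         rule_levels = unique(stats::na.omit(failed_rule))) {
  failed_rule <- as.character(failed_rule)
  keep <- is.na(failed_rule)
  rejected <- variants[!keep, , drop = FALSE]
  rejected$rule <- failed_rule[!keep]
  counts <- tibble::tibble(rule = unname(rule_levels),
                           n = vapply(unname(rule_levels),
                                      function(r) sum(failed_rule == r, na.rm = TRUE),
                                      integer(1), USE.NAMES = FALSE))
  new_filter_report(variants[keep, , drop = FALSE], rejected, counts,
                    rescued_count, nrow(variants))
}

#' Intersect two caller-specific candidate sets
#'
#' Somatic SNV candidates are kept only when both callers report the same
#' (chrom, pos, ref, alt) key. Feature annotations of the result are taken
#' from `set_a`, so downstream filtering is deterministic with respect to the
#' annotation source.
#'
#' @param set_a,set_b Variant tibbles (see [variant_records()]), each
#'   internally deduplicated on the variant key.
#' @return The rows of `set_a` whose key also occurs in `set_b`.
#' @examples
#' a <- variant_records("chr1", 100L, "A", "T")
#' b <- variant_records(c("chr1", "chr2"), c(100L, 5L), c("A", "C"), c("T", "G"))
#' intersect_callsets(a, b)
#' @export
intersect_callsets <- function(set_a, set_b) {
  validate_variant_records(set_a)
  validate_variant_records(set_b)
  for (nm in c("set_a", "set_b")) {
    keys <- variant_key(get(nm))
    dup <- keys[duplicated(keys)]
    if (length(dup) > 0) {
      abort(sprintf("Duplicate variant key in %s: %s", nm, dup[1]))
    }
  }
  set_a[variant_key(set_a) %in% variant_key(set_b), , drop = FALSE]
}

#' Apply the eight read-level artifact rules
#'
#' Removes a candidate SNV when it satisfies any of the eight read-level
#' removal rules (see [filter_thresholds()] for their definitions). Removal is
#' an OR over rules; for reporting, each removed variant is attributed to the
#' lowest-numbered rule it fails, so the per-rule counts partition the
#' removals.
#'
#' @param variants Variant tibble with all read-level statistics populated.
#' @param thresholds A [filter_thresholds()] object.
#' @return A `filter_report`: `retained` (rows unchanged), `rejected` (with a
#'   `rule` column), `rule_counts`, `rescued_count` (always 0 here) and
#'   `n_input`.
#' @examples
#' v <- variant_records("chr1", 1:2 * 100L, "C", "T",
#'                      dist_to_end_median = c(40, 5))
#' apply_read_level_filters(v)
#' @export
apply_read_level_filters <- function(variants, thresholds = filter_thresholds()) {
  validate_variant_records(variants, unname(read_level_fields))
  th <- thresholds
  fails <- cbind(
    rule1 = variants$dist_to_end_median < th$dist_end_median_min,
    rule2 = variants$dist_to_end_mad < th$dist_end_mad_min,
    rule3 = variants$frac_low_mapq > th$frac_low_mapq_max,
    rule4 = variants$mapq_median_varreads < th$mapq_median_min,
    rule5 = variants$baseq_median_varreads < th$baseq_median_min,
    rule6 = variants$strand_frac_varreads < th$strand_frac_var_min &
      variants$strand_frac_allreads >= th$strand_frac_all_min,
    rule7 = variants$repeat_len_adjacent >= th$repeat_len_max,
    rule8 = variants$nearby_variant_max > th$nearby_variant_max_allowed
  )
  rules <- colnames(fails)
  first_fail <- apply(fails, 1, function(row) {
    i <- which(row)
    if (length(i) == 0) NA_character_ else rules[i[1]]
  })
  if (nrow(variants) == 0) first_fail <- character(0)
  split_report(variants, first_fail, rule_levels = rules)
}

#' Apply the somatic allele-frequency window
#'
#' Retains variants with allele frequency strictly between the window bounds
#' (default 0.25 and 0.75): higher frequencies are more likely germline, lower
#' ones are enriched for FFPE artifacts. In low-coverage mode
#' (`enabled = FALSE`, as used for shallow cell-free DNA sequencing) the
#' window is not applied and the operation is the identity.
#'
#' @inheritParams apply_read_level_filters
#' @param enabled Apply the window? `FALSE` reproduces low-coverage calling,
#'   which does not filter on allele frequency.
#' @return A `filter_report` with rule id `"af_window"`.
#' @examples
#' v <- variant_records("chr1", c(100L, 200L), "C", "T",
#'                      allele_freq = c(0.5, 0.8))
#' apply_af_window(v)
#' @export
apply_af_window <- function(variants, thresholds = filter_thresholds(),
                            enabled = TRUE) {
  validate_variant_records(variants, "allele_freq")
  if (!enabled) {
    return(split_report(variants, rep(NA_character_, nrow(variants)),
                        rule_levels = "af_window"))
  }
  keep <- variants$allele_freq > thresholds$af_low &
    variants$allele_freq < thresholds$af_high
  split_report(variants, ifelse(keep, NA_character_, "af_window"),
               rule_levels = "af_window")
}

#' Apply the population-frequency filter with pathogenicity rescue
#'
#' Removes variants observed at population allele frequency at or above the
#' cutoff (default 0.001) in any database (1000 Genomes phase 3, ExAC,
#' NHLBI-ESP 6500, Haplotype Reference Consortium, Kaviar, or a matched
#' healthy panel), unless annotated Pathogenic in ClinVar or urinary-associated
#' in COSMIC, in which case they are retained and counted as rescued.
#'
#' @inheritParams apply_read_level_filters
#' @param rescue Keep database-frequent variants that carry a pathogenicity
#'   annotation?
#' @return A `filter_report` with rule id `"population"` and `rescued_count`
#'   set.
#' @examples
#' v <- variant_records("chr1", c(1L, 2L), "C", "T",
#'                      pop_freqs = list(c(ExAC = 0.01), numeric(0)))
#' apply_population_filter(v)
#' @export
apply_population_filter <- function(variants, thresholds = filter_thresholds(),
                                    rescue = TRUE) {
  validate_variant_records(variants,
                           c("pop_freqs", "clinvar_pathogenic", "cosmic_urinary"))
  freqs <- variants$pop_freqs
  if (nrow(variants) > 0 && any(unlist(freqs) < 0)) {
    abort("Population frequencies must be non-negative.")
  }
  frequent <- vapply(freqs, function(f) length(f) > 0 && any(f >= thresholds$pop_freq_max),
                     logical(1))
  rescued <- frequent &
    (variants$clinvar_pathogenic | variants$cosmic_urinary) & rescue
  removed <- frequent & !rescued
  split_report(variants, ifelse(removed, "population", NA_character_),
               rescued_count = sum(rescued), rule_levels = "population")
}

#' Run the full somatic SNV post-calling filter
#'
#' Chains the read-level rules, the allele-frequency window and the
#' population-frequency filter (with rescue) into one report. The retained set
#' is the pure conjunction of the stages, so stage order does not affect it;
#' per-rule counts attribute each removal to its first failing stage/rule.
#'
#' @inheritParams apply_read_level_filters
#' @param af_window Apply the allele-frequency window? Set `FALSE` for
#'   low-coverage data.
#' @param rescue Apply the ClinVar/COSMIC rescue in the population filter?
#' @return A `filter_report` whose `rule_counts` covers rules 1-8,
#'   `"af_window"` and `"population"`.
#' @examples
#' v <- simulate_variant_records(n_true = 5, n_artifact = 3, seed = 1)
#' filter_variants(v)
#' @export
filter_variants <- function(variants, thresholds = filter_thresholds(),
                            af_window = TRUE, rescue = TRUE) {
  r1 <- apply_read_level_filters(variants, thresholds)
  r2 <- apply_af_window(r1$retained, thresholds, enabled = af_window)
  r3 <- apply_population_filter(r2$retained, thresholds, rescue = rescue)
  rejected <- dplyr::bind_rows(r1$rejected, r2$rejected, r3$rejected)
  counts <- dplyr::bind_rows(r1$rule_counts, r2$rule_counts, r3$rule_counts)
  new_filter_report(r3$retained, rejected, counts, r3$rescued_count,
                    nrow(variants))
}
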