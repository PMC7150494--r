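#' Read-level and frequency thresholds for somatic SNV filtering
#'
#' Bundles every cutoff used by the post-calling filter engine. Defaults encode
#' the screening pipeline's published heuristics; any can be overridden.
#'
#' The eight read-level rules remove a variant when:
#' 1. the median shortest distance from the variant to either aligned read end
#'    is below `dist_end_median_min` bases;
#' 2. the median absolute deviation of that distance is below
#'    `dist_end_mad_min` bases;
#' 3. more than `frac_low_mapq_max` of covering reads have mapping quality
#'    below 1;
#' 4. the median mapping quality of variant-supporting reads is below
#'    `mapq_median_min`;
#' 5. the median base quality at the variant position is below
#'    `baseq_median_min`;
#' 6. the minority-strand fraction of variant reads is below
#'    `strand_frac_var_min` *and* the minority-strand fraction of all covering
#'    reads is at least `strand_frac_all_min` (the exception clause: when all
#'    reads share the imbalance, the variant is kept);
#' 7. an adjacent 1-4-mer repeat tract is `repeat_len_max` bases or longer;
#' 8. more than `nearby_variant_max_allowed` other variant positions fall in
#'    some `window_bp` window around (excluding) the position.
#'
#' The allele-frequency window retains variants with
#' `af_low < AF < af_high` (strict on both sides: higher frequencies look
#' germline, lower ones are enriched for FFPE artifacts). The population
#' filter removes variants seen at frequency `pop_freq_max` or higher in any
#' population database, unless rescued by pathogenicity annotation.
#'
#' @param dist_end_median_min,dist_end_mad_min Bases; rules 1-2.
#' @param frac_low_mapq_max Fraction in `[0,1]`; rule 3.
#' @param mapq_median_min,baseq_median_min Phred; rules 4-5.
#' @param strand_frac_var_min,strand_frac_all_min Minority-strand fractions in
#'   `[0, 0.5]`; rule 6.
#' @param repeat_len_max Bases; rule 7 (removal at or above).
#' @param window_bp,nearby_variant_max_allowed Rule 8 window and count.
#' @param af_low,af_high Allele-frequency window (exclusive bounds).
#' @param pop_freq_max Population-frequency removal cutoff (inclusive).
#' @return A named list of class `"filter_thresholds"`.
#' @examples
#' filter_thresholds()
#' filter_thresholds(mapq_median_min = 30)
#' @export
filter_thresholds <- function(dist_end_median_min = 10,
                              dist_end_mad_min = 3,
                              frac_low_mapq_max = 0.10,
                              mapq_median_min = 40,
                              baseq_median_min = 20,
                              strand_frac_var_min = 0.02,
                              strand_frac_all_min = 0.2,
                              repeat_len_max = 12,
                              window_bp = 50,
                              nearby_variant_max_allowed = 2,
                              af_low = 0.25,
                              af_high = 0.75,
                              pop_freq_max = 0.001) {
  th <- list(
    dist_end_median_min = dist_end_median_min,
    dist_end_mad_min = dist_end_mad_min,
    frac_low_mapq_max = frac_low_mapq_max,
    mapq_median_min = mapq_median_min,
    baseq_median_min = baseq_median_min,
    strand_frac_var_min = strand_frac_var_min,
    strand_frac_all_min = strand_frac_all_min,
    repeat_len_max = repeat_len_max,
    window_bp = window_bp,
    nearby_variant_max_allowed = nearby_variant_max_allowed,
    af_low = af_low,
    af_high = af_high,
    pop_freq_max = pop_freq_max
  )
  bad <- names(th)[!vapply(th, function(x) is.numeric(x) && length(x) == 1 && x > 0, logical(1))]
  if (length(bad) > 0) {
    abort(paste0("All thresholds must be single positive numbers; offending: ",
                 paste(bad, collapse = ", ")))
  }
  if (th$af_low >= th$af_high) {
    abort("`af_low` must be strictly less than `af_high`.")
  }
  structure(th, class = "filter_thresholds")
}

#' @export
print.filter_thresholds <- function(x, ...) {
  cat("Somatic SNV filter thresholds:\n")
  for (nm in names(x)) cat(sprintf("  %-28s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' AA-proportion screening thresholds
#'
#' Cutoffs on the AA-attributed fraction of a sample's mutations used for
#' single-sample subtype calls. In urinary cell-free DNA, samples above
#' `cfdna_high` are called AA Sig and samples below `cfdna_low` No-AA Sig;
#' the band between the validated extremes is flagged indeterminate. In tumour
#' tissue the single cutoff `tumor_high` separates the subtypes.
#'
#' @param cfdna_high,cfdna_low,tumor_high Proportions in `[0,1]`.
#' @return A named list of class `"screening_thresholds"`.
#' @examples
#' screening_thresholds()
#' @export
screening_thresholds <- function(cfdna_high = 0.15, cfdna_low = 0.05,
                                 tumor_high = 0.50) {
  if (!(cfdna_low < cfdna_high && cfdna_high <= tumor_high)) {
    abort("Require cfdna_low < cfdna_high <= tumor_high.")
  }
  structure(list(cfdna_high = cfdna_high, cfdna_low = cfdna_low,
                 tumor_high = tumor_high),
            class = "screening_thresholds")
}

#' @export
print.screening_thresholds <- function(x, ...) {
  cat("AA-proportion screening thresholds:\n")
  cat(sprintf("  cfDNA: AA Sig above %g, No-AA Sig below %g (indeterminate between)\n",
              x$cfdna_high, x$cfdna_low))
  cat(sprintf("  tumour: AA Sig above %g\n", x$tumor_high))
  invisible(x)
}
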