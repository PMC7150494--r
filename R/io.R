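vcf_info_keys <- c(
  DEM = "dist_to_end_median", DEMAD = "dist_to_end_mad",
  FLMQ = "frac_low_mapq", MQM = "mapq_median_varreads",
  BQM = "baseq_median_varreads", SFV = "strand_frac_varreads",
  SFA = "strand_frac_allreads", RPL = "repeat_len_adjacent",
  NV50 = "nearby_variant_max", VAF = "allele_freq"
)

#' Write candidate SNVs as an uncompressed VCF
#'
#' One record per variant; the read-level statistics, allele frequency,
#' population frequencies and rescue annotations travel as INFO keys (`DEM`,
#' `DEMAD`, `FLMQ`, `MQM`, `BQM`, `SFV`, `SFA`, `RPL`, `NV50`, `VAF`, `PF`,
#' `CLNP`, `COSU`, `CALLERS`, and `TRUTH` for simulated ground truth). The
#' inverse of [read_variant_vcf()].
#'
#' @param variants A variant tibble (see [variant_records()]).
#' @param path Output path (plain text).
#' @export
write_variant_vcf <- function(variants, path) {
  validate_variant_records(variants, unname(vcf_info_keys))
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
            names(vcf_info_keys), vcf_info_keys),
    "##INFO=<ID=PF,Number=.,Type=String,Description=\"Population frequencies as db:freq\">",
    "##INFO=<ID=CLNP,Number=0,Type=Flag,Description=\"ClinVar Pathogenic\">",
    "##INFO=<ID=COSU,Number=0,Type=Flag,Description=\"COSMIC urinary-associated\">",
    "##INFO=<ID=CALLERS,Number=.,Type=String,Description=\"Reporting callers\">",
    "##INFO=<ID=TRUTH,Number=1,Type=String,Description=\"Simulation ground-truth class\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t")
  )
  fmt_num <- function(x) sub("\\.?0+$", "", sprintf("%.6f", x))
  info <- vapply(seq_len(nrow(variants)), function(i) {
    parts <- sprintf("%s=%s", names(vcf_info_keys),
                     fmt_num(vapply(vcf_info_keys,
                                    function(f) variants[[f]][i], numeric(1))))
    pf <- variants$pop_freqs[[i]]
    if (length(pf) > 0) {
      parts <- c(parts, paste0("PF=", paste(sprintf("%s:%s", names(pf), fmt_num(pf)),
                                            collapse = "|")))
    }
    if (isTRUE(variants$clinvar_pathogenic[i])) parts <- c(parts, "CLNP")
    if (isTRUE(variants$cosmic_urinary[i])) parts <- c(parts, "COSU")
    parts <- c(parts, paste0("CALLERS=",
                             paste(variants$callers[[i]], collapse = "|")))
    if ("truth" %in% names(variants)) {
      parts <- c(parts, paste0("TRUTH=", variants$truth[i]))
    }
    paste(parts, collapse = ";")
  }, character(1))
  body <- paste(variants$chrom, variants$pos, ".", variants$ref, variants$alt,
                ".", "PASS", info, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read candidate SNVs from a VCF
#'
#' Parses a VCF whose INFO field carries the per-variant feature annotations
#' written by [write_variant_vcf()] (see that help page for the key
#' dictionary). Records missing any required key raise an error listing the
#' missing keys.
#'
#' @param path VCF path (uncompressed).
#' @return A variant tibble; a `truth` column is included when the file
#'   carries simulated ground truth.
#' @export
read_variant_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  fix <- matrix(fix, ncol = 7, dimnames = list(NULL, colnames(fix)))
  info <- unname(vcf@fix[, "INFO"])
  n <- nrow(fix)
  out <- tibble::tibble(chrom = fix[, "CHROM"],
                        pos = as.integer(fix[, "POS"]),
                        ref = fix[, "REF"], alt = fix[, "ALT"])
  missing_keys <- character(0)
  for (key in names(vcf_info_keys)) {
    vals <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, element = key)))
    if (n > 0 && any(is.na(vals))) {
      missing_keys <- c(missing_keys, key)
    }
    out[[vcf_info_keys[[key]]]] <- vals
  }
  if (length(missing_keys) > 0) {
    abort(paste0("VCF INFO is missing required key(s): ",
                 paste(missing_keys, collapse = ", ")))
  }
  pf_raw <- vcfR::extract.info(vcf, element = "PF")
  out$pop_freqs <- purrr::map(seq_len(n), function(i) {
    s <- pf_raw[i]
    if (is.na(s) || s == "") return(numeric(0))
    kv <- strsplit(strsplit(s, "|", fixed = TRUE)[[1]], ":", fixed = TRUE)
    setNames(vapply(kv, function(p) as.numeric(p[2]), numeric(1)),
             vapply(kv, `[`, character(1), 1))
  })
  out$clinvar_pathogenic <- grepl("(^|;)CLNP(;|$)", info)
  out$cosmic_urinary <- grepl("(^|;)COSU(;|$)", info)
  callers_raw <- vcfR::extract.info(vcf, element = "CALLERS")
  out$callers <- purrr::map(callers_raw, function(s) {
    if (is.na(s)) character(0) else strsplit(s, "|", fixed = TRUE)[[1]]
  })
  truth <- vcfR::extract.info(vcf, element = "TRUTH")
  if (n > 0 && !all(is.na(truth))) out$truth <- truth
  validate_variant_records(out, unname(vcf_info_keys))
  out
}

#' Read or write a mutation catalog as tab-delimited text
#'
#' 96 labelled context rows, one column per sample — the conventional layout
#' for signature analysis.
#'
#' @param catalog A catalog tibble.
#' @param path File path.
#' @export
write_catalog <- function(catalog, path) {
  m <- catalog_matrix(catalog)
  df <- dplyr::bind_cols(tibble::tibble(context = rownames(m)),
                         tibble::as_tibble(m))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_catalog
#' @return `read_catalog()` returns a tidy catalog tibble.
#' @export
read_catalog <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"context" %in% names(df)) {
    abort("Catalog file needs a 'context' column.")
  }
  out <- tidyr::pivot_longer(df, -"context", names_to = "sample_id",
                             values_to = "count") |>
    dplyr::mutate(count = as.integer(.data$count)) |>
    dplyr::select("sample_id", "context", "count") |>
    dplyr::arrange(match(.data$sample_id, unique(.data$sample_id)),
                   match(.data$context, sbs96_contexts()))
  validate_catalog(out)
  out
}

#' Write a per-rule rejection summary
#'
#' @param report A `filter_report`.
#' @param path Output TSV path.
#' @export
write_rejection_summary <- function(report, path) {
  stopifnot(inherits(report, "filter_report"))
  readr::write_tsv(report$rule_counts, path, progress = FALSE)
  invisible(path)
}
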