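BASES <- c("A", "C", "G", "T")
COMP <- c(A = "T", C = "G", G = "C", T = "A")
SUBSTITUTIONS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' The canonical 96 trinucleotide substitution classes
#'
#' Single-base substitutions are strand-collapsed so the mutated base is a
#' pyrimidine, giving 6 substitutions x 4 5'-flanks x 4 3'-flanks = 96
#' classes. The ordering is substitution-major, then 5' flank, then 3' flank,
#' alphabetical — the layout of the COSMIC signature matrix, so catalogs and
#' signature matrices align without permutation.
#'
#' @return Character vector of 96 labels such as `"A[C>A]A"`.
#' @examples
#' head(sbs96_contexts())
#' @export
sbs96_contexts <- function() {
  grid <- expand.grid(three = BASES, five = BASES, sub = SUBSTITUTIONS,
                      stringsAsFactors = FALSE)[, 3:1]
  paste0(grid$five, "[", grid$sub, "]", grid$three)
}

#' Strand-collapse a substitution and its flanks to a trinucleotide class
#'
#' When the mutated reference base is a purine, the substitution and both
#' flanking bases are reverse-complemented (so the flanks swap); the result
#' always has a pyrimidine reference. Vectorised over all four arguments.
#'
#' @param ref,alt Reference and alternate bases (A/C/G/T, unequal).
#' @param flank5,flank3 The bases immediately 5' and 3' of the position on the
#'   reference strand.
#' @return A tibble with columns `substitution`, `five_prime`, `three_prime`
#'   and the combined `context` label.
#' @examples
#' classify_context("A", "T", "C", "T")  # collapses to A[T>A]G
#' @export
classify_context <- function(ref, alt, flank5, flank3) {
  n <- max(length(ref), length(alt), length(flank5), length(flank3))
  ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  flank5 <- rep_len(flank5, n); flank3 <- rep_len(flank3, n)
  ok <- ref %in% BASES & alt %in% BASES & flank5 %in% BASES & flank3 %in% BASES
  if (!all(ok)) {
    abort(sprintf("Non-ACGT base in context input (first offender: ref=%s alt=%s flank5=%s flank3=%s).",
                  ref[!ok][1], alt[!ok][1], flank5[!ok][1], flank3[!ok][1]))
  }
  if (any(ref == alt)) abort("ref must differ from alt.")
  flip <- ref %in% c("A", "G")
  r <- ifelse(flip, COMP[ref], ref)
  a <- ifelse(flip, COMP[alt], alt)
  f5 <- ifelse(flip, COMP[flank3], flank5)
  f3 <- ifelse(flip, COMP[flank5], flank3)
  tibble::tibble(
    substitution = paste0(r, ">", a),
    five_prime = unname(f5),
    three_prime = unname(f3),
    context = paste0(f5, "[", r, ">", a, "]", f3)
  )
}

#' @keywords internal
empty_catalog <- function(sample_id = "sample") {
  tibble::tibble(sample_id = sample_id, context = sbs96_contexts(), count = 0L)
}

#' @keywords internal
validate_catalog <- function(catalog) {
  stopifnot(is.data.frame(catalog))
  need <- c("sample_id", "context", "count")
  miss <- setdiff(need, names(catalog))
  if (length(miss) > 0) {
    abort(paste0("Catalog is missing columns: ", paste(miss, collapse = ", ")))
  }
  if (any(catalog$count < 0)) abort("Catalog counts must be non-negative.")
  ctx <- sbs96_contexts()
  bad <- setdiff(unique(catalog$context), ctx)
  if (length(bad) > 0) {
    abort(paste0("Unknown context label(s): ", paste(head(bad, 3), collapse = ", ")))
  }
  invisible(catalog)
}

#' Convert a tidy catalog to a 96 x samples count matrix
#'
#' @param catalog A catalog tibble (`sample_id`, `context`, `count`).
#' @return Integer matrix, rows in canonical context order, one column per
#'   sample.
#' @export
catalog_matrix <- function(catalog) {
  validate_catalog(catalog)
  ctx <- sbs96_contexts()
  wide <- tidyr::pivot_wider(catalog, id_cols = "context",
                             names_from = "sample_id", values_from = "count",
                             values_fill = 0)
  m <- as.matrix(wide[match(ctx, wide$context), -1, drop = FALSE])
  m[is.na(m)] <- 0
  rownames(m) <- ctx
  m
}

#' Build a 96-context mutation catalog from filtered SNVs
#'
#' Looks up the two flanking reference bases for every SNV (coordinates are
#' 1-based, VCF convention; flanks are `pos - 1` and `pos + 1`),
#' strand-collapses with [classify_context()] and tallies per class. The
#' catalog total always equals the number of input SNVs.
#'
#' @param variants Variant tibble with `chrom`, `pos`, `ref`, `alt` and
#'   optionally `sample_id`.
#' @param reference A [Biostrings::DNAStringSet] or path to a FASTA file.
#' @param sample_id Sample label used when `variants` lacks a `sample_id`
#'   column.
#' @param chrom_normalize Reconcile `"chr1"`-versus-`"1"` naming between
#'   variants and reference by adding/stripping the `"chr"` prefix when the
#'   plain name is absent (default `TRUE`).
#' @return A catalog tibble (`sample_id`, `context`, `count`; 96 rows per
#'   sample, canonical order).
#' @examples
#' ref <- Biostrings::DNAStringSet(c(chr1 = "ACTGACTG"))
#' v <- variant_records("chr1", 2L, "C", "A")
#' build_catalog(v, ref)
#' @export
build_catalog <- function(variants, reference, sample_id = "sample",
                          chrom_normalize = TRUE) {
  validate_variant_records(variants)
  if (is.character(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
  }
  if (!"sample_id" %in% names(variants)) variants$sample_id <- sample_id
  if (nrow(variants) == 0) return(empty_catalog(sample_id))

  chrom <- variants$chrom
  if (chrom_normalize) {
    missing <- !(chrom %in% names(reference))
    flipped <- ifelse(grepl("^chr", chrom), sub("^chr", "", chrom),
                      paste0("chr", chrom))
    chrom[missing & flipped %in% names(reference)] <- flipped[missing & flipped %in% names(reference)]
  }
  unknown <- setdiff(unique(chrom), names(reference))
  if (length(unknown) > 0) {
    abort(paste0("Chromosome(s) not in reference: ", paste(unknown, collapse = ", ")))
  }
  widths <- setNames(Biostrings::width(reference), names(reference))
  at_edge <- variants$pos <= 1 | variants$pos >= widths[chrom]
  if (any(at_edge)) {
    abort(sprintf("Variant %s lies at a contig edge; flanking bases unavailable.",
                  variant_key(variants[which(at_edge)[1], ])))
  }
  tri <- as.character(Biostrings::subseq(reference[chrom],
                                         start = variants$pos - 1L,
                                         width = 3L))
  ref_base <- substr(tri, 2, 2)
  mismatch <- ref_base != variants$ref
  if (any(mismatch)) {
    i <- which(mismatch)[1]
    abort(sprintf("Variant %s: reference base is %s, not %s.",
                  variant_key(variants[i, ]), ref_base[i], variants$ref[i]))
  }
  cls <- classify_context(variants$ref, variants$alt,
                          substr(tri, 1, 1), substr(tri, 3, 3))
  ctx_levels <- sbs96_contexts()
  variants |>
    dplyr::mutate(.class = factor(cls$context, levels = ctx_levels)) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::reframe(context = ctx_levels,
                   count = as.integer(table(.data$.class)))
}

#' Thin a catalog to emulate low-coverage calling
#'
#' Shallow sequencing recovers only a fraction of a tumour's somatic SNVs.
#' Each mutation is retained independently with probability `fraction`
#' (binomial thinning per class), which preserves the relative spectrum in
#' expectation while shrinking the total.
#'
#' @param catalog A catalog tibble.
#' @param fraction Retention probability in `[0, 1]`.
#' @param seed Integer seed; thinning is reproducible given the seed.
#' @return A catalog tibble of the same shape with thinned counts.
#' @examples
#' cat96 <- simulate_catalog(1000, c("Signature 22" = 1), seed = 1)
#' downsample_catalog(cat96, 0.05, seed = 2)
#' @export
downsample_catalog <- function(catalog, fraction, seed) {
  validate_catalog(catalog)
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction < 0 || fraction > 1) {
    abort("`fraction` must be a single probability in [0, 1].")
  }
  counts <- as.integer(catalog$count)
  thinned <- withr::with_seed(seed, rbinom(length(counts), counts, fraction))
  dplyr::mutate(catalog, count = as.integer(thinned))
}

#' Total mutation count per sample of a catalog
#'
#' @param catalog A catalog tibble.
#' @return Tibble with `sample_id` and `total`.
#' @export
catalog_totals <- function(catalog) {
  validate_catalog(catalog)
  catalog |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop")
}
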