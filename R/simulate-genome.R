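#' Generate a synthetic reference chromosome
#'
#' A uniform-random DNA sequence long enough that every trinucleotide occurs
#' many times, used to anchor simulated variants to genuine flanking bases.
#'
#' @param length Sequence length in bases.
#' @param seed Integer seed.
#' @param name Contig name.
#' @return A [Biostrings::DNAStringSet] of one contig.
#' @examples
#' synthetic_reference(1000, seed = 1)
#' @export
synthetic_reference <- function(length = 1e5, seed, name = "chr1") {
  seq <- withr::with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = ""))
  setNames(Biostrings::DNAStringSet(seq), name)
}

#' @keywords internal
revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(s, ""), function(x) paste(rev(x), collapse = ""),
                character(1)))
}

#' Simulate a signature-derived variant set placed on a reference
#'
#' Draws trinucleotide classes from a signature mixture (as in
#' [simulate_catalog()]) and places each mutation at a reference position
#' whose actual flanking bases produce that class — on either strand — so
#' that [build_catalog()] on the simulated VCF reproduces the generator's
#' tally exactly. Read-level features are drawn to pass all filters; optional
#' artifact records (which the filter engine should remove) are placed at
#' leftover positions.
#'
#' @param n_mutations Number of true somatic SNVs.
#' @param weights Named signature mixture weights.
#' @param reference A [Biostrings::DNAStringSet] (one or more contigs), e.g.
#'   from [synthetic_reference()].
#' @param signatures Signature tibble.
#' @param n_artifact Number of artifact records to add.
#' @param thresholds [filter_thresholds()] used for feature generation.
#' @param seed Integer seed.
#' @return List: `variants` (tibble with `truth` column, sorted by position),
#'   `truth_catalog` (the generator's own tally of the true variants).
#' @examples
#' ref <- synthetic_reference(20000, seed = 1)
#' sim <- simulate_variant_vcf(100, c("Signature 22" = 1), ref, seed = 2)
#' sum(sim$truth_catalog$count)
#' @export
simulate_variant_vcf <- function(n_mutations, weights, reference,
                                 signatures = synthetic_signatures(),
                                 n_artifact = 0,
                                 thresholds = filter_thresholds(), seed) {
  weights <- normalize_weights(weights, signatures)
  probs <- signature_probs(signatures)
  p <- drop(probs[, names(weights), drop = FALSE] %*% weights)
  ctx <- sbs96_contexts()
  contig <- names(reference)[1]
  seq <- as.character(reference[[1]])
  L <- nchar(seq)
  centers <- 2:(L - 1)
  tris <- substring(seq, centers - 1, centers + 1)

  withr::with_seed(seed, {
    class_counts <- drop(rmultinom(1, n_mutations, p))
    pos_by_tri <- split(centers, tris)
    available <- setNames(lapply(pos_by_tri, function(x) sample(x)),
                          names(pos_by_tri))
    take <- function(tri, k) {
      pool <- available[[tri]]
      if (is.null(pool) || length(pool) < k) {
        abort(sprintf("Reference too short: need %d positions with trinucleotide %s.",
                      k, tri))
      }
      taken <- pool[seq_len(k)]
      available[[tri]] <<- pool[-seq_len(k)]
      taken
    }
    rows <- purrr::map(which(class_counts > 0), function(ci) {
      k <- class_counts[ci]
      lbl <- ctx[ci]
      f5 <- substr(lbl, 1, 1); ref_b <- substr(lbl, 3, 3)
      alt_b <- substr(lbl, 5, 5); f3 <- substr(lbl, 7, 7)
      plus_tri <- paste0(f5, ref_b, f3)
      minus_tri <- revcomp_chr(plus_tri)
      n_plus <- rbinom(1, k, 0.5)
      out <- list()
      if (n_plus > 0) {
        out$plus <- tibble::tibble(pos = take(plus_tri, n_plus),
                                   ref = ref_b, alt = alt_b)
      }
      if (k - n_plus > 0) {
        out$minus <- tibble::tibble(pos = take(minus_tri, k - n_plus),
                                    ref = COMP[[ref_b]], alt = COMP[[alt_b]])
      }
      dplyr::bind_rows(out)
    }) |> purrr::list_rbind()

    feats <- simulate_variant_records(
      n_true = n_mutations, n_artifact = n_artifact,
      thresholds = thresholds, seed = sample.int(2^31 - 1, 1)
    )
    feats$chrom <- contig
    feats$pos <- NA_integer_
    true_idx <- which(feats$truth == "true")
    feats$pos[true_idx] <- rows$pos
    feats$ref[true_idx] <- rows$ref
    feats$alt[true_idx] <- rows$alt
    art_idx <- which(feats$truth != "true")
    if (length(art_idx) > 0) {
      leftover <- sample(unlist(available), length(art_idx))
      feats$pos[art_idx] <- leftover
      feats$ref[art_idx] <- substr(seq, leftover, leftover)
      feats$alt[art_idx] <- vapply(feats$ref[art_idx], function(r)
        sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
    }
    feats <- dplyr::arrange(feats, .data$pos)
    truth_catalog <- tibble::tibble(
      sample_id = "truth", context = ctx,
      count = as.integer(class_counts)
    )
    list(variants = feats, truth_catalog = truth_catalog)
  })
}
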