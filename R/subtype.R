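#' Call AA Sig / No-AA Sig subtypes by hierarchical clustering
#'
#' Clusters samples on their merged signature exposures (the number of SNVs
#' attributed to each etiology group), cuts the tree at two clusters, and
#' labels the cluster with the larger mean AA-group exposure "AA Sig". The
#' default clusters `log1p`-transformed attributed counts with Euclidean
#' distance and Ward linkage, which is robust to the heavy-tailed count scale
#' of whole-genome catalogs; both choices are arguments.
#'
#' @param fit A merged `signature_fit` or tidy exposure tibble
#'   (`sample_id`, `signature`, `exposure`) containing an AA entry.
#' @param aa_label Label of the AA group.
#' @param transform One of `"log1p"` (default), `"proportion"` (rows summed
#'   to 1) or `"raw"`.
#' @param metric Distance measure passed to [stats::dist()].
#' @param linkage Agglomeration method passed to [stats::hclust()]
#'   (default `"ward.D2"`).
#' @return A tibble of subtype calls: `sample_id`, `label` (`"AA Sig"` /
#'   `"No-AA Sig"`), `aa_proportion`, `method = "clustering"`,
#'   `threshold_used` (`NA`), `indeterminate` (`FALSE`). The dendrogram leaf
#'   order is attached as attribute `"dendrogram_order"`.
#' @examples
#' cats <- dplyr::bind_rows(
#'   simulate_catalog(2000, c("Signature 22" = 0.7, "Signature 1" = 0.3),
#'                    seed = 1, sample_id = "s1"),
#'   simulate_catalog(2000, c("Signature 1" = 1), seed = 2, sample_id = "s2")
#' )
#' cluster_subtypes(merge_exposures(fit_exposures(cats)))
#' @export
cluster_subtypes <- function(fit, aa_label = "AA",
                             transform = c("log1p", "proportion", "raw"),
                             metric = "euclidean", linkage = "ward.D2") {
  transform <- match.arg(transform)
  exposures <- if (inherits(fit, "signature_fit")) fit$exposures else fit
  wide <- tidyr::pivot_wider(exposures, id_cols = "sample_id",
                             names_from = "signature",
                             values_from = "exposure", values_fill = 0)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$sample_id
  if (nrow(m) < 2) {
    abort("Clustering needs at least 2 samples; use classify_threshold() for single samples.")
  }
  if (!aa_label %in% colnames(m)) {
    abort(sprintf("No '%s' group among the exposures; merge first.", aa_label))
  }
  if (anyDuplicated(m) > 0) {
    abort("Two samples have identical exposure vectors; the dendrogram is degenerate.")
  }
  z <- switch(transform,
    log1p = log1p(m),
    proportion = m / rowSums(m),
    raw = m
  )
  hc <- hclust(dist(z, method = metric), method = linkage)
  cl <- cutree(hc, k = 2)
  aa_mean <- tapply(m[, aa_label], cl, mean)
  aa_cluster <- as.integer(names(aa_mean)[which.max(aa_mean)])
  calls <- tibble::tibble(
    sample_id = rownames(m),
    label = unname(ifelse(cl == aa_cluster, "AA Sig", "No-AA Sig")),
    aa_proportion = unname(m[, aa_label] / rowSums(m)),
    method = "clustering",
    threshold_used = NA_real_,
    indeterminate = FALSE
  )
  attr(calls, "dendrogram_order") <- rownames(m)[hc$order]
  calls
}

#' Call a subtype from the AA proportion alone
#'
#' Single-sample screening rule. In urinary cell-free DNA, an AA-attributed
#' proportion above `cfdna_high` (default 15%) calls AA Sig and below
#' `cfdna_low` (default 5%) calls No-AA Sig; proportions between the two
#' validated extremes are labelled No-AA Sig with `indeterminate = TRUE`. In
#' tumour tissue a single strict cutoff (`tumor_high`, default 50%) is used.
#'
#' @param aa_prop AA-attributed proportion(s) in `[0, 1]`, or a tibble from
#'   [aa_proportion()].
#' @param context `"tumor"` or `"cfdna"`.
#' @param thresholds A [screening_thresholds()] object.
#' @param sample_id Optional sample labels (when `aa_prop` is numeric).
#' @return A tibble of subtype calls: `sample_id`, `label`, `aa_proportion`,
#'   `method = "threshold"`, `threshold_used`, `indeterminate`.
#' @examples
#' classify_threshold(c(0.20, 0.04, 0.10), context = "cfdna")
#' @export
classify_threshold <- function(aa_prop, context = c("tumor", "cfdna"),
                               thresholds = screening_thresholds(),
                               sample_id = NULL) {
  context <- match.arg(context)
  if (is.data.frame(aa_prop)) {
    sample_id <- aa_prop$sample_id
    aa_prop <- aa_prop$aa_proportion
  }
  if (any(aa_prop < 0 | aa_prop > 1)) {
    abort("AA proportions must lie in [0, 1].")
  }
  sample_id <- sample_id %||% paste0("sample", seq_along(aa_prop))
  if (context == "cfdna") {
    label <- ifelse(aa_prop > thresholds$cfdna_high, "AA Sig", "No-AA Sig")
    indeterminate <- aa_prop <= thresholds$cfdna_high &
      aa_prop >= thresholds$cfdna_low
    threshold_used <- ifelse(aa_prop > thresholds$cfdna_high | indeterminate,
                             thresholds$cfdna_high, thresholds$cfdna_low)
  } else {
    label <- ifelse(aa_prop > thresholds$tumor_high, "AA Sig", "No-AA Sig")
    indeterminate <- rep(FALSE, length(aa_prop))
    threshold_used <- rep(thresholds$tumor_high, length(aa_prop))
  }
  tibble::tibble(sample_id = sample_id, label = label,
                 aa_proportion = aa_prop, method = "threshold",
                 threshold_used = threshold_used,
                 indeterminate = indeterminate)
}
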