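#' Assemble and validate a pipeline run configuration
#'
#' Collects every input path, mode and threshold for [run_pipeline()] and
#' validates it up front: referenced files must exist and the sample list
#' must be non-empty. Analysis starts either from per-sample candidate VCFs
#' plus a reference FASTA (the filter and catalog stages run) or directly
#' from a catalog table (refitting onward).
#'
#' @param vcfs Named character vector of per-sample VCF paths (names are
#'   sample ids), or `NULL` when starting from `catalogs`.
#' @param fasta Reference FASTA path (required with `vcfs`).
#' @param catalogs Path to a catalog TSV ([write_catalog()] layout), or
#'   `NULL`.
#' @param signatures Signature matrix: a tibble or TSV path; default
#'   [synthetic_signatures()].
#' @param merge_map Etiology merge map: tibble or YAML path; default
#'   [default_merge_map()].
#' @param clinical Optional clinical cohort CSV with a `subtype` column and,
#'   for survival output, `time`/`event`/`group` columns.
#' @param mode `"tumor"` (allele-frequency window on, clustering subtype
#'   calls), `"cfdna"` (window off, cfDNA screening thresholds) or
#'   `"low_coverage"` (window off, tumour threshold).
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed recorded in the manifest and used by any
#'   stochastic stage.
#' @param filter_thresholds,screening_thresholds Threshold bundles.
#' @param cluster_transform,cluster_metric,cluster_linkage Clustering options
#'   passed to [cluster_subtypes()].
#' @return A validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(vcfs = NULL, fasta = NULL, catalogs = NULL,
                            signatures = NULL, merge_map = NULL,
                            clinical = NULL,
                            mode = c("tumor", "cfdna", "low_coverage"),
                            out_dir, seed = 1,
                            filter_thresholds = aasig::filter_thresholds(),
                            screening_thresholds = aasig::screening_thresholds(),
                            cluster_transform = "log1p",
                            cluster_metric = "euclidean",
                            cluster_linkage = "ward.D2") {
  mode <- match.arg(mode)
  if (is.null(vcfs) && is.null(catalogs)) {
    abort("Provide either `vcfs` (with `fasta`) or `catalogs`.")
  }
  if (!is.null(vcfs)) {
    if (length(vcfs) == 0) abort("`vcfs` must name at least one sample.")
    if (is.null(names(vcfs)) || any(names(vcfs) == "")) {
      abort("`vcfs` must be a named vector: sample id -> path.")
    }
    if (is.null(fasta)) abort("`fasta` is required when starting from VCFs.")
  }
  for (p in c(unname(vcfs), fasta, catalogs, clinical,
              if (is.character(signatures)) signatures,
              if (is.character(merge_map)) merge_map)) {
    if (!file.exists(p)) abort(paste0("Input path does not exist: ", p))
  }
  structure(list(
    vcfs = vcfs, fasta = fasta, catalogs = catalogs,
    signatures = signatures, merge_map = merge_map, clinical = clinical,
    mode = mode, out_dir = out_dir, seed = seed,
    filter_thresholds = filter_thresholds,
    screening_thresholds = screening_thresholds,
    cluster_transform = cluster_transform,
    cluster_metric = cluster_metric,
    cluster_linkage = cluster_linkage,
    af_window = mode == "tumor"
  ), class = "pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  })
}

#' Run the full screening pipeline
#'
#' Orchestrates filter -> catalog -> refit -> merge -> subtype (-> clinical
#' statistics) over a cohort, writing every intermediate artifact with a
#' stable filename plus a JSON manifest recording the package version, seed,
#' mode, thresholds and an MD5 checksum per output. Re-running an identical
#' configuration reproduces identical files.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the subtype `calls`, the merged
#'   `exposures` fit, the `manifest` list and `out_dir`.
#' @examples
#' \donttest{
#' cats <- dplyr::bind_rows(
#'   simulate_catalog(5000, c("Signature 22" = 0.7, "Signature 5" = 0.3),
#'                    seed = 1, sample_id = "s1"),
#'   simulate_catalog(5000, c("Signature 5" = 1), seed = 2, sample_id = "s2")
#' )
#' tmp <- tempfile(); dir.create(tmp)
#' write_catalog(cats, file.path(tmp, "catalogs.tsv"))
#' cfg <- pipeline_config(catalogs = file.path(tmp, "catalogs.tsv"),
#'                        out_dir = file.path(tmp, "out"))
#' run <- run_pipeline(cfg)
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  written <- character(0)
  note <- function(path) { written <<- c(written, path); path }

  signatures <- run_stage("load_signatures", {
    s <- config$signatures %||% synthetic_signatures()
    if (is.character(s)) s <- read_signature_matrix(s)
    validate_signatures(s)
  })
  merge_map <- run_stage("load_merge_map", {
    m <- config$merge_map %||% default_merge_map()
    if (is.character(m)) m <- read_merge_map(m)
    m
  })

  if (!is.null(config$vcfs)) {
    catalog <- run_stage("filter_and_catalog", {
      reference <- Biostrings::readDNAStringSet(config$fasta)
      names(reference) <- sub("\\s.*$", "", names(reference))
      per_sample <- purrr::imap(config$vcfs, function(path, sid) {
        variants <- read_variant_vcf(path)
        report <- filter_variants(variants, config$filter_thresholds,
                                  af_window = config$af_window)
        message(sprintf("[filter] %s: %d in, %d retained", sid,
                        report$n_input, nrow(report$retained)))
        write_variant_vcf(report$retained,
                          note(out(sprintf("filtered_%s.vcf", sid))))
        list(report = report,
             catalog = build_catalog(report$retained, reference,
                                     sample_id = sid))
      })
      rejections <- purrr::imap(per_sample, function(x, sid) {
        dplyr::mutate(x$report$rule_counts, sample_id = sid, .before = 1)
      }) |> purrr::list_rbind()
      readr::write_tsv(rejections, note(out("rejection_summary.tsv")),
                       progress = FALSE)
      purrr::map(per_sample, "catalog") |> purrr::list_rbind()
    })
  } else {
    catalog <- run_stage("load_catalogs", read_catalog(config$catalogs))
  }
  write_catalog(catalog, note(out("catalogs.tsv")))
  message(sprintf("[catalog] %d sample(s), %d SNVs total",
                  length(unique(catalog$sample_id)), sum(catalog$count)))

  fit <- run_stage("refit", fit_exposures(catalog, signatures))
  write_exposures(fit, note(out("exposures_raw.tsv")))
  merged <- run_stage("merge", merge_exposures(fit, merge_map))
  write_exposures(merged, note(out("exposures_merged.tsv")))

  calls <- run_stage("subtype", {
    n_samples <- length(unique(catalog$sample_id))
    if (config$mode == "tumor" && n_samples >= 2) {
      calls <- cluster_subtypes(merged,
                                transform = config$cluster_transform,
                                metric = config$cluster_metric,
                                linkage = config$cluster_linkage)
      writeLines(attr(calls, "dendrogram_order"),
                 note(out("dendrogram_order.txt")))
      calls
    } else {
      ctx <- if (config$mode == "cfdna") "cfdna" else "tumor"
      classify_threshold(aa_proportion(merged), context = ctx,
                         thresholds = config$screening_thresholds)
    }
  })
  readr::write_tsv(calls, note(out("subtypes.tsv")), progress = FALSE)
  message(sprintf("[subtype] %d AA Sig / %d No-AA Sig",
                  sum(calls$label == "AA Sig"),
                  sum(calls$label == "No-AA Sig")))

  if (!is.null(config$clinical)) {
    run_stage("clinical", {
      cohort <- readr::read_csv(config$clinical, show_col_types = FALSE,
                                progress = FALSE)
      readr::write_tsv(build_table_one(cohort), note(out("table_one.tsv")),
                       progress = FALSE)
      if (all(c("time", "event", "group") %in% names(cohort))) {
        readr::write_tsv(km_estimate(cohort), note(out("km_curves.tsv")),
                         progress = FALSE)
        readr::write_tsv(logrank_test(cohort), note(out("logrank.tsv")),
                         progress = FALSE)
      }
    })
  }

  manifest <- list(
    package = "aasig",
    version = as.character(packageVersion("aasig")),
    seed = config$seed,
    mode = config$mode,
    thresholds = list(filter = unclass(config$filter_thresholds),
                      screening = unclass(config$screening_thresholds)),
    files = as.list(setNames(unname(tools::md5sum(sort(written))),
                             basename(sort(written))))
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(calls = calls, exposures = merged, manifest = manifest,
                 out_dir = config$out_dir))
}
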