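#' A synthetic COSMIC-style reference signature matrix
#'
#' Generates a deterministic 96 x 30 column-stochastic matrix laid out like
#' the COSMIC v2 signature set. It is a synthetic stand-in, not the COSMIC
#' download: a handful of columns are shaped after well-characterised
#' mutational processes so that recovery experiments are biologically
#' meaningful — most importantly "Signature 22", which concentrates ~3/4 of
#' its mass on T>A transversions (the aristolochic acid imprint, peaked at
#' C[T>A]G), plus a clock-like C>T-at-CpG column ("Signature 1"), APOBEC-like
#' TpC columns ("Signature 2"/"Signature 13"), a flat column ("Signature 5")
#' and a C>A-heavy tobacco-like column ("Signature 4"). The remaining columns
#' are sparse random profiles, fixed once by an internal seed so the matrix is
#' identical in every session.
#'
#' @param n_signatures Number of columns (default 30, COSMIC v2 size).
#' @return A tibble: `context` plus one probability column per signature
#'   (`"Signature 1"` ... ), each column summing to 1.
#' @examples
#' sig <- synthetic_signatures()
#' colSums(sig[, -1])[1:3]
#' @export
synthetic_signatures <- function(n_signatures = 30) {
  ctx <- sbs96_contexts()
  sub <- sub("^.\\[(.+)\\].$", "\\1", ctx)
  f5 <- substr(ctx, 1, 1)
  f3 <- substr(ctx, 7, 7)

  peaked <- function(mask, strength, base) {
    w <- base
    w[mask] <- w[mask] + strength / sum(mask)
    w / sum(w)
  }
  probs <- withr::with_seed(104729, {
    m <- sapply(seq_len(n_signatures), function(k) {
      raw <- rexp(96)^3  # heavy-tailed -> sparse, distinct profiles
      raw / sum(raw)
    })
    flat <- rep(1 / 96, 96)
    if (n_signatures >= 1)
      m[, 1] <- peaked(sub == "C>T" & f3 == "G", 12, flat)
    if (n_signatures >= 2)
      m[, 2] <- peaked(sub == "C>T" & f5 == "T", 15, flat)
    if (n_signatures >= 4)
      m[, 4] <- peaked(sub == "C>A", 6, flat)
    if (n_signatures >= 5)
      m[, 5] <- flat
    if (n_signatures >= 13)
      m[, 13] <- peaked(sub == "C>G" & f5 == "T", 15, flat)
    if (n_signatures >= 22) {
      aa <- peaked(sub == "T>A", 10, flat)
      aa[ctx == "C[T>A]G"] <- aa[ctx == "C[T>A]G"] + 0.25
      m[, 22] <- aa / sum(aa)
    }
    m
  })
  colnames(probs) <- paste("Signature", seq_len(n_signatures))
  out <- tibble::as_tibble(probs)
  out <- dplyr::bind_cols(tibble::tibble(context = ctx), out)
  validate_signatures(out)
}

#' @keywords internal
validate_signatures <- function(signatures) {
  stopifnot(is.data.frame(signatures))
  if (!"context" %in% names(signatures)) {
    abort("Signature matrix must have a 'context' column.")
  }
  ctx <- sbs96_contexts()
  if (!setequal(signatures$context, ctx) || nrow(signatures) != 96) {
    abort("Signature matrix must have exactly the 96 canonical context rows.")
  }
  signatures <- signatures[match(ctx, signatures$context), , drop = FALSE]
  m <- as.matrix(signatures[, -match("context", names(signatures)), drop = FALSE])
  if (any(m < 0)) abort("Signature probabilities must be non-negative.")
  bad <- colnames(m)[abs(colSums(m) - 1) > 1e-6]
  if (length(bad) > 0) {
    abort(paste0("Signature column(s) do not sum to 1: ",
                 paste(bad, collapse = ", ")))
  }
  signatures
}

#' @keywords internal
signature_probs <- function(signatures) {
  signatures <- validate_signatures(signatures)
  m <- as.matrix(signatures[, -match("context", names(signatures)), drop = FALSE])
  rownames(m) <- signatures$context
  m
}

#' Read or write a signature probability matrix
#'
#' Tab-delimited, 96 labelled rows by K labelled columns, the COSMIC download
#' layout. On read, rows are reordered to the canonical context order and the
#' matrix is validated (non-negative, columns sum to 1). Files using the
#' COSMIC column `"Somatic Mutation Type"` as the row label are recognised.
#'
#' @param path File path.
#' @return `read_signature_matrix()` returns a validated signature tibble.
#' @export
read_signature_matrix <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  label_col <- intersect(c("context", "Somatic Mutation Type"), names(x))
  if (length(label_col) == 0) {
    abort("Signature matrix file needs a 'context' (or 'Somatic Mutation Type') column.")
  }
  x$context <- x[[label_col[1]]]
  x <- x[, c("context",
             setdiff(names(x)[vapply(x, is.numeric, logical(1))], "context"))]
  validate_signatures(x)
}

#' @rdname read_signature_matrix
#' @param signatures A signature tibble.
#' @export
write_signature_matrix <- function(signatures, path) {
  readr::write_tsv(validate_signatures(signatures), path, progress = FALSE)
  invisible(path)
}

#' The default etiology merge map
#'
#' Reference signatures are merged into 10 groups by shared proposed etiology;
#' the AA group contains exactly signature 22, the aristolochic acid
#' signature. The map is data, not code: supply your own tibble (or a YAML
#' file via [read_merge_map()]) to override.
#'
#' @return A tibble with columns `signature` and `group` covering 30
#'   signatures and 10 groups: AA, clock, APOBEC, MMR, tobacco, UV, POLE,
#'   TMZ, aflatoxin, other.
#' @examples
#' dplyr::count(default_merge_map(), group)
#' @export
default_merge_map <- function() {
  groups <- list(
    AA = 22, clock = c(1, 5), APOBEC = c(2, 13), MMR = c(6, 15, 20, 21, 26),
    tobacco = c(4, 29), UV = 7, POLE = 10, TMZ = 11, aflatoxin = 24
  )
  named <- tibble::tibble(
    signature = paste("Signature", unlist(groups)),
    group = rep(names(groups), lengths(groups))
  )
  rest <- setdiff(paste("Signature", 1:30), named$signature)
  dplyr::bind_rows(named, tibble::tibble(signature = rest, group = "other"))
}

#' Read or write an etiology merge map
#'
#' Stored as YAML `signature: group` pairs.
#'
#' @param path File path.
#' @export
read_merge_map <- function(path) {
  x <- yaml::read_yaml(path)
  tibble::tibble(signature = names(x), group = unname(unlist(x)))
}

#' @rdname read_merge_map
#' @param merge_map A tibble with columns `signature`, `group`.
#' @export
write_merge_map <- function(merge_map, path) {
  yaml::write_yaml(setNames(as.list(merge_map$group), merge_map$signature),
                   path)
  invisible(path)
}

#' Non-negative least squares by the Lawson-Hanson active-set method
#'
#' Solves `min ||A x - b||_2` subject to `x >= 0`. This is the numerical core
#' of signature refitting; the active-set iteration terminates in finitely
#' many steps and resolves degeneracy deterministically (largest-gradient
#' entry enters the passive set first).
#'
#' @param A Numeric matrix (m x n).
#' @param b Numeric vector (length m).
#' @param tol Dual feasibility tolerance.
#' @return Numeric vector `x` of length n.
#' @examples
#' A <- matrix(c(1, 0, 0, 1, 1, 1), 3)
#' nnls_fit(A, c(2, 1, 1))
#' @export
nnls_fit <- function(A, b, tol = 1e-10) {
  stopifnot(is.matrix(A), length(b) == nrow(A))
  n <- ncol(A)
  x <- numeric(n)
  passive <- logical(n)
  w <- drop(crossprod(A, b - A %*% x))
  outer_max <- 10L * n
  outer <- 0L
  while (any(!passive) && max(w[!passive]) > tol && outer < outer_max) {
    outer <- outer + 1L
    cand <- which(!passive)
    passive[cand[which.max(w[cand])]] <- TRUE
    repeat {
      s <- numeric(n)
      s[passive] <- qr.coef(qr(A[, passive, drop = FALSE]), b)
      s[is.na(s)] <- 0
      if (min(s[passive]) > tol) {
        x <- s
        break
      }
      drop_set <- passive & s <= tol
      alpha <- min(x[drop_set] / (x[drop_set] - s[drop_set]))
      x <- x + alpha * (s - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  pmax(x, 0)
}

#' Refit mutation catalogs onto reference signatures
#'
#' Attributes each sample's 96-context catalog to the reference signatures by
#' non-negative least squares: exposures are the non-negative combination of
#' signature profiles closest (in Euclidean norm) to the observed counts, in
#' mutation-count units. Per sample, the residual norm and the cosine
#' similarity between the catalog and its reconstruction are reported.
#'
#' @param catalog A catalog tibble (one or more samples).
#' @param signatures Signature tibble (default [synthetic_signatures()]).
#' @param zero_action What to do with an all-zero catalog: `"error"`
#'   (default) or `"zero"` (return all-zero exposures).
#' @return An object of class `"signature_fit"` with [tidy()] (per-sample,
#'   per-signature exposures) and [glance()] (per-sample totals, residual
#'   norm, reconstruction cosine) methods.
#' @examples
#' cat96 <- simulate_catalog(2000, c("Signature 22" = 0.6, "Signature 1" = 0.4), seed = 7)
#' fit <- fit_exposures(cat96)
#' glance(fit)
#' @export
fit_exposures <- function(catalog, signatures = synthetic_signatures(),
                          zero_action = c("error", "zero")) {
  zero_action <- match.arg(zero_action)
  probs <- signature_probs(signatures)
  counts <- catalog_matrix(catalog)
  fits <- lapply(colnames(counts), function(sid) {
    b <- counts[, sid]
    if (sum(b) == 0) {
      if (zero_action == "error") {
        abort(sprintf("Sample '%s' has an all-zero catalog; nothing to refit.", sid))
      }
      e <- setNames(numeric(ncol(probs)), colnames(probs))
      return(list(exposures = e, residual_norm = 0, cosine = NA_real_))
    }
    e <- nnls_fit(probs, b)
    recon <- drop(probs %*% e)
    list(
      exposures = setNames(e, colnames(probs)),
      residual_norm = sqrt(sum((b - recon)^2)),
      cosine = sum(b * recon) / (sqrt(sum(b^2)) * sqrt(sum(recon^2)))
    )
  })
  names(fits) <- colnames(counts)
  exposures <- purrr::imap(fits, function(f, sid) {
    tibble::tibble(sample_id = sid, signature = names(f$exposures),
                   exposure = unname(f$exposures))
  }) |> purrr::list_rbind()
  stats <- purrr::imap(fits, function(f, sid) {
    tibble::tibble(sample_id = sid, total = sum(counts[, sid]),
                   fitted_total = sum(f$exposures),
                   residual_norm = f$residual_norm,
                   reconstruction_cosine = f$cosine)
  }) |> purrr::list_rbind()
  structure(list(exposures = exposures, stats = stats,
                 signature_names = colnames(probs), merged = FALSE),
            class = "signature_fit")
}

#' @export
print.signature_fit <- function(x, ...) {
  kind <- if (x$merged) "merged group" else "signature"
  cat(sprintf("Signature refit: %d sample(s), %d %s(s)\n",
              nrow(x$stats), length(x$signature_names), kind))
  print(x$stats)
  invisible(x)
}

#' @describeIn fit_exposures Per-sample, per-signature exposures as a tibble.
#' @param x A `signature_fit`.
#' @param ... Unused.
#' @export
tidy.signature_fit <- function(x, ...) {
  x$exposures
}

#' @describeIn fit_exposures Per-sample fit diagnostics as a tibble.
#' @export
glance.signature_fit <- function(x, ...) {
  x$stats
}

#' Merge fitted exposures by shared etiology
#'
#' Sums exposures over the groups of a merge map (by default the 10-group
#' etiology map with AA = signature 22). Totals are conserved exactly.
#'
#' @param fit A `signature_fit` from [fit_exposures()].
#' @param merge_map Tibble with columns `signature`, `group`, covering every
#'   fitted signature exactly once.
#' @return A `signature_fit` over the merged groups.
#' @examples
#' cat96 <- simulate_catalog(2000, c("Signature 22" = 1), seed = 3)
#' merged <- merge_exposures(fit_exposures(cat96))
#' tidy(merged)
#' @export
merge_exposures <- function(fit, merge_map = default_merge_map()) {
  stopifnot(inherits(fit, "signature_fit"))
  if (anyDuplicated(merge_map$signature) > 0) {
    abort("Merge map lists a signature more than once.")
  }
  unmapped <- setdiff(fit$signature_names, merge_map$signature)
  if (length(unmapped) > 0) {
    abort(paste0("Merge map does not cover: ", paste(unmapped, collapse = ", ")))
  }
  group_levels <- unique(merge_map$group)
  merged <- fit$exposures |>
    dplyr::left_join(merge_map, by = "signature") |>
    dplyr::group_by(.data$sample_id,
                    group = factor(.data$group, levels = group_levels)) |>
    dplyr::summarise(exposure = sum(.data$exposure), .groups = "drop") |>
    tidyr::complete(.data$sample_id, .data$group, fill = list(exposure = 0)) |>
    dplyr::transmute(.data$sample_id, signature = as.character(.data$group),
                     .data$exposure)
  structure(list(exposures = merged, stats = fit$stats,
                 signature_names = group_levels, merged = TRUE),
            class = "signature_fit")
}

#' AA-attributed proportion of each sample's mutations
#'
#' The fraction of a sample's fitted mutation load attributed to the AA group
#' (signature 22) — the screening statistic thresholded by
#' [classify_threshold()].
#'
#' @param fit A `signature_fit` (merged or raw) or a tidy exposure tibble
#'   (`sample_id`, `signature`, `exposure`).
#' @param aa_label Label of the AA entry (default `"AA"`; use
#'   `"Signature 22"` on an unmerged fit).
#' @return Tibble with `sample_id` and `aa_proportion`.
#' @examples
#' cat96 <- simulate_catalog(2000, c("Signature 22" = 1), seed = 3)
#' aa_proportion(merge_exposures(fit_exposures(cat96)))
#' @export
aa_proportion <- function(fit, aa_label = "AA") {
  exposures <- if (inherits(fit, "signature_fit")) fit$exposures else fit
  stopifnot(all(c("sample_id", "signature", "exposure") %in% names(exposures)))
  if (!aa_label %in% exposures$signature) {
    abort(sprintf("No '%s' entry among the exposures; merge first or set `aa_label`.",
                  aa_label))
  }
  out <- exposures |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      total = sum(.data$exposure),
      aa = sum(.data$exposure[.data$signature == aa_label]),
      .groups = "drop"
    )
  if (any(out$total <= 0)) {
    abort(sprintf("Sample '%s' has zero total exposure; AA proportion undefined.",
                  out$sample_id[out$total <= 0][1]))
  }
  dplyr::transmute(out, .data$sample_id, aa_proportion = .data$aa / .data$total)
}

#' Write a tidy exposure table to TSV
#'
#' @param fit A `signature_fit` or tidy exposure tibble.
#' @param path Output path.
#' @export
write_exposures <- function(fit, path) {
  exposures <- if (inherits(fit, "signature_fit")) fit$exposures else fit
  wide <- tidyr::pivot_wider(exposures, names_from = "signature",
                             values_from = "exposure")
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}
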