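#' Pearson chi-square test on a contingency table
#'
#' Association test used for the clinical characteristics table: Pearson
#' chi-square *without* continuity correction, `df = (r-1)(c-1)`, p-value from
#' the upper tail.
#'
#' @param counts An r x c matrix, table or data frame of non-negative counts
#'   (levels x subtypes), r, c >= 2.
#' @return Tibble with `statistic`, `df`, `p_value`.
#' @examples
#' chi_square_test(matrix(c(21, 6, 34, 29), 2))  # sex by subtype
#' @export
chi_square_test <- function(counts) {
  m <- as.matrix(counts)
  if (!is.numeric(m) || any(m < 0)) {
    abort("Counts must be a non-negative numeric matrix.")
  }
  if (nrow(m) < 2 || ncol(m) < 2) {
    abort("Need at least a 2 x 2 table.")
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("Zero row or column marginal; expected counts are undefined.")
  }
  res <- suppressWarnings(chisq.test(m, correct = FALSE))
  tibble::tibble(statistic = unname(res$statistic),
                 df = unname(res$parameter),
                 p_value = unname(res$p.value))
}

#' @keywords internal
validate_survival_records <- function(records) {
  need <- c("time", "event")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    abort(paste0("Survival records missing columns: ", paste(miss, collapse = ", ")))
  }
  if (nrow(records) == 0) abort("Need at least one survival record.")
  if (any(records$time <= 0)) abort("Survival times must be positive.")
  records
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator of the survival function, right-censored at
#' `event = FALSE`, computed per group when a `group` column is present.
#'
#' @param records Tibble with `time` (months, > 0), `event` (logical or 0/1)
#'   and optionally `group`.
#' @return A tibble of the survival step function: `group`, `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`, including an anchor row at time 0 with
#'   survival 1 per group. Survival is non-increasing within group.
#' @examples
#' km_estimate(tibble::tibble(time = c(1, 2), event = c(TRUE, TRUE)))
#' @export
km_estimate <- function(records) {
  validate_survival_records(records)
  if (!"group" %in% names(records)) records$group <- "all"
  fits <- records |>
    dplyr::group_by(.data$group) |>
    dplyr::group_map(function(df, key) {
      sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = df)
      tibble::tibble(
        group = key$group,
        time = c(0, sf$time),
        n_risk = c(nrow(df), sf$n.risk),
        n_event = c(0, sf$n.event),
        n_censor = c(0, sf$n.censor),
        survival = c(1, sf$surv)
      )
    })
  dplyr::bind_rows(fits)
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square with 1 degree of freedom comparing the
#' survival experience of exactly two groups.
#'
#' @param records Tibble with `time`, `event` and a two-level `group` column;
#'   at least one event overall.
#' @return Tibble with `statistic` and `p_value`.
#' @examples
#' rec <- simulate_cohort(n_per_group = 30, hazard_ratio = 3, seed = 1)
#' logrank_test(rec)
#' @export
logrank_test <- function(records) {
  validate_survival_records(records)
  if (!"group" %in% names(records)) {
    abort("Log-rank comparison needs a 'group' column.")
  }
  groups <- unique(records$group)
  if (length(groups) != 2) {
    abort(sprintf("Log-rank test needs exactly 2 non-empty groups, got %d.",
                  length(groups)))
  }
  if (sum(records$event) < 1) abort("Need at least one event overall.")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = records)
  tibble::tibble(statistic = unname(sd$chisq),
                 p_value = pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' @keywords internal
format_pvalue <- function(p) {
  ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))
}

#' Clinical characteristics stratified by subtype ("table one")
#'
#' For each categorical covariate, renders level counts with within-column
#' percentages (`"16(59.3)"` style, 1 decimal place) overall and per subtype,
#' and an association p-value (Pearson chi-square without continuity
#' correction, 3 decimal places, `"<0.001"` below that) on the covariate's
#' first row. Covariates named in `kruskal` use the Kruskal-Wallis test on
#' the level order instead, as is conventional for ordered categories such as
#' CKD stage. Single-level covariates are tabulated without a p-value.
#'
#' @param cohort Tibble with one row per patient: a subtype column plus
#'   categorical covariates.
#' @param subtype Name of the subtype column (default `"subtype"`).
#' @param covariates Character vector of covariate columns; default all
#'   character/factor/logical columns except the subtype and `sample_id`.
#' @param kruskal Covariates to test by Kruskal-Wallis on the level order.
#' @return A tibble: `variable`, `level`, `overall`, one rendered column per
#'   subtype level, `p_value` (character).
#' @examples
#' cohort <- simulate_cohort(n_per_group = 40, seed = 1)
#' build_table_one(cohort)
#' @export
build_table_one <- function(cohort, subtype = "subtype", covariates = NULL,
                            kruskal = character(0)) {
  if (!subtype %in% names(cohort)) {
    abort(sprintf("Cohort has no '%s' column.", subtype))
  }
  if (is.null(covariates)) {
    is_cat <- vapply(cohort, function(x)
      is.character(x) || is.factor(x) || is.logical(x), logical(1))
    covariates <- setdiff(names(cohort)[is_cat], c(subtype, "sample_id"))
  }
  groups <- cohort[[subtype]]
  group_levels <- if (is.factor(groups)) levels(groups) else sort(unique(groups))
  n_total <- nrow(cohort)
  n_group <- vapply(group_levels, function(g) sum(groups == g), numeric(1))

  render <- function(n, denom) {
    denom <- rep_len(denom, length(n))
    ifelse(denom > 0, sprintf("%d(%.1f)", as.integer(n), 100 * n / denom),
           sprintf("%d", as.integer(n)))
  }
  purrr::map(covariates, function(v) {
    x <- cohort[[v]]
    lv <- if (is.factor(x)) levels(x) else sort(unique(as.character(x)))
    counts <- vapply(group_levels, function(g)
      vapply(lv, function(l) sum(x == l & groups == g), numeric(1)),
      numeric(length(lv)))
    counts <- matrix(counts, nrow = length(lv),
                     dimnames = list(lv, group_levels))
    p_chr <- ""
    if (length(lv) >= 2 && length(group_levels) >= 2 &&
        !any(colSums(counts) == 0)) {
      p <- if (v %in% kruskal) {
        stats::kruskal.test(as.integer(factor(x, levels = lv)), factor(groups))$p.value
      } else {
        chi_square_test(counts)$p_value
      }
      p_chr <- format_pvalue(p)
    }
    rows <- tibble::tibble(
      variable = v, level = lv,
      overall = render(rowSums(counts), n_total)
    )
    for (g in group_levels) {
      rows[[g]] <- render(counts[, g], n_group[[g]])
    }
    rows$p_value <- c(p_chr, rep("", length(lv) - 1))
    rows
  }) |> purrr::list_rbind()
}
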