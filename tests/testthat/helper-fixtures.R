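# Small fixtures shared across test files; everything is generated in code.

# a tiny two-signature matrix with disjoint support: uniform over C>A
# contexts versus uniform over T>G contexts
disjoint_signatures <- function() {
  ctx <- sbs96_contexts()
  sub <- sub("^.\\[(.+)\\].$", "\\1", ctx)
  tibble::tibble(
    context = ctx,
    sigA = ifelse(sub == "C>A", 1 / 16, 0),
    sigB = ifelse(sub == "T>G", 1 / 16, 0)
  )
}

# catalog with given named context counts, zero elsewhere
catalog_from_counts <- function(counts, sample_id = "s") {
  out <- tibble::tibble(sample_id = sample_id, context = sbs96_contexts(),
                        count = 0L)
  out$count[match(names(counts), out$context)] <- as.integer(counts)
  out
}

# expand a levels-by-subtype count matrix into a patient-level cohort tibble
cohort_from_counts <- function(counts, variable = "covariate") {
  rows <- expand.grid(level = rownames(counts), subtype = colnames(counts),
                      stringsAsFactors = FALSE)
  rows$n <- as.vector(counts)
  out <- rows[rep(seq_len(nrow(rows)), rows$n), c("level", "subtype")]
  names(out)[1] <- variable
  tibble::as_tibble(out)
}
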