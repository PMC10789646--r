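# Internal helpers shared across modules.

# iBAQ column name for a sample id, following the MaxQuant dialect
# "iBAQ <sample_id>".
ibaq_col <- function(sample_id) paste("iBAQ", sample_id)

# Samples of one condition, in replicate order.
condition_samples <- function(design, cond) {
  d <- design[design$condition == cond, , drop = FALSE]
  d$sample_id[order(d$replicate)]
}

# Extract the groups x samples iBAQ matrix from an entries/groups tibble.
ibaq_matrix <- function(entries, design) {
  cols <- ibaq_col(design$sample_id)
  missing <- setdiff(cols, names(entries))
  if (length(missing) > 0) {
    abort(paste0(
      "missing iBAQ column(s) for designed sample(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  m <- as.matrix(entries[, cols, drop = FALSE])
  colnames(m) <- design$sample_id
  m
}

# Representative accession of an entry: first token of the semicolon-joined
# protein id string.
representative_accession <- function(protein_ids) {
  vapply(strsplit(protein_ids, ";", fixed = TRUE), `[[`, character(1), 1L)
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# state; a NULL seed uses (and advances) the current stream.
with_seed_or_current <- function(seed, expr) {
  if (is.null(seed)) {
    force(expr)
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}
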