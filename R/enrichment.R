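# riBAQ normalization and +/-UV enrichment classification.
#
# A group is "present" in a condition when its pooled iBAQ is strictly
# positive in every replicate of that condition. riBAQ is computed per
# sample over the groups present in that sample's condition, so every sample
# column is compositional (sums to 1).

#' Compute riBAQ values under the both-replicates presence rule
#'
#' For each condition, a group is retained when it has iBAQ > 0 in every
#' replicate of that condition; groups present in neither condition are
#' dropped. Within each sample, riBAQ of a retained group is its iBAQ
#' divided by the summed iBAQ of all groups retained for that sample's
#' condition; groups not retained for the condition get riBAQ 0. Every sample
#' column therefore sums to 1 over retained groups.
#'
#' @param groups Groups tibble from [group_proteins()] (or an entries tibble
#'   with the same iBAQ columns).
#' @param design Sample design tibble with at least two replicates per
#'   condition.
#' @return A tibble with one row per retained group: `group_id` (generated if
#'   absent), `representative` (if present in input), one riBAQ column per
#'   sample (named by `sample_id`), and logical presence/zero flags
#'   `present_plus`, `present_minus`, `zero_plus`, `zero_minus` used by
#'   [classify_enrichment()].
#' @export
compute_ribaq <- function(groups, design) {
  design <- validate_sample_design(design)
  for (cond in c("plusUV", "minusUV")) {
    if (length(condition_samples(design, cond)) < 2) {
      abort(sprintf("condition %s needs at least 2 replicates", cond))
    }
  }
  m <- ibaq_matrix(groups, design)
  plus_s <- condition_samples(design, "plusUV")
  minus_s <- condition_samples(design, "minusUV")

  present_plus <- rowSums(m[, plus_s, drop = FALSE] > 0) == length(plus_s)
  present_minus <- rowSums(m[, minus_s, drop = FALSE] > 0) == length(minus_s)
  zero_plus <- rowSums(m[, plus_s, drop = FALSE] != 0) == 0
  zero_minus <- rowSums(m[, minus_s, drop = FALSE] != 0) == 0

  keep <- present_plus | present_minus
  out <- tibble::tibble(
    group_id = if ("group_id" %in% names(groups)) groups$group_id else
      sprintf("G%05d", seq_len(nrow(groups)))
  )
  if ("representative" %in% names(groups)) out$representative <- groups$representative
  for (s in design$sample_id) {
    present_cond <- if (s %in% plus_s) present_plus else present_minus
    denom <- sum(m[present_cond, s])
    if (denom <= 0) {
      abort(sprintf("degenerate sample %s: retained-group intensity sum is 0", s))
    }
    out[[s]] <- ifelse(present_cond, m[, s] / denom, 0)
  }
  out$present_plus <- present_plus
  out$present_minus <- present_minus
  out$zero_plus <- zero_plus
  out$zero_minus <- zero_minus
  out[keep, , drop = FALSE]
}

#' Per-condition mean riBAQ
#'
#' Arithmetic mean of riBAQ across the replicates of each condition; groups
#' excluded from a condition have mean 0 there.
#'
#' @param ribaq riBAQ tibble from [compute_ribaq()].
#' @param design Sample design tibble.
#' @return A tibble with columns `group_id`, `mean_plus`, `mean_minus`.
#' @export
condition_means <- function(ribaq, design) {
  design <- validate_sample_design(design)
  plus_s <- condition_samples(design, "plusUV")
  minus_s <- condition_samples(design, "minusUV")
  tibble::tibble(
    group_id = ribaq$group_id,
    mean_plus = rowMeans(as.matrix(ribaq[, plus_s, drop = FALSE])),
    mean_minus = rowMeans(as.matrix(ribaq[, minus_s, drop = FALSE]))
  )
}

#' Fold enrichment and t-test p-value for one group
#'
#' Fold enrichment is the ratio of condition means on the linear scale. The
#' p-value comes from a two-sided two-sample t-test (pooled-variance Student's test by
#' default, or Welch's unequal-variance test), computed on log2-transformed riBAQ when
#' `log_transform` is `TRUE` (the default; log2 stabilizes the multiplicative
#' replicate noise). When both groups of values are constant the test is
#' degenerate: equal means give p = 1, unequal means give the smallest
#' representable positive p.
#'
#' @param plus_values,minus_values Strictly positive riBAQ values of the +UV
#'   and -UV replicates (length >= 2 each).
#' @param log_transform Test on log2 values (default `TRUE`).
#' @param test `"student"` (default) or `"welch"`.
#' @return A tibble with columns `fold_enrichment`, `log2_fc`, `p_value`.
#' @export
test_enrichment <- function(plus_values, minus_values, log_transform = TRUE,
                            test = c("student", "welch")) {
  test <- match.arg(test)
  if (length(plus_values) < 2 || length(minus_values) < 2) {
    abort("at least 2 replicate values per condition are required")
  }
  if (any(plus_values <= 0) || any(minus_values <= 0)) {
    abort("test_enrichment requires strictly positive values; route exclusive groups separately")
  }
  fold <- mean(plus_values) / mean(minus_values)
  x <- if (log_transform) log2(plus_values) else plus_values
  y <- if (log_transform) log2(minus_values) else minus_values
  p <- tryCatch(
    t.test(x, y, var.equal = (test == "student"))$p.value,
    error = function(e) {
      # both samples constant: t-test undefined
      if (isTRUE(all.equal(mean(x), mean(y)))) 1 else .Machine$double.xmin
    }
  )
  tibble::tibble(
    fold_enrichment = fold,
    log2_fc = log2(fold),
    p_value = p
  )
}

#' Classify groups into the exclusive/common/enriched partition
#'
#' Implements the +/-UV interactome calls: a group detected in every +UV
#' replicate and with iBAQ 0 in every -UV replicate is `exclusive_plus`
#' (and symmetrically `exclusive_minus`); groups present in both conditions
#' are "common" and receive a fold enrichment and t-test p-value from
#' [test_enrichment()] on their per-replicate riBAQ. Common groups are called
#' `common_enriched` when `p <= p_threshold` and fold >= `fc_threshold`,
#' `common_depleted` when `p <= p_threshold` and fold <= 1/`fc_threshold`,
#' otherwise `common_ns`. Groups present in only one condition but with a
#' nonzero intensity in some opposite-condition replicate are neither
#' exclusive nor testable and fall into `common_ns` with `NA` fold and p.
#'
#' @param ribaq riBAQ tibble from [compute_ribaq()].
#' @param design Sample design tibble.
#' @param p_threshold Significance level on the (optionally adjusted)
#'   p-value; default 0.05.
#' @param fc_threshold Linear fold-change cutoff; default 2.
#' @param log_transform,test Passed to [test_enrichment()].
#' @param p_adjust Multiple-testing adjustment for the common-group p-values
#'   before thresholding: `"none"` (default, matching the raw p <= 0.05 rule)
#'   or `"BH"`.
#' @return A tibble with columns `group_id`, `representative` (if available),
#'   `mean_plus`, `mean_minus`, `fold_enrichment`, `log2_fc`, `p_value`, and
#'   `category` (factor with levels `exclusive_plus`, `exclusive_minus`,
#'   `common_enriched`, `common_depleted`, `common_ns`).
#' @export
classify_enrichment <- function(ribaq, design, p_threshold = 0.05,
                                fc_threshold = 2, log_transform = TRUE,
                                test = c("student", "welch"),
                                p_adjust = c("none", "BH")) {
  test <- match.arg(test)
  p_adjust <- match.arg(p_adjust)
  stopifnot_scalar_number(p_threshold, "p_threshold")
  if (p_threshold <= 0 || p_threshold >= 1) abort("p_threshold must be in (0, 1)")
  if (fc_threshold < 1) abort("fc_threshold must be >= 1")
  design <- validate_sample_design(design)
  plus_s <- condition_samples(design, "plusUV")
  minus_s <- condition_samples(design, "minusUV")

  means <- condition_means(ribaq, design)
  n <- nrow(ribaq)
  category <- character(n)
  fold <- rep(NA_real_, n)
  p <- rep(NA_real_, n)

  excl_plus <- ribaq$present_plus & ribaq$zero_minus
  excl_minus <- ribaq$present_minus & ribaq$zero_plus
  common <- ribaq$present_plus & ribaq$present_minus
  category[excl_plus] <- "exclusive_plus"
  category[excl_minus] <- "exclusive_minus"
  category[!excl_plus & !excl_minus & !common] <- "common_ns"

  pm <- as.matrix(ribaq[, plus_s, drop = FALSE])
  mm <- as.matrix(ribaq[, minus_s, drop = FALSE])
  for (i in which(common)) {
    r <- test_enrichment(pm[i, ], mm[i, ], log_transform = log_transform, test = test)
    fold[i] <- r$fold_enrichment
    p[i] <- r$p_value
  }
  p_eff <- p
  if (p_adjust == "BH") p_eff[common] <- p.adjust(p[common], method = "BH")
  category[common] <- dplyr::case_when(
    p_eff[common] <= p_threshold & fold[common] >= fc_threshold ~ "common_enriched",
    p_eff[common] <= p_threshold & fold[common] <= 1 / fc_threshold ~ "common_depleted",
    TRUE ~ "common_ns"
  )

  out <- tibble::tibble(
    group_id = ribaq$group_id,
    mean_plus = means$mean_plus,
    mean_minus = means$mean_minus,
    fold_enrichment = fold,
    log2_fc = log2(fold),
    p_value = p,
    category = factor(category, levels = c(
      "exclusive_plus", "exclusive_minus",
      "common_enriched", "common_depleted", "common_ns"
    ))
  )
  if ("representative" %in% names(ribaq)) {
    out <- dplyr::mutate(out, representative = ribaq$representative,
                         .after = "group_id")
  }
  out
}

#' Venn counts over enrichment categories
#'
#' @param records Records tibble from [classify_enrichment()].
#' @return A one-row tibble with `n_exclusive_plus`, `n_exclusive_minus`,
#'   `n_common` (all common categories) and `n_common_enriched`.
#' @export
venn_counts <- function(records) {
  cat <- as.character(records$category)
  tibble::tibble(
    n_exclusive_plus = sum(cat == "exclusive_plus"),
    n_exclusive_minus = sum(cat == "exclusive_minus"),
    n_common = sum(cat %in% c("common_enriched", "common_depleted", "common_ns")),
    n_common_enriched = sum(cat == "common_enriched")
  )
}

#' Volcano-plot table
#'
#' One row per common-category record with a finite fold enrichment and
#' p-value; exclusive records (no finite fold/p) are omitted. Sorted by
#' ascending p-value.
#'
#' @param records Records tibble from [classify_enrichment()].
#' @return A tibble with columns `group_id`, `log2_fc`, `neg_log10_p`,
#'   `category`.
#' @export
volcano_table <- function(records) {
  common <- records[grepl("^common_", records$category) &
                      is.finite(records$log2_fc) &
                      is.finite(records$p_value), , drop = FALSE]
  out <- tibble::tibble(
    group_id = common$group_id,
    log2_fc = common$log2_fc,
    neg_log10_p = -log10(common$p_value),
    category = common$category
  )
  dplyr::arrange(out, dplyr::desc(.data$neg_log10_p))
}
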