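design4 <- toy_design()

test_that("riBAQ normalizes each sample over retained groups", {
  # three groups, present everywhere, iBAQ 60/30/10 in every sample
  ib <- matrix(rep(c(60, 30, 10), 4), 3, 4,
               dimnames = list(NULL, design4$sample_id))
  entries <- make_entries(list("a", "b", "c"), ib)
  rb <- compute_ribaq(entries, design4)
  for (s in design4$sample_id) expect_equal(rb[[s]], c(0.6, 0.3, 0.1))

  # present in +UV rep1 but 0 in rep2: excluded from the +UV columns
  ib2 <- ib
  ib2[2, "p2"] <- 0
  rb2 <- compute_ribaq(make_entries(list("a", "b", "c"), ib2), design4)
  expect_equal(rb2$p1[2], 0)
  expect_equal(rb2$p2[2], 0)
  expect_false(rb2$present_plus[2])
  expect_true(rb2$present_minus[2])
  # the others renormalize over the retained set
  expect_equal(rb2$p1, c(60 / 70, 0, 10 / 70))

  # a single retained group gets riBAQ 1
  ib3 <- matrix(c(42, 40, 41, 39), 1, 4,
                dimnames = list(NULL, design4$sample_id))
  rb3 <- compute_ribaq(make_entries(list("z"), ib3), design4)
  expect_equal(unlist(rb3[1, design4$sample_id]), rep(1, 4),
               ignore_attr = TRUE)
})

test_that("riBAQ columns sum to 1 and are invariant to per-sample scaling", {
  sim <- simulate_proteomics(n_background = 120, n_true_interactors = 10,
                             n_exclusive_plus = 5, seed = 21)
  groups <- group_proteins(filter_entries(sim$entries)$kept)
  rb <- compute_ribaq(groups, sim$design)
  for (s in sim$design$sample_id) {
    expect_equal(sum(rb[[s]]), 1, tolerance = 1e-9)
  }
  # multiply one sample's iBAQ by a constant: riBAQ, folds, p unchanged
  scaled <- groups
  scaled[["iBAQ p1"]] <- scaled[["iBAQ p1"]] * 37.5
  rb_scaled <- compute_ribaq(scaled, sim$design)
  expect_equal(rb_scaled, rb, tolerance = 1e-12)
  rec <- classify_enrichment(rb, sim$design)
  rec_scaled <- classify_enrichment(rb_scaled, sim$design)
  expect_equal(rec_scaled$fold_enrichment, rec$fold_enrichment,
               tolerance = 1e-12)
  expect_equal(rec_scaled$p_value, rec$p_value, tolerance = 1e-12)
})

test_that("condition means average replicates and are 0 for excluded conditions", {
  rb <- make_ribaq_row("G1", 0.02, 0.04, 0, 0)
  m <- condition_means(rb, design4)
  expect_equal(m$mean_plus, 0.03)
  expect_equal(m$mean_minus, 0)
  # equal replicates: mean equals the common value
  rb2 <- make_ribaq_row("G2", 0.05, 0.05, 0.01, 0.01)
  m2 <- condition_means(rb2, design4)
  expect_equal(m2$mean_plus, 0.05)
  expect_equal(m2$mean_minus, 0.01)
})

test_that("test_enrichment computes linear fold and a sane t-test", {
  # identical lists: fold 1, p 1
  r <- test_enrichment(c(0.02, 0.03), c(0.02, 0.03))
  expect_equal(r$fold_enrichment, 1)
  expect_equal(r$p_value, 1)

  # arithmetic of the fold
  r2 <- test_enrichment(c(0.02, 0.02), c(0.005, 0.005))
  expect_equal(r2$fold_enrichment, 4)
  expect_equal(r2$log2_fc, 2)

  expect_error(test_enrichment(c(0.02, 0), c(0.01, 0.01)), "positive")
  expect_error(test_enrichment(0.02, c(0.01, 0.01)), "2 replicate")

  # null calibration: empirical type-I error near the nominal level
  withr::with_seed(123, {
    p <- replicate(1000, {
      test_enrichment(exp(rnorm(2)), exp(rnorm(2)))$p_value
    })
  })
  expect_gte(mean(p <= 0.05), 0.03)
  expect_lte(mean(p <= 0.05), 0.07)
})

test_that("classification implements the exclusive/common partition rules", {
  rb <- dplyr::bind_rows(
    make_ribaq_row("excl_plus", 0.02, 0.03, 0, 0),
    make_ribaq_row("excl_minus", 0, 0, 0.02, 0.03),
    make_ribaq_row("enriched", 0.040, 0.041, 0.0100, 0.0101),
    make_ribaq_row("depleted", 0.0100, 0.0101, 0.040, 0.041),
    make_ribaq_row("flat", 0.020, 0.021, 0.0198, 0.0205),
    make_ribaq_row("big_fold_no_p", 0.060, 0.0001, 0.010, 0.010),
    make_ribaq_row("partial", 0.02, 0.03, 0.01, 0) # present +, partial -
  )
  rec <- classify_enrichment(rb, design4)
  got <- setNames(as.character(rec$category), rec$group_id)
  expect_equal(got[["excl_plus"]], "exclusive_plus")
  expect_equal(got[["excl_minus"]], "exclusive_minus")
  expect_equal(got[["enriched"]], "common_enriched")
  expect_equal(got[["depleted"]], "common_depleted")
  expect_equal(got[["flat"]], "common_ns")
  # large fold but hopeless variance: not significant
  expect_equal(got[["big_fold_no_p"]], "common_ns")
  # ambiguous partial detection: neither exclusive nor testable
  expect_equal(got[["partial"]], "common_ns")
  expect_true(is.na(rec$p_value[rec$group_id == "partial"]))

  # categories partition the analyzed groups
  expect_false(any(is.na(rec$category)))
  vc <- venn_counts(rec)
  expect_equal(vc$n_exclusive_plus + vc$n_exclusive_minus + vc$n_common,
               nrow(rec))
})

test_that("venn counts and volcano table follow their contracts", {
  empty <- classify_enrichment(
    make_ribaq_row("G1", 0.5, 0.5, 0.5, 0.5)[0, ], design4)
  expect_equal(unlist(venn_counts(empty)), c(
    n_exclusive_plus = 0, n_exclusive_minus = 0,
    n_common = 0, n_common_enriched = 0
  ))

  records <- tibble::tibble(
    group_id = c("a", "b", "c"),
    mean_plus = c(0.04, 0.02, 0.01),
    mean_minus = c(0.01, 0.02, 0),
    fold_enrichment = c(4, 1, NA),
    log2_fc = log2(c(4, 1, NA)),
    p_value = c(0.01, 1, NA),
    category = factor(c("common_enriched", "common_ns", "exclusive_plus"),
                      levels = levels(classify_enrichment(
                        make_ribaq_row("x", 0.5, 0.5, 0.25, 0.25),
                        design4)$category))
  )
  v <- volcano_table(records)
  # exclusive records are omitted; sorted by ascending p
  expect_equal(v$group_id, c("a", "b"))
  expect_equal(v$log2_fc[1], 2)
  expect_equal(v$neg_log10_p[1], 2)
  expect_equal(v$neg_log10_p[2], 0)
})

test_that("degenerate samples are fatal", {
  ib <- matrix(c(0, 0, 5, 5), 1, 4,
               dimnames = list(NULL, design4$sample_id))
  entries <- make_entries(list("a"), ib)
  # only group absent from +UV: +UV columns have no retained group
  expect_error(compute_ribaq(entries, design4), "degenerate")
})
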