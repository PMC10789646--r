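peaks_tbl <- function(chrom, start, end) {
  tibble::tibble(chrom = chrom, start = start, end = end)
}

random_peaks <- function(n, genome_size = 1e6, max_width = 800) {
  width <- sample(50:max_width, n, replace = TRUE)
  start <- floor(runif(n) * (genome_size - width))
  dplyr::arrange(peaks_tbl("chr1", start, start + width), start)
}

test_that("overlap_fraction counts anchor peaks with >= 1 bp intersection", {
  a <- peaks_tbl("chr1", c(100, 500, 900), c(200, 600, 1000))
  inside <- peaks_tbl("chr1", 50, 300)
  expect_equal(overlap_fraction(peaks_tbl("chr1", 120, 180), inside), 1)
  # disjoint chromosomes
  expect_equal(overlap_fraction(a, peaks_tbl("chr2", 100, 200)), 0)
  # 2 of 3 anchors overlap
  other <- peaks_tbl("chr1", c(150, 950), c(160, 960))
  expect_equal(overlap_fraction(a, other), 2 / 3)
  # self overlap is always 1; merging the other set changes nothing
  expect_equal(overlap_fraction(a, a), 1)
  expect_equal(overlap_fraction(a, merge_peaks(other)),
               overlap_fraction(a, other))
  # half-open intervals: touching end/start do not overlap
  expect_equal(overlap_fraction(peaks_tbl("chr1", 0, 100),
                                peaks_tbl("chr1", 100, 200)), 0)
  expect_error(overlap_fraction(a[0, ], a), "empty")
})

test_that("venn3 classifies per anchor and all perspectives sum to set sizes", {
  a <- peaks_tbl("chr1", c(0, 1000, 2000), c(100, 1100, 2100))
  # identical sets: everything in the triple region
  v_same <- venn3(a, a, a)
  both_a <- v_same[v_same$anchor == "a" & v_same$region == "both", ]
  expect_equal(both_a$n, 3)
  # pairwise disjoint: everything anchor-only
  b <- peaks_tbl("chr1", 5000, 5100)
  c3 <- peaks_tbl("chr2", 0, 100)
  v_dis <- venn3(a, b, c3)
  expect_equal(v_dis$n[v_dis$anchor == "a" & v_dis$region == "neither"], 3)
  for (anchor in c("a", "b", "c")) {
    sizes <- c(a = 3L, b = 1L, c = 1L)
    expect_equal(sum(v_dis$n[v_dis$anchor == anchor]), sizes[[anchor]],
                 ignore_attr = TRUE)
  }
})

test_that("overlap and venn3 match the quadratic per-peak oracle on random sets", {
  for (seed in 1:15) {
    withr::with_seed(seed, {
      a <- random_peaks(sample(20:200, 1))
      b <- random_peaks(sample(20:200, 1))
      c3 <- random_peaks(sample(20:200, 1))
    })
    expect_equal(overlap_fraction(a, b), oracle_overlap_fraction(a, b))
    v <- venn3(a, b, c3, names = c("A", "B", "C"))
    expect_equal(v$n[v$anchor == "A"], oracle_venn_counts(a, b, c3))
    expect_equal(v$n[v$anchor == "B"], oracle_venn_counts(b, a, c3))
    expect_equal(v$n[v$anchor == "C"], oracle_venn_counts(c3, a, b))
  }
})

test_that("tss_matrix handles constants, strand mirroring and edge padding", {
  lens <- c(chr1 = 10000)
  const <- signal_track(list(chr1 = rep(2.5, 200)), 50, lens)
  tss <- tibble::tibble(chrom = "chr1", pos = c(3000, 5000, 7000))
  tm <- tss_matrix(const, tss, flank = 1000, bin_size = 50)
  expect_equal(dim(tm$matrix), c(3, 40))
  expect_true(all(tm$matrix == 2.5))
  # stable sort keeps input order on ties
  expect_equal(rownames(tm$matrix), c("tss_1", "tss_2", "tss_3"))

  # asymmetric bump: a minus-strand TSS sees the mirror of the plus row
  vals <- rep(0, 200)
  vals[61:70] <- 1 # [3000, 3500)
  bump <- signal_track(list(chr1 = vals), 50, lens)
  tss2 <- tibble::tibble(chrom = "chr1", pos = c(3100, 3100),
                         strand = c("+", "-"))
  tm2 <- tss_matrix(bump, tss2, flank = 1000, bin_size = 50)
  expect_equal(unname(tm2$matrix["tss_2", ]), rev(unname(tm2$matrix["tss_1", ])))

  # windows past the chromosome end are zero-padded and flagged
  tss3 <- tibble::tibble(chrom = "chr1", pos = 9900)
  tm3 <- tss_matrix(const, tss3, flank = 1000, bin_size = 50)
  expect_true(tm3$edge_flagged[1])
  expect_lt(mean(tm3$matrix[1, ]), 2.5)
  # unknown chromosomes are dropped with a warning and counted
  expect_warning(
    tm4 <- tss_matrix(const, tibble::tibble(chrom = c("chr1", "chrX"),
                                            pos = c(5000, 100))),
    "unknown"
  )
  expect_equal(tm4$n_dropped, 1)
  expect_equal(nrow(tm4$matrix) + tm4$n_dropped, 2)
})

test_that("tss_matrix equals the naive per-bp oracle on random tracks", {
  for (seed in 1:8) {
    withr::with_seed(seed, {
      lens <- c(chr1 = 20000)
      track <- signal_track(list(chr1 = rnorm(400)), 50, lens)
      tss <- tibble::tibble(
        chrom = "chr1",
        pos = sample(0:19999, 5),
        strand = sample(c("+", "-"), 5, replace = TRUE)
      )
    })
    tm <- tss_matrix(track, tss, flank = 500, bin_size = 50)
    mo <- oracle_tss_matrix(track, tss, flank = 500, bin_size = 50)
    # compare before sorting: re-sort oracle rows the same way
    ord <- order(-rowMeans(mo))
    expect_equal(unname(tm$matrix), mo[ord, , drop = FALSE], tolerance = 1e-12)
    # mean profile is the column mean
    expect_equal(tm$profile$mean_signal, unname(colMeans(mo)), tolerance = 1e-12)
  }
})

test_that("signal_correlation is symmetric with unit diagonal and flags flat tracks", {
  lens <- c(chr1 = 5000)
  withr::with_seed(4, v <- rnorm(100))
  t1 <- signal_track(list(chr1 = v), 50, lens)
  t2 <- signal_track(list(chr1 = -v), 50, lens)
  m <- signal_correlation(list(x = t1, neg = t2))
  expect_equal(m["x", "x"], 1)
  expect_equal(m["x", "neg"], -1)
  expect_equal(m, t(m))

  flat <- signal_track(list(chr1 = rep(1, 100)), 50, lens)
  expect_warning(m2 <- signal_correlation(list(x = t1, flat = flat)),
                 "zero-variance")
  expect_true(is.na(m2["x", "flat"]))
  expect_equal(m2["x", "x"], 1)

  # direct recomputation on tracks with controlled co-occurrence
  sim <- simulate_peaks(include_prob = c(1, 0.5), n_latent = 300,
                        noise_sd = 0.05, seed = 9)
  m3 <- signal_correlation(sim$tracks)
  v1 <- unlist(sim$tracks[[1]]$values)
  v2 <- unlist(sim$tracks[[2]]$values)
  expect_equal(m3[1, 2], cor(v1, v2))
  expect_gt(m3[1, 2], 0.3)
})

test_that("peaks and tracks round trip through BED and bedGraph", {
  sim <- simulate_peaks(n_latent = 40, include_prob = c(1, 0.8),
                        seed = 5)
  tmp_bed <- withr::local_tempfile(fileext = ".bed")
  write_peaks(sim$peaks[[1]], tmp_bed)
  back <- read_peaks(tmp_bed)
  expect_equal(back[, c("chrom", "start", "end")],
               sim$peaks[[1]][, c("chrom", "start", "end")])

  tmp_bg <- withr::local_tempfile(fileext = ".bedGraph")
  track <- sim$tracks[[1]]
  write_bedgraph(track, tmp_bg)
  back_track <- read_bedgraph(tmp_bg, track$bin_size, track$chrom_lengths)
  expect_equal(back_track$values$chr1, track$values$chr1, tolerance = 1e-6)
})
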