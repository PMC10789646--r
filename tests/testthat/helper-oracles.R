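# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use naive algorithms (all-pairs scans, repeated merging,
# per-bp loops, bisection) that share no code with the package internals.

# Partition of entries by shared-peptide grouping: all-pairs fraction matrix,
# then repeated merging of any two clusters linked by an above-threshold pair
# until a fixpoint. Returns a list of sorted integer vectors (sorted by first
# element) — input order independent.
oracle_group_partition <- function(peptide_sets, threshold = 0.30,
                                   rule = "min_set") {
  n <- length(peptide_sets)
  frac <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      a <- unique(peptide_sets[[i]])
      b <- unique(peptide_sets[[j]])
      ns <- length(intersect(a, b))
      den <- if (rule == "min_set") min(length(a), length(b)) else
        length(union(a, b))
      frac[i, j] <- ns / den
    }
  }
  clusters <- as.list(seq_len(n))
  repeat {
    merged <- FALSE
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        link <- any(frac[clusters[[i]], clusters[[j]], drop = FALSE] > threshold)
        if (link) {
          clusters[[i]] <- sort(c(clusters[[i]], clusters[[j]]))
          clusters[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  clusters <- lapply(clusters, sort)
  clusters[order(vapply(clusters, min, integer(1)))]
}

# Canonical form of a partition given as a membership-defining list of index
# vectors, for comparison.
canonical_partition <- function(groups) {
  groups <- lapply(groups, sort)
  groups[order(vapply(groups, min, numeric(1)))]
}

# Does interval [s1, e1) intersect [s2, e2) by >= 1 bp?
iv_hits <- function(chrom1, s1, e1, chrom2, s2, e2) {
  chrom1 == chrom2 & s1 < e2 & s2 < e1
}

# Per-peak quadratic scan: fraction of anchor peaks hitting any other peak.
oracle_overlap_fraction <- function(anchor, other) {
  hit <- vapply(seq_len(nrow(anchor)), function(i) {
    any(iv_hits(anchor$chrom[i], anchor$start[i], anchor$end[i],
                other$chrom, other$start, other$end))
  }, logical(1))
  mean(hit)
}

# Quadratic scan venn classification from one anchor's perspective:
# counts (neither, second_only, third_only, both).
oracle_venn_counts <- function(anchor, second, third) {
  in2 <- vapply(seq_len(nrow(anchor)), function(i) {
    any(iv_hits(anchor$chrom[i], anchor$start[i], anchor$end[i],
                second$chrom, second$start, second$end))
  }, logical(1))
  in3 <- vapply(seq_len(nrow(anchor)), function(i) {
    any(iv_hits(anchor$chrom[i], anchor$start[i], anchor$end[i],
                third$chrom, third$start, third$end))
  }, logical(1))
  c(sum(!in2 & !in3), sum(in2 & !in3), sum(!in2 & in3), sum(in2 & in3))
}

# Naive per-bp TSS matrix: for every row and window bin, average the per-bp
# signal (bp outside the chromosome count as 0).
oracle_tss_matrix <- function(track, tss, flank, bin_size) {
  n_col <- 2 * flank / bin_size
  mat <- matrix(0, nrow(tss), n_col)
  for (i in seq_len(nrow(tss))) {
    vals <- track$values[[tss$chrom[i]]]
    clen <- track$chrom_lengths[[tss$chrom[i]]]
    for (j in seq_len(n_col)) {
      s <- tss$pos[i] - flank + (j - 1) * bin_size
      total <- 0
      for (bp in s:(s + bin_size - 1)) {
        if (bp >= 0 && bp < clen) {
          total <- total + vals[bp %/% track$bin_size + 1]
        }
      }
      mat[i, j] <- total / bin_size
    }
    if (!is.null(tss$strand) && tss$strand[i] == "-") mat[i, ] <- rev(mat[i, ])
  }
  mat
}

# Bound fraction by bisection on the free-titrant concentration x:
# bound = N*Mt*x/(kd+x) and x + bound = Xt. Independent of the closed-form
# quadratic used in the package.
oracle_theta_bisect <- function(Xt, Mt, N, kd, tol = 1e-12) {
  g <- function(x) x + N * Mt * x / (kd + x) - Xt
  lo <- 0
  hi <- Xt
  for (k in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol * max(1, Xt)) break
  }
  x <- (lo + hi) / 2
  x / (kd + x)
}
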