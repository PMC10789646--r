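# Peak-level colocalization summaries on already-called peak sets.
#
# Coordinates are 0-based half-open throughout ([start, end), BED
# convention); conversion to the 1-based closed GRanges representation
# happens only at the IRanges boundary.

# peaks tibble (chrom, start, end[, strand]) -> GRanges
peaks_to_granges <- function(peaks) {
  if (nrow(peaks) == 0) {
    return(GenomicRanges::GRanges())
  }
  if (any(peaks$start >= peaks$end)) abort("peak intervals must satisfy start < end")
  if (any(peaks$start < 0)) abort("peak starts must be non-negative")
  strand <- if ("strand" %in% names(peaks)) peaks$strand else "*"
  strand[strand == "."] <- "*"
  GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1, end = peaks$end),
    strand = strand
  )
}

granges_to_peaks <- function(gr) {
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "."
  tibble::tibble(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = strand
  )
}

#' Read / write BED peak files
#'
#' BED3/BED6 files are parsed into a peaks tibble with 0-based half-open
#' coordinates (`chrom`, `start`, `end`, `strand`, plus `name` and `score`
#' when present), sorted by (chrom, start).
#'
#' @param path BED file path.
#' @return For `read_peaks`, a peaks tibble.
#' @export
read_peaks <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- granges_to_peaks(gr)
  if (!is.null(gr$name)) out$name <- gr$name
  if (!is.null(gr$score)) out$score <- gr$score
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' @rdname read_peaks
#' @param peaks Peaks tibble (`chrom`, `start`, `end`, optional `strand`,
#'   `name`, `score`).
#' @export
write_peaks <- function(peaks, path) {
  gr <- peaks_to_granges(peaks)
  if ("name" %in% names(peaks)) gr$name <- peaks$name
  if ("score" %in% names(peaks)) gr$score <- peaks$score
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Merge overlapping intervals within a peak set
#'
#' @param peaks Peaks tibble.
#' @return A peaks tibble with overlapping/adjacent-at->=1bp intervals
#'   merged, sorted by (chrom, start). Never has more rows than the input.
#' @export
merge_peaks <- function(peaks) {
  if (nrow(peaks) == 0) return(peaks[, c("chrom", "start", "end")])
  gr <- GenomicRanges::reduce(peaks_to_granges(peaks), ignore.strand = TRUE)
  out <- granges_to_peaks(gr)[, c("chrom", "start", "end")]
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Fraction of anchor peaks overlapping another peak set
#'
#' The fraction of `anchor` intervals with at least 1 bp of intersection
#' with the merged `other` set. Asymmetric by design: swap the arguments for
#' the other perspective.
#'
#' @param anchor Non-empty peaks tibble whose peaks are counted.
#' @param other Peaks tibble overlapped against (merged internally, so
#'   pre-merging it does not change the result).
#' @return A single number in `[0, 1]`.
#' @export
overlap_fraction <- function(anchor, other) {
  if (nrow(anchor) == 0) abort("anchor peak set is empty")
  a <- peaks_to_granges(anchor)
  b <- GenomicRanges::reduce(peaks_to_granges(other), ignore.strand = TRUE)
  # disjoint chromosome sets are a legitimate zero-overlap case, not a
  # user error: silence the seqlevel warning
  hits <- suppressWarnings(
    GenomicRanges::countOverlaps(a, b, ignore.strand = TRUE)
  ) > 0
  mean(hits)
}

#' Three-set Venn classification of peaks
#'
#' Peak-level Venn counts are anchor-dependent (a peak of one set can overlap
#' several peaks of another), so all three anchor perspectives are reported:
#' for each anchor set, every peak is classified by whether it overlaps the
#' merged second and/or merged third set.
#'
#' @param a,b,c Peaks tibbles.
#' @param names Character vector of length 3 naming the sets.
#' @return A tibble with columns `anchor`, `second`, `third`, `region` (one
#'   of `"neither"`, `"second_only"`, `"third_only"`, `"both"`) and `n`.
#'   Within each anchor, the four region counts sum to that set's peak count.
#' @export
venn3 <- function(a, b, c, names = c("a", "b", "c")) {
  sets <- list(a, b, c)
  merged <- lapply(sets, function(p) {
    GenomicRanges::reduce(peaks_to_granges(p), ignore.strand = TRUE)
  })
  res <- lapply(1:3, function(i) {
    others <- setdiff(1:3, i)
    gr <- peaks_to_granges(sets[[i]])
    in2 <- suppressWarnings(GenomicRanges::countOverlaps(
      gr, merged[[others[1]]], ignore.strand = TRUE)) > 0
    in3 <- suppressWarnings(GenomicRanges::countOverlaps(
      gr, merged[[others[2]]], ignore.strand = TRUE)) > 0
    tibble::tibble(
      anchor = names[i],
      second = names[others[1]],
      third = names[others[2]],
      region = c("neither", "second_only", "third_only", "both"),
      n = c(sum(!in2 & !in3), sum(in2 & !in3), sum(!in2 & in3), sum(in2 & in3))
    )
  })
  dplyr::bind_rows(res)
}

#' Binned genome-wide signal track
#'
#' A fixed-bin representation of a coverage/signal track: bin `j` of a
#' chromosome covers base pairs `[(j-1) * bin_size, j * bin_size)`.
#'
#' @param values Named list (one element per chromosome) of numeric bin
#'   vectors.
#' @param bin_size Bin width in bp.
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp;
#'   each value vector must have `ceiling(length / bin_size)` entries.
#' @return An object of class `signal_track`.
#' @export
signal_track <- function(values, bin_size, chrom_lengths) {
  stopifnot_scalar_number(bin_size, "bin_size", lower = 1)
  if (!setequal(names(values), names(chrom_lengths))) {
    abort("names of `values` and `chrom_lengths` must match")
  }
  for (chrom in names(values)) {
    expect_len <- ceiling(chrom_lengths[[chrom]] / bin_size)
    if (length(values[[chrom]]) != expect_len) {
      abort(sprintf("chromosome %s: expected %d bins, got %d",
                    chrom, expect_len, length(values[[chrom]])))
    }
  }
  structure(
    list(values = values[names(chrom_lengths)], bin_size = bin_size,
         chrom_lengths = chrom_lengths),
    class = "signal_track"
  )
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("signal_track: %d chromosome(s), bin size %d bp, %d bins\n",
              length(x$values), x$bin_size, sum(lengths(x$values))))
  invisible(x)
}

#' Tidy a signal track into a long tibble
#'
#' @param x A `signal_track`.
#' @param ... Unused.
#' @return A tibble with columns `chrom`, `start`, `end`, `value`.
#' @method tidy signal_track
#' @export
tidy.signal_track <- function(x, ...) {
  purrr::map_dfr(names(x$values), function(chrom) {
    v <- x$values[[chrom]]
    clen <- x$chrom_lengths[[chrom]]
    tibble::tibble(
      chrom = rep(chrom, length(v)),
      start = (seq_along(v) - 1) * x$bin_size,
      end = pmin(seq_along(v) * x$bin_size, clen),
      value = v
    )
  })
}

#' Read / write a bedGraph signal file
#'
#' bedGraph intervals are regridded onto fixed bins; each bin takes the
#' bp-weighted mean of the covering interval values (uncovered bp contribute
#' 0).
#'
#' @param path bedGraph file path.
#' @param bin_size Bin width in bp.
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @return For `read_bedgraph`, a `signal_track`.
#' @export
read_bedgraph <- function(path, bin_size, chrom_lengths) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  values <- lapply(names(chrom_lengths), function(chrom) {
    n_bins <- ceiling(chrom_lengths[[chrom]] / bin_size)
    acc <- numeric(n_bins)
    sel <- gr[as.character(GenomeInfoDb::seqnames(gr)) == chrom]
    if (length(sel) > 0) {
      s <- BiocGenerics::start(sel) - 1L # back to 0-based
      e <- BiocGenerics::end(sel)
      val <- sel$score
      for (k in seq_along(sel)) {
        b0 <- floor(s[k] / bin_size)
        b1 <- floor((e[k] - 1) / bin_size)
        for (b in b0:b1) {
          ov <- min(e[k], (b + 1) * bin_size) - max(s[k], b * bin_size)
          if (b + 1 <= n_bins) acc[b + 1] <- acc[b + 1] + val[k] * ov / bin_size
        }
      }
    }
    acc
  })
  names(values) <- names(chrom_lengths)
  signal_track(values, bin_size, chrom_lengths)
}

#' @rdname read_bedgraph
#' @param track A `signal_track`.
#' @export
write_bedgraph <- function(track, path) {
  d <- tidy.signal_track(track)
  d <- d[d$value != 0, , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = d$chrom,
    ranges = IRanges::IRanges(start = d$start + 1, end = d$end),
    score = d$value
  )
  GenomeInfoDb::seqlengths(gr) <-
    track$chrom_lengths[GenomeInfoDb::seqlevels(gr)]
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

# bp-weighted mean of track bins over [s, e) on one chromosome; bp outside
# [0, chrom_length) contribute 0 ("edge padding").
window_mean <- function(values, chrom_len, bin_size, s, e) {
  width <- e - s
  cs <- max(s, 0)
  ce <- min(e, chrom_len)
  if (cs >= ce) return(0)
  b0 <- floor(cs / bin_size)
  b1 <- floor((ce - 1) / bin_size)
  bins <- b0:b1
  ov <- pmin(ce, (bins + 1) * bin_size) - pmax(cs, bins * bin_size)
  sum(values[bins + 1] * ov) / width
}

#' TSS-anchored signal matrix
#'
#' Builds the matrix behind tornado/metagene plots: for each transcription
#' start site, the mean signal in consecutive bins across
#' `[pos - flank, pos + flank)`. Windows running off a chromosome end are
#' padded with 0 and flagged; minus-strand rows are column-reversed so that
#' column 1 is always the 5'-most bin. Rows are sorted by descending row
#' mean (stable, so ties keep input order).
#'
#' @param track A [signal_track()].
#' @param tss Tibble with columns `chrom`, `pos` (0-based TSS coordinate)
#'   and optionally `strand` (`+`, `-` or `.`; default `+`) and `name`.
#' @param flank Half-window in bp (default 5000); must be divisible by
#'   `bin_size`.
#' @param bin_size Matrix bin width in bp (default 50); may differ from the
#'   track's bin size (values are bp-weighted means of track bins).
#' @return An object of class `tss_matrix`: list with `matrix` (rows named
#'   by TSS name/index, sorted), `positions` (bin-center offsets from the
#'   TSS), `profile` (tibble of position and mean signal over rows),
#'   `edge_flagged` (logical per sorted row), `n_dropped` (TSS on unknown
#'   chromosomes), `flank`, `bin_size`.
#' @export
tss_matrix <- function(track, tss, flank = 5000, bin_size = 50) {
  stopifnot(inherits(track, "signal_track"))
  if (flank %% bin_size != 0) abort("flank must be divisible by bin_size")
  tss <- tibble::as_tibble(tss)
  if (!"strand" %in% names(tss)) tss$strand <- "+"
  if (!"name" %in% names(tss)) tss$name <- sprintf("tss_%d", seq_len(nrow(tss)))

  known <- tss$chrom %in% names(track$chrom_lengths)
  n_dropped <- sum(!known)
  if (n_dropped > 0) {
    warn(sprintf("dropping %d TSS on unknown chromosome(s)", n_dropped))
  }
  tss <- tss[known, , drop = FALSE]
  n_col <- as.integer(2 * flank / bin_size)
  n_row <- nrow(tss)
  mat <- matrix(0, nrow = n_row, ncol = n_col)
  edge <- logical(n_row)
  for (i in seq_len(n_row)) {
    chrom <- tss$chrom[i]
    vals <- track$values[[chrom]]
    clen <- track$chrom_lengths[[chrom]]
    w0 <- tss$pos[i] - flank
    starts <- w0 + (seq_len(n_col) - 1) * bin_size
    edge[i] <- w0 < 0 || (tss$pos[i] + flank) > clen
    mat[i, ] <- vapply(starts, function(s) {
      window_mean(vals, clen, track$bin_size, s, s + bin_size)
    }, numeric(1))
    if (tss$strand[i] == "-") mat[i, ] <- rev(mat[i, ])
  }
  rownames(mat) <- tss$name
  ord <- order(-rowMeans(mat)) # stable radix/ties keep input order
  mat <- mat[ord, , drop = FALSE]
  positions <- -flank + (seq_len(n_col) - 0.5) * bin_size
  structure(
    list(
      matrix = mat,
      positions = positions,
      profile = tibble::tibble(
        position = positions,
        mean_signal = if (n_row > 0) colMeans(mat) else rep(NA_real_, n_col)
      ),
      edge_flagged = edge[ord],
      n_dropped = n_dropped,
      flank = flank,
      bin_size = bin_size
    ),
    class = "tss_matrix"
  )
}

#' @export
print.tss_matrix <- function(x, ...) {
  cat(sprintf("tss_matrix: %d rows x %d bins (+/- %d bp at %d bp), %d dropped\n",
              nrow(x$matrix), ncol(x$matrix), x$flank, x$bin_size, x$n_dropped))
  invisible(x)
}

#' Pairwise correlation of signal tracks
#'
#' Correlates the concatenated genome-wide bin vectors of each pair of
#' tracks. All tracks must share binning and chromosome lengths. A
#' zero-variance track yields `NA` correlations with a warning.
#'
#' @param tracks Named list of [signal_track()] objects.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A symmetric correlation matrix with unit diagonal (for tracks
#'   with nonzero variance).
#' @export
signal_correlation <- function(tracks, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(tracks) < 2) abort("need at least 2 tracks")
  ref <- tracks[[1]]
  vecs <- lapply(tracks, function(t) {
    if (t$bin_size != ref$bin_size ||
        !identical(t$chrom_lengths[names(ref$chrom_lengths)], ref$chrom_lengths)) {
      abort("all tracks must share bin size and chromosome lengths")
    }
    unlist(t$values[names(ref$values)], use.names = FALSE)
  })
  m <- do.call(cbind, vecs)
  if (is.null(colnames(m))) colnames(m) <- paste0("track", seq_along(tracks))
  flat <- apply(m, 2, function(v) sd(v) == 0)
  if (any(flat)) {
    warn(paste0("zero-variance track(s): ",
                paste(colnames(m)[flat], collapse = ", "),
                "; correlations reported as NA"))
  }
  cm <- suppressWarnings(cor(m, method = method))
  cm[flat, ] <- NA_real_
  cm[, flat] <- NA_real_
  diag(cm)[!flat] <- 1
  cm
}
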