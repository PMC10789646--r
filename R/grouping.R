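# Shared-peptide protein grouping: entries whose peptide sets overlap by more
# than a threshold fraction are merged (single linkage, transitive closure).

#' Fraction of peptides shared by two entries
#'
#' Under the default `min_set` rule the fraction is the intersection size
#' divided by the size of the smaller set, so a protein whose peptides are a
#' subset of another's scores 1. The `jaccard` rule divides by the union size
#' instead. Both are symmetric.
#'
#' @param a,b Non-empty character vectors of peptide identifiers (compared as
#'   exact, case-sensitive strings).
#' @param rule Denominator rule, `"min_set"` (default) or `"jaccard"`.
#' @return A single number in `[0, 1]`.
#' @export
shared_peptide_fraction <- function(a, b, rule = c("min_set", "jaccard")) {
  rule <- match.arg(rule)
  a <- unique(a)
  b <- unique(b)
  if (length(a) == 0 || length(b) == 0) {
    abort("shared_peptide_fraction is undefined for empty peptide sets")
  }
  n_shared <- length(intersect(a, b))
  denom <- switch(rule,
    min_set = min(length(a), length(b)),
    jaccard = length(union(a, b))
  )
  n_shared / denom
}

#' Group proteins by shared peptides
#'
#' Builds the graph whose vertices are entries and whose edges connect pairs
#' with [shared_peptide_fraction()] strictly greater than `share_threshold`,
#' then merges each connected component into one group (transitive closure /
#' single linkage). Groups pool the union of member peptides and, by default,
#' the per-sample sum of member iBAQ values. The representative of a group is
#' the member with the largest total iBAQ across all samples (ties broken
#' lexicographically by accession). Output rows are sorted by descending
#' pooled total iBAQ (ties by representative accession), so the partition is
#' independent of input order.
#'
#' @param entries Entries tibble (non-empty peptide sets required).
#' @param share_threshold Merge when the shared fraction exceeds this value
#'   (strict inequality). Default 0.30.
#' @param rule Denominator rule passed to [shared_peptide_fraction()].
#' @param combine How to pool member intensities: `"sum"` (default) or
#'   `"representative"` (keep the representative member's values).
#' @return A tibble with columns `group_id`, `representative`, `gene_symbol`,
#'   `members` (semicolon-joined accessions), `n_members`, `peptide_ids`
#'   (list-column, union over members) and one pooled `iBAQ <sample_id>`
#'   column per sample.
#' @export
group_proteins <- function(entries, share_threshold = 0.30,
                           rule = c("min_set", "jaccard"),
                           combine = c("sum", "representative")) {
  rule <- match.arg(rule)
  combine <- match.arg(combine)
  stopifnot_scalar_number(share_threshold, "share_threshold", lower = 0, upper = 1)
  if (share_threshold <= 0) abort("share_threshold must be in (0, 1]")
  n <- nrow(entries)
  if (n == 0) abort("no entries to group")
  if (any(lengths(entries$peptide_ids) == 0)) {
    abort("all entries must have non-empty peptide sets for grouping")
  }

  # Candidate pairs via an inverted peptide -> entry index, so only entries
  # sharing at least one peptide are compared.
  long <- tibble::tibble(
    idx = rep.int(seq_len(n), lengths(entries$peptide_ids)),
    pep = unlist(entries$peptide_ids, use.names = FALSE)
  )
  long <- dplyr::distinct(long)
  pairs <- dplyr::inner_join(long, long, by = "pep", relationship = "many-to-many")
  pairs <- dplyr::filter(pairs, .data$idx.x < .data$idx.y)
  pairs <- dplyr::count(pairs, .data$idx.x, .data$idx.y, name = "n_shared")
  sizes <- lengths(lapply(entries$peptide_ids, unique))
  if (nrow(pairs) > 0) {
    denom <- if (rule == "min_set") {
      pmin(sizes[pairs$idx.x], sizes[pairs$idx.y])
    } else {
      sizes[pairs$idx.x] + sizes[pairs$idx.y] - pairs$n_shared
    }
    pairs <- pairs[pairs$n_shared / denom > share_threshold, , drop = FALSE]
  }

  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(pairs) > 0) {
    g <- igraph::add_edges(g, rbind(pairs$idx.x, pairs$idx.y))
  }
  membership <- igraph::components(g)$membership

  ibaq_cols <- grep("^iBAQ ", names(entries), value = TRUE)
  ib <- as.matrix(entries[, ibaq_cols, drop = FALSE])
  total_ibaq <- rowSums(ib)
  rep_acc <- representative_accession(entries$protein_ids)

  groups <- lapply(split(seq_len(n), membership), function(members) {
    ord <- order(-total_ibaq[members], rep_acc[members])
    lead <- members[ord[1]]
    pooled <- if (combine == "sum" && length(members) > 1) {
      colSums(ib[members, , drop = FALSE])
    } else {
      ib[lead, ]
    }
    c(
      list(
        representative = rep_acc[lead],
        gene_symbol = entries$gene_symbol[lead],
        members = paste(rep_acc[members][ord], collapse = ";"),
        n_members = length(members),
        peptide_ids = list(sort(unique(unlist(entries$peptide_ids[members])))),
        total = sum(pooled)
      ),
      as.list(pooled)
    )
  })
  out <- dplyr::bind_rows(lapply(groups, tibble::as_tibble))
  out <- dplyr::arrange(out, dplyr::desc(.data$total), .data$representative)
  out$total <- NULL
  out <- dplyr::mutate(out,
    group_id = sprintf("G%05d", dplyr::row_number()), .before = 1)
  out
}

#' Write a grouped-protein table
#'
#' @param groups Groups tibble from [group_proteins()].
#' @param path Output path for a TSV (group_id, representative, members,
#'   pooled iBAQ per sample).
#' @return `path`, invisibly.
#' @export
write_groups <- function(groups, path) {
  out <- dplyr::select(groups, -"peptide_ids")
  for (col in grep("^iBAQ ", names(out), value = TRUE)) {
    out[[col]] <- sprintf("%.17g", out[[col]])
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
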