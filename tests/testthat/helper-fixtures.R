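# Shared fixtures: small in-code entry tables and designs.

representative_ids <- function(entries) {
  vapply(strsplit(entries$protein_ids, ";", fixed = TRUE), `[[`,
         character(1), 1L)
}

toy_design <- function(n_replicates = 2) {
  tibble::tibble(
    sample_id = c(paste0("p", seq_len(n_replicates)),
                  paste0("m", seq_len(n_replicates))),
    condition = rep(c("plusUV", "minusUV"), each = n_replicates),
    replicate = rep(seq_len(n_replicates), 2)
  )
}

# Build an entries tibble from a list of peptide vectors and an iBAQ matrix
# (rows = entries, columns named by sample id).
make_entries <- function(peptides, ibaq, accessions = NULL,
                         contaminant = FALSE, reverse = FALSE,
                         only_by_site = FALSE) {
  n <- length(peptides)
  if (is.null(accessions)) accessions <- sprintf("ACC%03d", seq_len(n))
  entries <- tibble::tibble(
    protein_ids = accessions,
    protein_name = paste("protein", accessions),
    gene_symbol = paste0("GENE", seq_len(n)),
    peptide_ids = peptides,
    contaminant = rep_len(contaminant, n),
    reverse = rep_len(reverse, n),
    only_by_site = rep_len(only_by_site, n)
  )
  for (s in colnames(ibaq)) entries[[paste("iBAQ", s)]] <- ibaq[, s]
  entries
}

# A ribaq-like tibble for direct classification tests: per-sample riBAQ
# values plus the presence/zero flags compute_ribaq() would produce.
make_ribaq_row <- function(group_id, p1, p2, m1, m2) {
  tibble::tibble(
    group_id = group_id,
    p1 = p1, p2 = p2, m1 = m1, m2 = m2,
    present_plus = p1 > 0 & p2 > 0,
    present_minus = m1 > 0 & m2 > 0,
    zero_plus = p1 == 0 & p2 == 0,
    zero_minus = m1 == 0 & m2 == 0
  )
}
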