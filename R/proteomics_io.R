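# Reading/writing the MaxQuant proteinGroups.txt dialect and the entry-level
# filters that precede quantification.

# Dialect column names.
.pg_cols <- list(
  ids = "Protein IDs",
  name = "Protein names",
  gene = "Gene names",
  peptides = "Peptide IDs",
  contaminant = "Potential contaminant",
  reverse = "Reverse",
  only_by_site = "Only identified by site"
)

#' Read a sample design table
#'
#' The design binds each mass-spectrometry run to its experimental condition
#' (UV-irradiated or not) and biological replicate. The proteinGroups dialect
#' itself carries no design information, so this lives in a separate
#' tab-separated file with columns `sample_id`, `condition` (one of `plusUV`,
#' `minusUV`) and `replicate` (positive integer).
#'
#' @param path Path to a tab-separated design file.
#' @return A tibble with columns `sample_id`, `condition`, `replicate`.
#' @export
read_sample_design <- function(path) {
  d <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    condition = readr::col_character(),
    replicate = readr::col_integer()
  ), progress = FALSE)
  validate_sample_design(d)
}

#' Validate a sample design tibble
#'
#' @param design A data frame with columns `sample_id`, `condition`,
#'   `replicate`.
#' @return The design as a tibble, invisibly checked.
#' @export
validate_sample_design <- function(design) {
  design <- tibble::as_tibble(design)
  req <- c("sample_id", "condition", "replicate")
  missing <- setdiff(req, names(design))
  if (length(missing) > 0) {
    abort(paste0("design is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(design$sample_id)) {
    abort("design sample_id values must be unique")
  }
  bad <- setdiff(unique(design$condition), c("plusUV", "minusUV"))
  if (length(bad) > 0) {
    abort(paste0("unknown condition value(s): ", paste(bad, collapse = ", "),
                 " (expected plusUV/minusUV)"))
  }
  if (any(design$replicate < 1)) abort("replicate numbers must be >= 1")
  design
}

#' Write a sample design table
#'
#' @param design Design tibble as returned by [read_sample_design()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_design <- function(design, path) {
  readr::write_tsv(validate_sample_design(design), path, progress = FALSE)
  invisible(path)
}

#' Read a proteinGroups-style table
#'
#' Parses the tab-separated MaxQuant `proteinGroups.txt` dialect into a tidy
#' entries tibble: one row per protein group entry, with the semicolon-joined
#' accession string, protein/gene names, the peptide identifier set as a
#' list-column, logical flag columns, and one numeric `iBAQ <sample_id>`
#' column per designed sample. Empty or missing iBAQ cells are parsed as 0
#' (not detected). Column order in the file is irrelevant.
#'
#' @param path Path to a tab-separated proteinGroups-style file.
#' @param design Sample design tibble; every `sample_id` must have a matching
#'   `iBAQ <sample_id>` column in the file.
#' @return A tibble with columns `protein_ids`, `protein_name`, `gene_symbol`,
#'   `peptide_ids` (list of character vectors), `contaminant`, `reverse`,
#'   `only_by_site`, and the per-sample iBAQ columns.
#' @export
read_protein_groups <- function(path, design) {
  design <- validate_sample_design(design)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, na = character())
  if (!.pg_cols$ids %in% names(raw)) {
    abort(sprintf("file has no \"%s\" column: %s", .pg_cols$ids, path))
  }
  want <- ibaq_col(design$sample_id)
  missing <- setdiff(want, names(raw))
  if (length(missing) > 0) {
    abort(paste0(
      "configuration error: designed sample(s) without an iBAQ column: ",
      paste(missing, collapse = ", ")
    ))
  }

  parse_flag <- function(col) {
    if (!col %in% names(raw)) return(rep(FALSE, nrow(raw)))
    trimws(raw[[col]]) == "+"
  }
  parse_ibaq <- function(col) {
    x <- trimws(raw[[col]])
    x[x == "" | is.na(x) | x == "NaN" | x == "NA"] <- "0"
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      abort(sprintf("unparseable numeric value \"%s\" in row %d, column \"%s\"",
                    raw[[col]][i], i, col))
    }
    if (any(v < 0)) {
      i <- which(v < 0)[1]
      abort(sprintf("negative iBAQ value in row %d, column \"%s\"", i, col))
    }
    v
  }
  opt_chr <- function(col) {
    if (col %in% names(raw)) raw[[col]] else rep("", nrow(raw))
  }

  peptides <- strsplit(opt_chr(.pg_cols$peptides), ";", fixed = TRUE)
  peptides <- lapply(peptides, function(p) p[p != ""])

  entries <- tibble::tibble(
    protein_ids = raw[[.pg_cols$ids]],
    protein_name = opt_chr(.pg_cols$name),
    gene_symbol = opt_chr(.pg_cols$gene),
    peptide_ids = peptides,
    contaminant = parse_flag(.pg_cols$contaminant),
    reverse = parse_flag(.pg_cols$reverse),
    only_by_site = parse_flag(.pg_cols$only_by_site)
  )
  for (s in design$sample_id) {
    entries[[ibaq_col(s)]] <- parse_ibaq(ibaq_col(s))
  }
  if (any(entries$protein_ids == "")) abort("entries with empty Protein IDs")
  non_decoy_empty <- !entries$reverse & lengths(entries$peptide_ids) == 0
  if (any(non_decoy_empty)) {
    abort(sprintf("non-decoy entry with empty peptide set in row %d",
                  which(non_decoy_empty)[1]))
  }
  entries
}

#' Write a proteinGroups-style table
#'
#' Inverse of [read_protein_groups()]: emits the same tab-separated dialect,
#' with iBAQ values formatted at full double precision so that a write/read
#' round trip reproduces the entries exactly.
#'
#' @param entries Entries tibble as returned by [read_protein_groups()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_groups <- function(entries, path) {
  flag <- function(x) ifelse(x, "+", "")
  out <- tibble::tibble(
    !!.pg_cols$ids := entries$protein_ids,
    !!.pg_cols$name := entries$protein_name %||% "",
    !!.pg_cols$gene := entries$gene_symbol %||% "",
    !!.pg_cols$peptides := vapply(entries$peptide_ids, paste, character(1),
                                  collapse = ";"),
    !!.pg_cols$contaminant := flag(entries$contaminant),
    !!.pg_cols$reverse := flag(entries$reverse),
    !!.pg_cols$only_by_site := flag(entries$only_by_site)
  )
  for (col in grep("^iBAQ ", names(entries), value = TRUE)) {
    out[[col]] <- sprintf("%.17g", entries[[col]])
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read an accession rename map
#'
#' Tab-separated file with columns `accession`, `name`, `symbol` giving the
#' preferred protein name and gene symbol for selected accessions.
#'
#' @param path Path to the rename map file.
#' @return A tibble with columns `accession`, `name`, `symbol`.
#' @export
read_rename_map <- function(path) {
  m <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  req <- c("accession", "name", "symbol")
  missing <- setdiff(req, names(m))
  if (length(missing) > 0) {
    abort(paste0("rename map is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(m$accession)) abort("rename map accessions must be unique")
  m
}

#' Replace default protein names and symbols
#'
#' Applies user-defined preferred names: entries whose representative
#' accession (first accession in `protein_ids`) appears in the map get their
#' `protein_name` and `gene_symbol` replaced; all other entries pass through
#' unchanged. Row order is preserved.
#'
#' @param entries Entries tibble.
#' @param rename_map Tibble with columns `accession`, `name`, `symbol`
#'   (see [read_rename_map()]); may be empty.
#' @return The entries tibble with names/symbols replaced where mapped.
#' @export
apply_rename <- function(entries, rename_map) {
  if (is.null(rename_map) || nrow(rename_map) == 0) return(entries)
  rep_acc <- representative_accession(entries$protein_ids)
  idx <- match(rep_acc, rename_map$accession)
  hit <- !is.na(idx)
  entries$protein_name[hit] <- rename_map$name[idx[hit]]
  entries$gene_symbol[hit] <- rename_map$symbol[idx[hit]]
  entries
}

#' Remove contaminant and decoy entries
#'
#' Drops entries flagged as potential contaminants or reverse-database decoys.
#' Entries flagged only as "identified by site" are retained. The two output
#' tibbles partition the input and preserve its order; entries carrying both
#' flags are removed once and counted under "reverse".
#'
#' @param entries Entries tibble.
#' @return A list with elements `kept` (entries tibble) and `removed`
#'   (entries tibble with an extra `reason` column, `"reverse"` or
#'   `"contaminant"`).
#' @export
filter_entries <- function(entries) {
  drop <- entries$contaminant | entries$reverse
  removed <- entries[drop, , drop = FALSE]
  removed$reason <- ifelse(removed$reverse, "reverse", "contaminant")
  list(
    kept = entries[!drop, , drop = FALSE],
    removed = removed
  )
}

#' Write the removal log
#'
#' @param removed The `removed` tibble from [filter_entries()].
#' @param path Output path for a two-column TSV (accession, reason).
#' @return `path`, invisibly.
#' @export
write_removal_log <- function(removed, path) {
  log <- tibble::tibble(
    accession = representative_accession(removed$protein_ids),
    reason = removed$reason
  )
  readr::write_tsv(log, path, progress = FALSE)
  invisible(path)
}
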