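# Orchestration of the interactome post-processing chain behind a single
# validated configuration, with a reproducible run manifest.

.pipeline_keys <- c(
  "protein_groups", "design", "rename", "out_dir",
  "p_threshold", "fc_threshold", "share_threshold", "denominator_rule",
  "log_transform", "test", "p_adjust", "combine", "seed", "verbose"
)

.pipeline_defaults <- list(
  p_threshold = 0.05,
  fc_threshold = 2.0,
  share_threshold = 0.30,
  denominator_rule = "min_set",
  log_transform = TRUE,
  test = "student",
  p_adjust = "none",
  combine = "sum",
  seed = 1,
  verbose = FALSE
)

#' Validate a pipeline configuration
#'
#' @param config Named list with input/output paths (`protein_groups`,
#'   `design`, optional `rename`, `out_dir`) and analysis settings
#'   (`p_threshold`, `fc_threshold`, `share_threshold`, `denominator_rule`,
#'   `log_transform`, `test`, `p_adjust`, `combine`, `seed`, `verbose`).
#'   Unknown keys are rejected.
#' @return A character vector of problems; empty when the configuration is
#'   runnable.
#' @export
validate_config <- function(config) {
  problems <- character()
  unknown <- setdiff(names(config), .pipeline_keys)
  if (length(unknown) > 0) {
    problems <- c(problems, paste0("unknown key: ", unknown))
  }
  cfg <- utils::modifyList(.pipeline_defaults, config)
  for (key in c("protein_groups", "design")) {
    if (is.null(config[[key]])) {
      problems <- c(problems, paste0(key, " is required"))
    } else if (!file.exists(config[[key]])) {
      problems <- c(problems, paste0(key, " file does not exist: ", config[[key]]))
    }
  }
  if (!is.null(config$rename) && !file.exists(config$rename)) {
    problems <- c(problems, paste0("rename file does not exist: ", config$rename))
  }
  if (is.null(config$out_dir)) problems <- c(problems, "out_dir is required")
  num_ok <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x)
  if (!num_ok(cfg$p_threshold) || cfg$p_threshold <= 0 || cfg$p_threshold >= 1) {
    problems <- c(problems, "p_threshold out of (0,1)")
  }
  if (!num_ok(cfg$fc_threshold) || cfg$fc_threshold < 1) {
    problems <- c(problems, "fc_threshold must be >= 1")
  }
  if (!num_ok(cfg$share_threshold) || cfg$share_threshold <= 0 ||
      cfg$share_threshold > 1) {
    problems <- c(problems, "share_threshold out of (0,1]")
  }
  if (!cfg$denominator_rule %in% c("min_set", "jaccard")) {
    problems <- c(problems, "denominator_rule must be min_set or jaccard")
  }
  if (!cfg$test %in% c("welch", "student")) {
    problems <- c(problems, "test must be welch or student")
  }
  if (!cfg$p_adjust %in% c("none", "BH")) {
    problems <- c(problems, "p_adjust must be none or BH")
  }
  if (!cfg$combine %in% c("sum", "representative")) {
    problems <- c(problems, "combine must be sum or representative")
  }
  problems
}

#' Run the interactome post-processing pipeline
#'
#' Executes read, rename, contaminant/decoy filtering, shared-peptide
#' grouping, riBAQ normalization, enrichment classification and summary
#' generation in one pass, writing all artifact tables plus a run manifest
#' (JSON: configuration echo, package version, stage counts) to `out_dir`.
#' Outputs are deterministic functions of the inputs and configuration:
#' re-running produces byte-identical files.
#'
#' @param config Configuration list; see [validate_config()].
#' @return Invisibly, a list with the tibbles of each stage (`entries`,
#'   `kept`, `groups`, `ribaq`, `records`, `venn`) and the `manifest`.
#' @export
run_interactome <- function(config) {
  problems <- validate_config(config)
  if (length(problems) > 0) {
    abort(paste0("configuration error:\n", paste("-", problems, collapse = "\n")))
  }
  cfg <- utils::modifyList(.pipeline_defaults, config)
  say <- function(...) if (isTRUE(cfg$verbose)) message("[xlinkquant] ", ...)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$out_dir, f)

  say("reading design and protein groups")
  design <- read_sample_design(cfg$design)
  entries <- read_protein_groups(cfg$protein_groups, design)
  if (!is.null(cfg$rename)) {
    entries <- apply_rename(entries, read_rename_map(cfg$rename))
  }

  say("filtering contaminants and decoys")
  flt <- filter_entries(entries)
  write_protein_groups(flt$kept, out("filtered_proteinGroups.txt"))
  write_removal_log(flt$removed, out("removed_entries.tsv"))

  say("grouping shared-peptide proteins")
  groups <- group_proteins(flt$kept, share_threshold = cfg$share_threshold,
                           rule = cfg$denominator_rule, combine = cfg$combine)
  write_groups(groups, out("protein_groups_merged.tsv"))

  say("computing riBAQ and classifying enrichment")
  ribaq <- compute_ribaq(groups, design)
  records <- classify_enrichment(ribaq, design,
                                 p_threshold = cfg$p_threshold,
                                 fc_threshold = cfg$fc_threshold,
                                 log_transform = cfg$log_transform,
                                 test = cfg$test, p_adjust = cfg$p_adjust)
  enr_out <- records
  enr_out$category <- as.character(enr_out$category)
  for (col in c("mean_plus", "mean_minus", "fold_enrichment", "log2_fc", "p_value")) {
    enr_out[[col]] <- sprintf("%.17g", enr_out[[col]])
  }
  readr::write_tsv(enr_out, out("enrichment.tsv"), progress = FALSE)

  venn <- venn_counts(records)
  jsonlite::write_json(as.list(venn), out("venn_counts.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  volcano <- volcano_table(records)
  volcano$category <- as.character(volcano$category)
  readr::write_tsv(volcano, out("volcano.tsv"), progress = FALSE)

  manifest <- list(
    tool = "xlinkquant",
    version = as.character(utils::packageVersion("xlinkquant")),
    config = cfg[order(names(cfg))],
    counts = list(
      entries_read = nrow(entries),
      removed_contaminant = sum(flt$removed$reason == "contaminant"),
      removed_reverse = sum(flt$removed$reason == "reverse"),
      entries_kept = nrow(flt$kept),
      groups = nrow(groups),
      groups_analyzed = nrow(ribaq),
      n_exclusive_plus = venn$n_exclusive_plus,
      n_exclusive_minus = venn$n_exclusive_minus,
      n_common = venn$n_common,
      n_common_enriched = venn$n_common_enriched
    )
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  say("done: ", cfg$out_dir)
  invisible(list(entries = entries, kept = flt$kept, groups = groups,
                 ribaq = ribaq, records = records, venn = venn,
                 manifest = manifest))
}
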