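# Pipeline orchestration: fixed stage order, per-stage conservation
# accounting, and a consolidated report.
#
# Stage order (fixed; asserted by tests): taxonomy assignment ->
# scaffold contamination filter -> microbial-only removal -> HGT
# aggregation/calling -> flank validation -> HGT-scaffold removal ->
# optional cross-species comparison -> optional orthogroup dynamics ->
# assembly metrics. Contamination filtering precedes HGT calling on
# purpose: genes on contaminated scaffolds are never HGT candidates.

#' Run the contamination/HGT screening pipeline
#'
#' @param scaffolds scaffold table ([scaffold_records()]).
#' @param genes gene-model table ([gene_models()] / [read_annotation()]).
#' @param calls taxonomy-call table ([assign_scope()] /
#'   [read_taxonomy_calls()]).
#' @param hits donor/recipient hit table ([read_hit_table()]).
#' @param config a [filter_config()].
#' @param og_counts optional orthogroup count table; when given the
#'   quartile categorization stage runs.
#' @param reference_ids,presence_tables optional reference HGT protein
#'   ids and per-species hit tables; when given the cross-species
#'   presence stage runs.
#' @param top_k scaffold count for the percent-in-top-k metric.
#' @param quiet suppress stage-tagged progress lines (written to
#'   standard error).
#' @return an object of class `"hgt_pipeline_report"` with elements
#'   `stages` (per-stage input/kept/removed counts), `scaffold_filter`,
#'   `hgt` (the `"hgt_screen"`), `final_scaffolds`, `final_genes`,
#'   `presence`, `orthogroup_categories`, `metrics_before`,
#'   `metrics_after`, `config`.
#' @export
run_pipeline <- function(scaffolds, genes, calls, hits,
                         config = filter_config(),
                         og_counts = NULL,
                         reference_ids = NULL, presence_tables = NULL,
                         top_k = NULL, quiet = FALSE) {
  validate_filter_config(config)
  if (nrow(genes) == 0) stop_validation("empty gene set")
  say <- function(stage, fmt, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  stages <- list()
  note <- function(stage, n_in, n_kept) {
    stages[[stage]] <<- data.frame(stage = stage, input = n_in, kept = n_kept,
                                   removed = n_in - n_kept)
  }

  metrics_before <- assembly_metrics(scaffolds, genes,
                                     top_k = min(top_k %||% nrow(scaffolds),
                                                 nrow(scaffolds)))

  # 1. scaffold contamination filter
  sf <- apply_scaffold_filter(scaffolds, genes, calls, config)
  note("scaffold_contamination", nrow(scaffolds), nrow(sf$kept))
  say("scaffold_contamination", "%d scaffolds in, %d removed, %d kept",
      nrow(scaffolds), nrow(sf$removed), nrow(sf$kept))
  genes1 <- subset_genes_to_scaffolds(genes, sf$kept)
  note("genes_on_contaminated", nrow(genes), nrow(genes1))

  # 2. microbial-only removal
  mo <- remove_microbial_only_scaffolds(sf$kept, genes1, calls)
  note("microbial_only", nrow(sf$kept), nrow(mo$kept))
  say("microbial_only", "%d scaffolds removed (microbial genes only)",
      nrow(mo$removed))
  genes2 <- subset_genes_to_scaffolds(genes1, mo$kept)

  # 3-5. HGT screen (aggregation, calling, flank validation)
  hg <- screen_hgt(genes2, hits, calls, config)
  n_cand <- sum(hg$candidates$verdict %in% c("retained", "removed_flank"))
  say("hgt_screen", "%d hit-profile candidates, %d retained, %d scaffold(s) condemned",
      n_cand, nrow(hg$retained), length(hg$scaffolds_to_remove))
  keep3 <- !(mo$kept$scaffold_id %in% hg$scaffolds_to_remove)
  final_scaffolds <- mo$kept[keep3, , drop = FALSE]
  note("hgt_flank_scaffolds", nrow(mo$kept), nrow(final_scaffolds))
  final_genes <- subset_genes_to_scaffolds(genes2, final_scaffolds)

  # 6. optional cross-species comparison
  presence <- NULL
  if (!is.null(reference_ids) && !is.null(presence_tables)) {
    pm <- best_hit_presence(reference_ids, presence_tables, config$evalue_max)
    presence <- list(matrix = pm, summary = summarize_presence(pm))
    say("hgt_compare", "%d reference proteins screened across %d species",
        length(reference_ids), length(presence_tables))
  }

  # 7. optional orthogroup dynamics
  og_cat <- NULL
  if (!is.null(og_counts)) {
    og_cat <- categorize_orthogroups(og_counts)
    say("orthodynamics", "%d orthogroups categorized", nrow(og_counts))
  }

  metrics_after <- assembly_metrics(final_scaffolds, final_genes,
                                    top_k = min(top_k %||% nrow(final_scaffolds),
                                                nrow(final_scaffolds)))

  report <- list(stages = do.call(rbind, c(stages, make.row.names = FALSE)),
                 scaffold_filter = sf,
                 hgt = hg,
                 final_scaffolds = final_scaffolds,
                 final_genes = final_genes,
                 presence = presence,
                 orthogroup_categories = og_cat,
                 metrics_before = metrics_before,
                 metrics_after = metrics_after,
                 config = config,
                 version = as.character(utils::packageVersion("hgtscreen")))
  class(report) <- "hgt_pipeline_report"
  report
}

#' @export
print.hgt_pipeline_report <- function(x, ...) {
  cat("hgtscreen pipeline report (v", x$version, ")\n", sep = "")
  cat("stage                      input  kept  removed\n")
  for (i in seq_len(nrow(x$stages)))
    cat(sprintf("  %-24s %6d %5d %8d\n", x$stages$stage[i], x$stages$input[i],
                x$stages$kept[i], x$stages$removed[i]))
  cat(sprintf("retained HGT candidates: %d\n", nrow(x$hgt$retained)))
  if (nrow(x$hgt$retained))
    cat("  ", paste(x$hgt$retained$gene_id, collapse = ", "), "\n")
  cat(sprintf("assembly: %d -> %d scaffolds, N50 %s -> %s bp\n",
              x$metrics_before$scaffold_count, x$metrics_after$scaffold_count,
              format(x$metrics_before$n50, big.mark = ","),
              format(x$metrics_after$n50, big.mark = ",")))
  invisible(x)
}

#' Run the pipeline on a fixture directory
#'
#' Reads the files written by [write_fixture()] and calls
#' [run_pipeline()].
#'
#' @param dir fixture directory.
#' @param config a [filter_config()].
#' @param ... passed to [run_pipeline()].
#' @return an `"hgt_pipeline_report"`.
#' @export
run_pipeline_dir <- function(dir, config = filter_config(), ...) {
  seqs <- read_scaffold_fasta(file.path(dir, "scaffolds.fasta"))
  scaffolds <- scaffold_records(seqs)
  genes <- read_annotation(file.path(dir, "genes.gff3"))
  calls <- read_taxonomy_calls(file.path(dir, "taxonomy.tsv"))
  hits <- read_hit_table(file.path(dir, "hits.tsv"))
  og_path <- file.path(dir, "orthogroups.tsv")
  og <- if (file.exists(og_path)) read_orthogroup_counts(og_path) else NULL
  run_pipeline(scaffolds, genes, calls, hits, config = config,
               og_counts = og, ...)
}

#' Read and validate a key = value pipeline configuration file
#'
#' The file holds `key = value` lines (comments with `#`, blank lines
#' ignored) for any subset of the [filter_config()] scalar fields;
#' `coverage_cutoffs` and the two contaminant-scope sets take
#' comma-separated values. Unknown keys are rejected; absent keys take
#' the defaults.
#'
#' @param path config file path.
#' @return a validated [filter_config()].
#' @export
validate_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^\\[", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lines[vapply(kv, length, 1L) != 2]
  if (length(bad))
    stop_config("malformed config line(s): ", paste(bad, collapse = "; "))
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  allowed <- names(formals(filter_config))
  unknown <- setdiff(keys, allowed)
  if (length(unknown))
    stop_config("unknown config key(s): ", paste(unknown, collapse = ", "),
                "; allowed: ", paste(allowed, collapse = ", "))
  if (anyDuplicated(keys))
    stop_config("duplicate config key(s): ",
                paste(unique(keys[duplicated(keys)]), collapse = ", "))
  args <- list()
  char_keys <- c("contaminant_scopes_scaffold", "contaminant_scopes_transcript")
  for (i in seq_along(keys)) {
    v <- strsplit(vals[i], ",", fixed = TRUE)[[1]]
    v <- trimws(v)
    args[[keys[i]]] <- if (keys[i] %in% char_keys) v else as.numeric(v)
  }
  do.call(filter_config, args)
}
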