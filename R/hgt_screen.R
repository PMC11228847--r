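# Donor/recipient hit-profile screening and flanking-gene validation.
#
# A gene is an HGT candidate when it has between donor_hits_min and
# donor_hits_max distinct donor-database subjects (pooled across donor
# databases) at E-value strictly below the cutoff, and no significant
# recipient-database (plant lineage) hit. Candidates are then validated
# by the taxonomy of their immediately adjacent genes: a real transfer
# is integrated among plant genes, whereas a candidate flanked by
# non-plant genes marks a contaminant scaffold.

HIT_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
              "qstart", "qend", "sstart", "send", "evalue", "bitscore")

#' Read a tabular protein-alignment hit table
#'
#' Reads the 12-column BLAST/DIAMOND tabular dialect (qseqid, sseqid,
#' pident, length, mismatch, gapopen, qstart, qend, sstart, send, evalue,
#' bitscore) with a required 13th column `db_label` naming the donor or
#' recipient database the subject came from.
#'
#' @param path path to a headerless tab-separated hit table.
#' @return `data.frame` with the 13 named columns.
#' @export
read_hit_table <- function(path) {
  hits <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(hits) != 13)
    stop_validation("hit table must have 13 columns (12-column tabular ",
                    "alignment dialect + db_label), found ", ncol(hits))
  names(hits) <- c(HIT_COLS, "db_label")
  validate_hits(hits)
  hits
}

#' @noRd
validate_hits <- function(hits, labels = c(DONOR_LABELS, RECIPIENT_LABELS)) {
  assert_cols(hits, c("qseqid", "sseqid", "evalue", "bitscore", "db_label"),
              "hit table")
  bad <- setdiff(unique(hits$db_label), labels)
  if (length(bad))
    stop_validation("unknown db_label(s): ", paste(bad, collapse = ", "),
                    "; allowed: ", paste(labels, collapse = ", "))
  invisible(hits)
}

#' Aggregate alignment hits into donor/recipient subject counts
#'
#' Counts DISTINCT subjects per database label among hits with
#' `evalue < evalue_max` (strict); multiple HSP rows against one subject
#' count once. Totals pool distinct subjects across all donor labels and
#' across all recipient labels.
#'
#' @param hits hit table (see [read_hit_table()]); may cover many query
#'   genes.
#' @param evalue_max significance cutoff (strict).
#' @return `data.frame` with one row per query: `gene_id`, one
#'   `donor_<label>` column per donor database, `donor_total`,
#'   `recipient_total`.
#' @export
aggregate_hits <- function(hits, evalue_max = 1e-5) {
  validate_hits(hits)
  sig <- hits[hits$evalue < evalue_max, , drop = FALSE]
  genes <- sort(unique(hits$qseqid))
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  key <- paste(sig$qseqid, sig$db_label, sig$sseqid, sep = "\r")
  sig <- sig[!duplicated(key), , drop = FALSE]
  for (lab in DONOR_LABELS) {
    tab <- table(factor(sig$qseqid[sig$db_label == lab], levels = genes))
    out[[paste0("donor_", lab)]] <- as.integer(tab)
  }
  is_donor <- sig$db_label %in% DONOR_LABELS
  out$donor_total <- as.integer(table(factor(sig$qseqid[is_donor], levels = genes)))
  out$recipient_total <- as.integer(table(factor(sig$qseqid[!is_donor], levels = genes)))
  out
}

#' Call HGT candidates from aggregated hit profiles
#'
#' @param aggregates output of [aggregate_hits()] (one row per gene;
#'   genes with no hits at all may simply be absent — they are not
#'   candidates).
#' @param config a [filter_config()]; candidacy requires
#'   `donor_total` in `[donor_hits_min, donor_hits_max]` (inclusive) and
#'   `recipient_total == 0`.
#' @return `aggregates` with a `verdict` column
#'   (`candidate` / `rejected_hits`).
#' @export
call_hgt_candidates <- function(aggregates, config = filter_config()) {
  validate_filter_config(config)
  assert_cols(aggregates, c("gene_id", "donor_total", "recipient_total"),
              "hit aggregate table")
  cand <- aggregates$donor_total >= config$donor_hits_min &
    aggregates$donor_total <= config$donor_hits_max &
    aggregates$recipient_total == 0
  aggregates$verdict <- ifelse(cand, "candidate", "rejected_hits")
  aggregates
}

#' Validate an HGT candidate by its flanking genes
#'
#' Looks up the genes immediately adjacent (by start coordinate,
#' strand-agnostic) to the candidate on its scaffold and classifies the
#' neighborhood: both flanks plant -> `all_plant`; candidate at a
#' scaffold end with its single flank plant -> `terminal_partial`; any
#' flank non-plant (unannotated included — only a well-annotated plant
#' flank vouches for integration) -> `has_nonplant`; candidate alone on
#' its scaffold -> `isolated`.
#'
#' @param gene_id candidate gene id.
#' @param genes gene-model table (the candidate's scaffold must contain
#'   it).
#' @param calls taxonomy-call table.
#' @return one of `"all_plant"`, `"terminal_partial"`, `"has_nonplant"`,
#'   `"isolated"`.
#' @export
validate_flanks <- function(gene_id, genes, calls) {
  validate_calls(calls)
  row <- genes[genes$gene_id == gene_id, , drop = FALSE]
  if (nrow(row) != 1)
    stop_validation("candidate gene ", gene_id, " not found in the gene set")
  on_scaf <- sort_genes(genes[genes$scaffold_id == row$scaffold_id, , drop = FALSE])
  i <- which(on_scaf$gene_id == gene_id)
  neighbors <- on_scaf$gene_id[c(i - 1, i + 1)[c(i - 1, i + 1) >= 1 &
                                                 c(i - 1, i + 1) <= nrow(on_scaf)]]
  if (length(neighbors) == 0) return("isolated")
  scope <- calls$scope[match(neighbors, calls$feature_id)]
  scope[is.na(scope)] <- "unannotated"
  if (any(scope != "plant")) return("has_nonplant")
  if (length(neighbors) == 1) return("terminal_partial")
  "all_plant"
}

#' Finalize the HGT screen: retain candidates or condemn scaffolds
#'
#' Candidates flanked by non-plant genes (or isolated) are judged to sit
#' on contaminant scaffolds: their whole scaffold is queued for removal
#' and the candidate is marked `removed_flank`. Candidates with plant
#' flanks (`all_plant` or `terminal_partial`) are retained.
#'
#' @param candidates candidate table ([call_hgt_candidates()] output,
#'   `verdict == "candidate"` rows are assessed; rejected rows pass
#'   through unchanged).
#' @param genes gene-model table.
#' @param calls taxonomy-call table.
#' @return an object of class `"hgt_screen"`: `list(candidates,
#'   retained, scaffolds_to_remove)` where `candidates` gains
#'   `flank_status`, `scaffold_id` and a final `verdict` in
#'   `{retained, rejected_hits, removed_flank}`.
#' @export
finalize_hgt <- function(candidates, genes, calls) {
  assert_cols(candidates, c("gene_id", "verdict"), "candidate table")
  candidates$scaffold_id <- genes$scaffold_id[match(candidates$gene_id, genes$gene_id)]
  candidates$flank_status <- rep(NA_character_, nrow(candidates))
  is_cand <- candidates$verdict == "candidate"
  for (i in which(is_cand)) {
    candidates$flank_status[i] <- validate_flanks(candidates$gene_id[i], genes, calls)
  }
  keep <- is_cand & candidates$flank_status %in% c("all_plant", "terminal_partial")
  fail <- is_cand & !keep
  candidates$verdict[keep] <- "retained"
  candidates$verdict[fail] <- "removed_flank"
  out <- list(candidates = candidates,
              retained = candidates[keep, , drop = FALSE],
              scaffolds_to_remove = sort(unique(candidates$scaffold_id[fail])))
  class(out) <- "hgt_screen"
  out
}

#' Run the whole HGT screen on one gene set
#'
#' Convenience wrapper: [aggregate_hits()] at the configured cutoff,
#' [call_hgt_candidates()], then flank validation via [finalize_hgt()].
#'
#' @param genes gene-model table (post contamination filtering).
#' @param hits donor+recipient hit table.
#' @param calls taxonomy-call table.
#' @param config a [filter_config()].
#' @return an `"hgt_screen"` object (see [finalize_hgt()]).
#' @export
screen_hgt <- function(genes, hits, calls, config = filter_config()) {
  hits <- hits[hits$qseqid %in% genes$gene_id, , drop = FALSE]
  agg <- aggregate_hits(hits, config$evalue_max)
  cand <- call_hgt_candidates(agg, config)
  finalize_hgt(cand, genes, calls)
}

#' @export
print.hgt_screen <- function(x, ...) {
  v <- x$candidates$verdict
  cat("HGT screen\n")
  cat(sprintf("  genes with significant hits: %d\n", nrow(x$candidates)))
  cat(sprintf("  hit-profile candidates:      %d\n",
              sum(v %in% c("retained", "removed_flank"))))
  cat(sprintf("  removed by flank check:      %d (on %d scaffold(s))\n",
              sum(v == "removed_flank"), length(x$scaffolds_to_remove)))
  cat(sprintf("  retained HGT candidates:     %d\n", sum(v == "retained")))
  if (sum(v == "retained"))
    cat("   ", paste(x$retained$gene_id, collapse = ", "), "\n")
  invisible(x)
}

#' Write the candidate report
#' @param screen an `"hgt_screen"` object.
#' @param path output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_hgt_report <- function(screen, path) {
  write.table(screen$candidates, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
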