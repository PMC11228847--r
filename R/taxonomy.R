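# Taxonomy-scope assignment and the transcript/gene-level filters.
#
# All filters return a list(retained, removed, ...) and satisfy
# conservation (|retained| + |removed| = |input|) and idempotence.

#' Assign a taxonomy scope to features from annotation evidence
#'
#' Combines per-feature similarity-search and orthology (EggNOG-style)
#' taxonomy calls into one scope per feature. Similarity evidence takes
#' precedence over orthology; features with neither are `unannotated`.
#' The scope vocabulary is closed: plant, bacteria, fungi, archaea,
#' metazoa, insecta, amoeba, unannotated.
#'
#' @param feature_id character vector of feature ids (unique).
#' @param similarity scope from the similarity search, `NA` when absent.
#' @param orthology scope from orthology assignment, `NA` when absent.
#' @param best_evalue optional numeric best E-value of the evidence.
#' @return taxonomy-call `data.frame`: `feature_id`, `scope`, `source`
#'   (`similarity`/`orthology`/`none`), `best_evalue`.
#' @examples
#' assign_scope("g1", similarity = "fungi", orthology = "plant")$scope
#' @export
assign_scope <- function(feature_id, similarity = NA, orthology = NA,
                         best_evalue = NA_real_) {
  n <- length(feature_id)
  feature_id <- as.character(feature_id)
  if (anyDuplicated(feature_id))
    stop_validation("duplicate feature_id in taxonomy evidence")
  similarity <- rep_len(as.character(similarity), n)
  orthology <- rep_len(as.character(orthology), n)
  best_evalue <- rep_len(as.numeric(best_evalue), n)
  known <- c(SCOPE_LEVELS, NA)
  bad <- setdiff(unique(c(similarity, orthology)), known)
  if (length(bad))
    stop_validation("unknown taxonomy scope(s): ", paste(bad, collapse = ", "),
                    "; allowed: ", paste(SCOPE_LEVELS, collapse = ", "))
  scope <- ifelse(!is.na(similarity), similarity,
                  ifelse(!is.na(orthology), orthology, "unannotated"))
  source <- ifelse(!is.na(similarity), "similarity",
                   ifelse(!is.na(orthology), "orthology", "none"))
  data.frame(feature_id = feature_id, scope = scope, source = source,
             best_evalue = best_evalue, stringsAsFactors = FALSE)
}

#' @noRd
validate_calls <- function(calls) {
  assert_cols(calls, c("feature_id", "scope"), "taxonomy-call table")
  bad <- setdiff(unique(calls$scope), SCOPE_LEVELS)
  if (length(bad))
    stop_validation("unknown taxonomy scope(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(calls$feature_id))
    stop_validation("more than one taxonomy call for a feature")
  invisible(calls)
}

#' Remove internal ORFs from a transcript set
#'
#' Predicted ORFs lacking both a start and a stop codon ("internal") are
#' dropped; complete and 5'/3'-partial ORFs are retained.
#'
#' @param orfs `data.frame` with columns `orf_id` and `completeness`
#'   (one of `complete`, `five_prime_partial`, `three_prime_partial`,
#'   `internal`).
#' @return `list(retained, removed)` of row subsets.
#' @export
filter_internal_orfs <- function(orfs) {
  assert_cols(orfs, c("orf_id", "completeness"), "ORF table")
  ok <- c("complete", "five_prime_partial", "three_prime_partial", "internal")
  bad <- setdiff(unique(orfs$completeness), ok)
  if (length(bad))
    stop_validation("unknown ORF completeness: ", paste(bad, collapse = ", "))
  keep <- orfs$completeness != "internal"
  list(retained = orfs[keep, , drop = FALSE],
       removed = orfs[!keep, , drop = FALSE])
}

#' Filter transcripts by expression level
#'
#' Retains transcripts strictly above the FPKM floor; a transcript at
#' exactly the floor is removed.
#'
#' @param expr `data.frame` with columns `transcript_id` and `fpkm`
#'   (all `>= 0`).
#' @param fpkm_min expression floor (default 0.5).
#' @return `list(retained, removed)`.
#' @export
filter_by_expression <- function(expr, fpkm_min = 0.5) {
  assert_cols(expr, c("transcript_id", "fpkm"), "expression table")
  if (any(expr$fpkm < 0)) stop_validation("FPKM values must be >= 0")
  keep <- expr$fpkm > fpkm_min
  list(retained = expr[keep, , drop = FALSE],
       removed = expr[!keep, , drop = FALSE])
}

#' Remove contaminant transcripts by taxonomy scope
#'
#' Transcripts whose scope falls in the contaminant set (by default
#' archaea, bacteria, fungi, insecta, amoeba — the transcript-level set,
#' wider than the scaffold-level one) are removed, and the per-scope
#' breakdown is reported as counts and percentages of the annotated
#' input (two decimals).
#'
#' @param calls taxonomy-call table for transcripts.
#' @param contaminant_scopes scopes to remove.
#' @return `list(retained, removed, summary)`; `summary` has columns
#'   `scope`, `n`, `pct`.
#' @export
filter_contaminant_transcripts <- function(calls,
                                           contaminant_scopes = c("archaea", "bacteria",
                                                                  "fungi", "insecta", "amoeba")) {
  validate_calls(calls)
  drop <- calls$scope %in% contaminant_scopes
  n_tot <- nrow(calls)
  tab <- table(factor(calls$scope[drop], levels = sort(contaminant_scopes)))
  summary <- data.frame(scope = names(tab), n = as.integer(tab),
                        pct = round_half_up(100 * as.integer(tab) / max(n_tot, 1), 2),
                        stringsAsFactors = FALSE)
  summary <- rbind(summary,
                   data.frame(scope = "total", n = sum(drop),
                              pct = round_half_up(100 * sum(drop) / max(n_tot, 1), 2)))
  list(retained = calls[!drop, , drop = FALSE],
       removed = calls[drop, , drop = FALSE],
       summary = summary)
}

#' Keep only genes with a complete protein domain
#'
#' Genes lacking any complete domain hit are removed; this filter is what
#' collapses spuriously predicted (typically mono-exonic) gene models.
#' Domain-table ids absent from the gene set produce a warning and are
#' ignored.
#'
#' @param genes gene-model table.
#' @param domain_hits `data.frame` with columns `gene_id`, `domain`
#'   (one row per complete-domain hit; genes may be absent = no domain).
#' @return `list(retained, removed)` of gene rows.
#' @export
filter_genes_by_domain <- function(genes, domain_hits) {
  assert_cols(genes, "gene_id", "gene table")
  assert_cols(domain_hits, c("gene_id", "domain"), "domain-hit table")
  unknown <- setdiff(unique(domain_hits$gene_id), genes$gene_id)
  if (length(unknown))
    warning(length(unknown), " domain-table gene id(s) not in the gene set; ignored")
  with_domain <- unique(domain_hits$gene_id[domain_hits$domain != ""])
  keep <- genes$gene_id %in% with_domain
  list(retained = genes[keep, , drop = FALSE],
       removed = genes[!keep, , drop = FALSE])
}

#' Read/write helpers for the module's tab-separated interchange tables
#'
#' Taxonomy calls: `feature_id`, `scope`, `source`, `best_evalue`.
#' ORFs: `orf_id`, `completeness`. Expression: `transcript_id`, `fpkm`.
#'
#' @param path file path.
#' @return the table as a `data.frame` (readers) or `path` (writer).
#' @name taxonomy_tables
NULL

#' @rdname taxonomy_tables
#' @export
read_taxonomy_calls <- function(path) {
  calls <- read.delim(path, stringsAsFactors = FALSE)
  validate_calls(calls)
  calls
}

#' @rdname taxonomy_tables
#' @param calls taxonomy-call table.
#' @export
write_taxonomy_calls <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
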