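# Assembly-level contaminant removal from per-gene taxonomy composition.

#' Contaminant-gene fraction of one scaffold
#'
#' Fraction of a scaffold's genes whose taxonomy scope is in the
#' contaminant set. The denominator is ALL genes on the scaffold —
#' unannotated genes count there (absence of a plant call is not evidence
#' of plant origin) — and a scaffold with no genes has fraction 0.
#'
#' @param scaffold_id one scaffold id.
#' @param genes gene-model table.
#' @param calls taxonomy-call table (feature_id matches gene_id).
#' @param contaminant_scopes scopes counted as contaminant
#'   (default archaea/bacteria/fungi).
#' @return fraction in `[0, 1]`.
#' @export
scaffold_contaminant_fraction <- function(scaffold_id, genes, calls,
                                          contaminant_scopes = c("archaea", "bacteria", "fungi")) {
  validate_calls(calls)
  g <- genes[genes$scaffold_id == scaffold_id, , drop = FALSE]
  if (nrow(g) == 0) return(0)
  scope <- calls$scope[match(g$gene_id, calls$feature_id)]
  scope[is.na(scope)] <- "unannotated"
  sum(scope %in% contaminant_scopes) / nrow(g)
}

#' @noRd
scaffold_composition <- function(scaffolds, genes, calls, contaminant_scopes) {
  validate_calls(calls)
  bad <- setdiff(unique(genes$scaffold_id), scaffolds$scaffold_id)
  if (length(bad))
    stop_validation("gene(s) reference unknown scaffold: ",
                    paste(bad, collapse = ", "))
  scope <- calls$scope[match(genes$gene_id, calls$feature_id)]
  scope[is.na(scope)] <- "unannotated"
  f <- factor(genes$scaffold_id, levels = scaffolds$scaffold_id)
  n_genes <- as.integer(table(f))
  n_contam <- as.integer(table(f[scope %in% contaminant_scopes]))
  n_plant <- as.integer(table(f[scope == "plant"]))
  data.frame(scaffold_id = scaffolds$scaffold_id,
             length = scaffolds$length,
             n_genes = n_genes,
             n_contaminant_genes = n_contam,
             n_plant_genes = n_plant,
             contam_fraction = ifelse(n_genes > 0, n_contam / pmax(n_genes, 1), 0),
             stringsAsFactors = FALSE)
}

#' Apply the scaffold-composition contamination rules
#'
#' A scaffold is removed when either rule fires: length <= 10 kb with a
#' contaminant-gene fraction >= 0.40 (`short_rule`), or length >= 10 kb
#' with a fraction >= 0.55 (`long_rule`). At exactly 10 kb both rules are
#' applicable and removal uses their union (the short rule is recorded
#' when both fire). Retained scaffolds that still carry at least one
#' contaminant gene are flagged (`flagged_kept`) for review, not removed.
#'
#' @param scaffolds scaffold table.
#' @param genes gene-model table.
#' @param calls taxonomy-call table.
#' @param config a [filter_config()].
#' @return an object of class `"scaffold_filter"`:
#'   `list(kept, removed, verdicts)` where `kept`/`removed` are scaffold
#'   tables and `verdicts` has one row per input scaffold
#'   (`scaffold_id`, `length`, `n_genes`, `n_contaminant_genes`,
#'   `contam_fraction`, `rule_fired`, `kept`, `flagged_kept`).
#' @export
apply_scaffold_filter <- function(scaffolds, genes, calls, config = filter_config()) {
  validate_filter_config(config)
  comp <- scaffold_composition(scaffolds, genes, calls,
                               config$contaminant_scopes_scaffold)
  short_fire <- comp$length <= config$short_scaffold_len &
    comp$contam_fraction >= config$short_contam_frac
  long_fire <- comp$length >= config$short_scaffold_len &
    comp$contam_fraction >= config$long_contam_frac
  remove <- short_fire | long_fire
  rule <- ifelse(short_fire, "short_rule", ifelse(long_fire, "long_rule", "none"))
  verdicts <- data.frame(comp[c("scaffold_id", "length", "n_genes",
                                "n_contaminant_genes", "contam_fraction")],
                         rule_fired = rule,
                         kept = !remove,
                         flagged_kept = !remove & comp$n_contaminant_genes >= 1,
                         stringsAsFactors = FALSE)
  out <- list(kept = scaffolds[!remove, , drop = FALSE],
              removed = scaffolds[remove, , drop = FALSE],
              verdicts = verdicts)
  class(out) <- "scaffold_filter"
  out
}

#' @export
print.scaffold_filter <- function(x, ...) {
  cat("Scaffold contamination filter\n")
  cat(sprintf("  scaffolds in:  %d\n", nrow(x$verdicts)))
  cat(sprintf("  removed:       %d (short rule %d, long rule %d)\n",
              nrow(x$removed),
              sum(x$verdicts$rule_fired == "short_rule"),
              sum(x$verdicts$rule_fired == "long_rule")))
  cat(sprintf("  kept:          %d (flagged with >=1 contaminant gene: %d)\n",
              nrow(x$kept), sum(x$verdicts$flagged_kept)))
  invisible(x)
}

#' Remove scaffolds carrying only microbial genes
#'
#' Drops scaffolds that have at least one gene, at least one microbial
#' (bacteria/fungi/archaea) gene, and no plant-scope gene. Unannotated
#' genes neither trigger removal nor rescue a scaffold.
#'
#' @inheritParams apply_scaffold_filter
#' @param microbial_scopes scopes whose presence (with no plant gene)
#'   condemns a scaffold.
#' @return `list(kept, removed)` scaffold tables.
#' @export
remove_microbial_only_scaffolds <- function(scaffolds, genes, calls,
                                            microbial_scopes = c("bacteria", "fungi", "archaea")) {
  comp <- scaffold_composition(scaffolds, genes, calls, microbial_scopes)
  remove <- comp$n_genes >= 1 & comp$n_contaminant_genes >= 1 & comp$n_plant_genes == 0
  list(kept = scaffolds[!remove, , drop = FALSE],
       removed = scaffolds[remove, , drop = FALSE])
}

#' Write the scaffold verdict report
#' @param filter result of [apply_scaffold_filter()].
#' @param path output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_scaffold_verdicts <- function(filter, path) {
  write.table(filter$verdicts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop genes located on removed scaffolds
#' @param genes gene-model table.
#' @param kept_scaffolds scaffold table of retained scaffolds.
#' @return gene subset on kept scaffolds.
#' @export
subset_genes_to_scaffolds <- function(genes, kept_scaffolds) {
  genes[genes$scaffold_id %in% kept_scaffolds$scaffold_id, , drop = FALSE]
}
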