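# Cross-species presence screening of a reference HGT protein set.
#
# A reference protein is "present" in another species when its best-hit
# search against that species' proteome has at least one alignment below
# the E-value cutoff. "Max target sequences 1" is modeled as post-hoc
# best-hit selection (lowest evalue, ties by highest bitscore, then
# lexicographic subject id) from the full hit table, so the module is
# testable without re-running searches.

#' Presence matrix of reference proteins across species
#'
#' @param reference_ids character vector of reference protein ids (one
#'   row each, even when never hit).
#' @param hit_tables named list of hit tables (see [read_hit_table()]
#'   minus the `db_label` requirement: only `qseqid`, `sseqid`, `evalue`,
#'   `bitscore` are used), one per species.
#' @param evalue_max significance cutoff (strict).
#' @return an object of class `"presence_matrix"`: `list(presence,
#'   top_hits)` where `presence` is a logical matrix (reference x
#'   species) and `top_hits` a `data.frame` of the selected best hit per
#'   present pair.
#' @export
best_hit_presence <- function(reference_ids, hit_tables, evalue_max = 1e-5) {
  reference_ids <- as.character(reference_ids)
  if (anyDuplicated(reference_ids))
    stop_validation("duplicate reference ids")
  if (is.null(names(hit_tables)) || any(names(hit_tables) == ""))
    stop_validation("hit_tables must be a named list (one table per species)")
  species <- names(hit_tables)
  presence <- matrix(FALSE, length(reference_ids), length(species),
                     dimnames = list(reference_ids, species))
  tops <- list()
  for (sp in species) {
    h <- hit_tables[[sp]]
    assert_cols(h, c("qseqid", "sseqid", "evalue", "bitscore"), "hit table")
    h <- h[h$evalue < evalue_max & h$qseqid %in% reference_ids, , drop = FALSE]
    if (nrow(h) == 0) next
    o <- order(h$qseqid, h$evalue, -h$bitscore, h$sseqid, method = "radix")
    h <- h[o, , drop = FALSE]
    best <- h[!duplicated(h$qseqid), , drop = FALSE]
    presence[best$qseqid, sp] <- TRUE
    tops[[sp]] <- data.frame(species = sp, reference_id = best$qseqid,
                             subject_id = best$sseqid, evalue = best$evalue,
                             bitscore = best$bitscore, stringsAsFactors = FALSE)
  }
  out <- list(presence = presence,
              top_hits = if (length(tops)) do.call(rbind, c(tops, make.row.names = FALSE))
              else data.frame(species = character(0), reference_id = character(0),
                              subject_id = character(0), evalue = numeric(0),
                              bitscore = numeric(0)))
  class(out) <- "presence_matrix"
  out
}

#' Summarize a presence matrix into shared/unique categories
#'
#' Partitions the reference set by its presence pattern across the
#' screened species: absent in all, present in all, present only in each
#' single species, and (for 3+ species) every remaining pattern. Counts
#' always sum to the reference-set size; percentages are of that size,
#' rounded half away from zero to the nearest integer.
#'
#' @param matrix a `"presence_matrix"` or a logical matrix
#'   (reference x species).
#' @return an object of class `"presence_summary"`: `data.frame` with
#'   `category`, `species_set`, `n`, `pct`, plus attribute
#'   `n_reference`.
#' @export
summarize_presence <- function(matrix) {
  m <- if (inherits(matrix, "presence_matrix")) matrix$presence else matrix
  if (!is.matrix(m) || !is.logical(m))
    stop_validation("presence must be a logical matrix")
  n_ref <- nrow(m)
  species <- colnames(m)
  pattern <- apply(m, 1, function(r) paste(species[r], collapse = "+"))
  pattern[pattern == ""] <- "(none)"
  all_pat <- c("(none)",
               unlist(lapply(seq_along(species), function(k)
                 apply(utils::combn(species, k), 2, paste, collapse = "+"))))
  tab <- table(factor(pattern, levels = all_pat))
  category <- ifelse(all_pat == "(none)", "absent_in_all",
                     ifelse(all_pat == paste(species, collapse = "+"), "present_in_all",
                            ifelse(!grepl("+", all_pat, fixed = TRUE), "only_in", "shared_by")))
  out <- data.frame(category = category, species_set = all_pat,
                    n = as.integer(tab),
                    pct = round_half_up(100 * as.integer(tab) / max(n_ref, 1)),
                    stringsAsFactors = FALSE)
  attr(out, "n_reference") <- n_ref
  class(out) <- c("presence_summary", "data.frame")
  out
}

#' @export
print.presence_summary <- function(x, ...) {
  cat("Cross-species presence of", attr(x, "n_reference"), "reference proteins\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-14s %-28s %5d (%d%%)\n", x$category[i], x$species_set[i],
                x$n[i], x$pct[i]))
  invisible(x)
}

#' Write presence matrix and summary as tab-separated files
#' @param matrix a `"presence_matrix"`.
#' @param summary a `"presence_summary"`.
#' @param matrix_path,summary_path output paths.
#' @return invisibly, the paths.
#' @export
write_presence_report <- function(matrix, summary, matrix_path, summary_path) {
  m <- data.frame(reference_id = rownames(matrix$presence),
                  matrix$presence, check.names = FALSE)
  write.table(m, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(summary), summary_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(matrix_path, summary_path))
}
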