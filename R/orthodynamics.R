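# Quartile-based gene-family expansion/contraction calls and
# longest-gene annotation transfer.

#' Categorize per-species counts of one gene family by quartiles
#'
#' For one orthogroup, the first and third quartiles are computed over
#' the DISTINCT per-species gene counts (linear-interpolation quantiles,
#' `stats::quantile` type 7 by default). A species strictly below Q1 is
#' `contracted`, strictly above Q3 `expanded`, otherwise `neutral`.
#' With fewer than two distinct counts there is no dispersion and all
#' species are neutral.
#'
#' @param counts named (by species) non-negative integer vector of gene
#'   counts in the orthogroup.
#' @param quantile_type quantile definition passed to
#'   `stats::quantile(type=)`; default 7 (linear interpolation).
#' @param distinct use distinct counts for the quartiles (default TRUE);
#'   set FALSE to compute them over the raw per-species counts instead.
#' @return character vector (same names as `counts`) in
#'   `{expanded, contracted, neutral}`.
#' @examples
#' quartile_categorize(c(A = 1, B = 4, C = 10))
#' @export
quartile_categorize <- function(counts, quantile_type = 7, distinct = TRUE) {
  if (any(counts < 0)) stop_validation("gene counts must be >= 0")
  vals <- if (distinct) unique(as.numeric(counts)) else as.numeric(counts)
  if (length(unique(vals)) < 2)
    return(setNames(rep("neutral", length(counts)), names(counts)))
  q <- quantile(vals, probs = c(0.25, 0.75), type = quantile_type, names = FALSE)
  setNames(ifelse(counts < q[1], "contracted",
                  ifelse(counts > q[2], "expanded", "neutral")),
           names(counts))
}

#' Categorize every orthogroup in a gene-count table
#'
#' @param og_counts orthogroup count table: first column `og_id`, one
#'   integer column per species (OrthoFinder GeneCount dialect).
#' @param quantile_type,distinct see [quartile_categorize()].
#' @return `data.frame` with `og_id` and one category column per species.
#' @export
categorize_orthogroups <- function(og_counts, quantile_type = 7, distinct = TRUE) {
  assert_cols(og_counts, "og_id", "orthogroup count table")
  species <- setdiff(names(og_counts), "og_id")
  if (length(species) == 0) stop_validation("no species columns in count table")
  cats <- t(apply(as.matrix(og_counts[species]), 1, quartile_categorize,
                  quantile_type = quantile_type, distinct = distinct))
  out <- data.frame(og_id = og_counts$og_id, cats, stringsAsFactors = FALSE)
  names(out) <- c("og_id", species)
  rownames(out) <- NULL
  out
}

#' Transfer functional annotation from the longest orthogroup member
#'
#' The longest member gene (spliced coding length; ties broken by
#' lexicographically smaller gene id) is the orthogroup's representative
#' and its annotation is assigned to the whole group, whatever species
#' it comes from. When the representative lacks an annotation the group
#' annotation stays empty, with a warning — the rule is longest-only.
#'
#' @param members `data.frame` with columns `gene_id`, `species`,
#'   `length` and optionally `annotation` (`NA`/"" = unannotated).
#' @return one-row `data.frame`: `representative_gene`,
#'   `representative_species`, `annotation`.
#' @export
transfer_annotation <- function(members) {
  if (nrow(members) == 0) stop_domain("empty orthogroup")
  assert_cols(members, c("gene_id", "species", "length"), "orthogroup members")
  o <- order(-members$length, members$gene_id, method = "radix")
  top <- members[o[1], , drop = FALSE]
  ann <- if ("annotation" %in% names(members)) top$annotation else NA_character_
  if (is.na(ann) || identical(ann, ""))
    warning("longest member ", top$gene_id, " is unannotated; group left unannotated")
  data.frame(representative_gene = top$gene_id,
             representative_species = top$species,
             annotation = if (is.null(ann)) NA_character_ else ann,
             stringsAsFactors = FALSE)
}

#' Count distinct gene-family members recovered by homology search
#'
#' Given family query proteins searched against a proteome, counts the
#' distinct subject genes hit at `evalue < evalue_max` by any query —
#' the paralog-complement size of the family in that proteome.
#'
#' @param family_queries character vector of query ids belonging to the
#'   family.
#' @param hits hit table (`qseqid`, `sseqid`, `evalue`).
#' @param evalue_max significance cutoff (strict).
#' @return integer distinct-subject count.
#' @export
count_family_members <- function(family_queries, hits, evalue_max = 1e-5) {
  assert_cols(hits, c("qseqid", "sseqid", "evalue"), "hit table")
  sel <- hits$qseqid %in% family_queries & hits$evalue < evalue_max
  length(unique(hits$sseqid[sel]))
}

#' Venn-style shared/unique orthogroup counts
#'
#' @param membership logical matrix (orthogroup x species), or an
#'   orthogroup count table (counts > 0 define membership).
#' @return `data.frame` with `species_set`, `n`: one row per non-empty
#'   species combination plus `(none)`; rows partition the orthogroups.
#' @export
orthogroup_set_summary <- function(membership) {
  if (is.data.frame(membership) && "og_id" %in% names(membership)) {
    species <- setdiff(names(membership), "og_id")
    membership <- as.matrix(membership[species]) > 0
  }
  if (!is.matrix(membership) || !is.logical(membership))
    stop_validation("membership must be a logical matrix or a count table")
  species <- colnames(membership)
  pattern <- apply(membership, 1, function(r) paste(species[r], collapse = "+"))
  pattern[pattern == ""] <- "(none)"
  all_pat <- c("(none)",
               unlist(lapply(seq_along(species), function(k)
                 apply(utils::combn(species, k), 2, paste, collapse = "+"))))
  tab <- table(factor(pattern, levels = all_pat))
  data.frame(species_set = all_pat, n = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Read an orthogroup gene-count table
#'
#' Tab-separated, first column the orthogroup id, one count column per
#' species (OrthoFinder GeneCount dialect; a trailing `Total` column is
#' dropped when present).
#'
#' @param path file path.
#' @return count table with first column renamed `og_id`.
#' @export
read_orthogroup_counts <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(tab)[1] <- "og_id"
  tab$Total <- NULL
  num <- setdiff(names(tab), "og_id")
  for (s in num) {
    if (!is.numeric(tab[[s]]))
      stop_validation("non-numeric count column: ", s)
    if (any(tab[[s]] < 0)) stop_validation("negative counts in column ", s)
  }
  tab
}

#' @rdname read_orthogroup_counts
#' @param og_counts count table.
#' @export
write_orthogroup_counts <- function(og_counts, path) {
  write.table(og_counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
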