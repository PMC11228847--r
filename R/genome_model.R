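#' @importFrom stats quantile rlnorm rnorm rpois runif setNames
#' @importFrom utils read.delim write.table
NULL

# ---- scaffold records -------------------------------------------------------

#' Build a scaffold table from sequences or lengths
#'
#' Scaffolds are represented as a plain `data.frame` with one row per
#' scaffold: `scaffold_id`, `length` (bp) and optional `mean_coverage`
#' (mean mapped-read depth). When a `DNAStringSet` is given, lengths are
#' taken from the sequences.
#'
#' @param x a named `Biostrings::DNAStringSet`, or a named integer/numeric
#'   vector of scaffold lengths.
#' @param mean_coverage optional numeric vector of mean depths (recycled
#'   `NA` when absent), all values `>= 0`.
#' @return `data.frame` with columns `scaffold_id`, `length`,
#'   `mean_coverage`.
#' @export
scaffold_records <- function(x, mean_coverage = NULL) {
  if (methods::is(x, "DNAStringSet")) {
    lens <- Biostrings::width(x)
    ids <- names(x)
  } else {
    lens <- as.numeric(x)
    ids <- names(x)
  }
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop_validation("scaffolds must be named")
  if (anyDuplicated(ids))
    stop_validation("duplicate scaffold_id: ",
                    paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(lens < 1)) stop_validation("scaffold lengths must be >= 1 bp")
  cov <- if (is.null(mean_coverage)) rep(NA_real_, length(ids)) else as.numeric(mean_coverage)
  if (length(cov) != length(ids))
    stop_validation("mean_coverage must match the number of scaffolds")
  if (any(!is.na(cov) & cov < 0)) stop_validation("mean_coverage must be >= 0")
  data.frame(scaffold_id = as.character(ids), length = lens,
             mean_coverage = cov, stringsAsFactors = FALSE, row.names = NULL)
}

# ---- gene models ------------------------------------------------------------

#' Construct a gene-model table
#'
#' Genes use 0-based half-open coordinates internally (GFF3 on disk is
#' 1-based inclusive). Each gene carries an `exons` list column holding a
#' two-column matrix (`start`, `end`, 0-based half-open) for the exons of
#' its longest transcript; `exon_count` always equals `nrow(exons)`.
#' Genes are ordered by (`scaffold_id`, `start`, `gene_id`), which makes
#' flank lookup deterministic.
#'
#' @param gene_id,scaffold_id character vectors.
#' @param start,end 0-based half-open gene span, `0 <= start < end`.
#' @param strand `"+"` or `"-"`.
#' @param exons optional list of exon matrices; defaults to one exon
#'   spanning the gene.
#' @param cds optional list of CDS matrices (same convention) or `NULL`
#'   entries; `cds_length` falls back to the exon total when absent.
#' @param scaffolds optional scaffold table used to check `end <= length`.
#' @return sorted `data.frame` with columns `gene_id`, `scaffold_id`,
#'   `start`, `end`, `strand`, `exon_count`, `cds_length`, `exons`, `cds`.
#' @export
gene_models <- function(gene_id, scaffold_id, start, end, strand = "+",
                        exons = NULL, cds = NULL, scaffolds = NULL) {
  n <- length(gene_id)
  gene_id <- as.character(gene_id)
  scaffold_id <- rep_len(as.character(scaffold_id), n)
  start <- rep_len(as.numeric(start), n)
  end <- rep_len(as.numeric(end), n)
  strand <- rep_len(as.character(strand), n)
  if (anyDuplicated(gene_id))
    stop_validation("duplicate gene_id: ",
                    paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  if (any(start < 0) || any(start >= end))
    stop_validation("gene coordinates must satisfy 0 <= start < end")
  if (!all(strand %in% c("+", "-")))
    stop_validation("strand must be '+' or '-'")
  if (is.null(exons))
    exons <- mapply(function(s, e) cbind(start = s, end = e),
                    start, end, SIMPLIFY = FALSE)
  if (is.null(cds)) cds <- vector("list", n)
  for (i in seq_len(n)) {
    ex <- exons[[i]]
    if (is.null(ex)) {
      exons[[i]] <- ex <- cbind(start = start[i], end = end[i])
    }
    if (any(ex[, 1] < start[i]) || any(ex[, 2] > end[i]))
      stop_validation("exon outside gene span for gene ", gene_id[i])
  }
  if (!is.null(scaffolds)) {
    idx <- match(scaffold_id, scaffolds$scaffold_id)
    if (anyNA(idx))
      stop_validation("gene(s) reference unknown scaffold: ",
                      paste(unique(scaffold_id[is.na(idx)]), collapse = ", "))
    if (any(end > scaffolds$length[idx]))
      stop_validation("gene end beyond scaffold length")
  }
  exon_count <- vapply(exons, nrow, 1L)
  cds_length <- vapply(seq_len(n), function(i) {
    if (!is.null(cds[[i]]) && nrow(cds[[i]]) > 0)
      sum(cds[[i]][, 2] - cds[[i]][, 1])
    else sum(exons[[i]][, 2] - exons[[i]][, 1])
  }, numeric(1))
  g <- data.frame(gene_id = gene_id, scaffold_id = scaffold_id,
                  start = start, end = end, strand = strand,
                  exon_count = exon_count, cds_length = cds_length,
                  stringsAsFactors = FALSE)
  g$exons <- exons
  g$cds <- cds
  sort_genes(g)
}

#' @noRd
sort_genes <- function(genes) {
  o <- order(genes$scaffold_id, genes$start, genes$gene_id, method = "radix")
  genes <- genes[o, , drop = FALSE]
  rownames(genes) <- NULL
  genes
}

# ---- GFF3 I/O ---------------------------------------------------------------

#' Read gene models from GFF3
#'
#' Parses `gene`/`mRNA`/`exon`/`CDS` features (via `rtracklayer`) into the
#' internal gene-model table. On-disk coordinates are 1-based inclusive and
#' are converted to 0-based half-open. For multi-transcript genes the
#' longest transcript (largest summed exon length) is kept; `exon_count`
#' is its number of exon features. Genes whose `exon` features fall outside
#' the gene span raise a validation error; a line with the wrong number of
#' columns raises a parse error naming the line.
#'
#' @param path path to a GFF3 file.
#' @return gene-model `data.frame` (see [gene_models()]), ordered by
#'   (`scaffold_id`, `start`, `gene_id`).
#' @export
read_annotation <- function(path) {
  lines <- readLines(path, warn = FALSE)
  fasta_at <- which(startsWith(lines, "##FASTA"))
  body_end <- if (length(fasta_at)) fasta_at[1] - 1L else length(lines)
  for (i in seq_len(body_end)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    nf <- length(strsplit(ln, "\t", fixed = TRUE)[[1]])
    if (nf != 9L)
      stop_validation("malformed GFF3 line ", i, ": expected 9 tab-separated ",
                      "columns, found ", nf)
  }
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$type <- as.character(df$type)
  df$ID <- if ("ID" %in% names(df)) as.character(df$ID) else NA_character_
  parent <- if ("Parent" %in% names(df)) {
    vapply(df$Parent, function(p) if (length(p)) as.character(p)[1] else NA_character_,
           character(1))
  } else rep(NA_character_, nrow(df))
  df$parent <- parent

  is_gene <- df$type == "gene"
  is_tx <- df$type %in% c("mRNA", "transcript")
  is_exon <- df$type == "exon"
  is_cds <- df$type == "CDS"
  if (!any(is_gene)) stop_validation("no gene features found in ", path)
  genes_raw <- df[is_gene, , drop = FALSE]
  if (anyNA(genes_raw$ID)) stop_validation("gene feature without ID attribute")

  tx_parent <- setNames(df$parent[is_tx], df$ID[is_tx])
  # map exon/CDS to a gene: via transcript parent, or directly
  feat_gene <- function(p) {
    ifelse(p %in% names(tx_parent), unname(tx_parent[p]), p)
  }
  feat_tx <- function(p) ifelse(p %in% names(tx_parent), p, paste0(p, ".t0"))

  build_ranges <- function(sub) {
    # split per transcript id, 0-based half-open
    split(cbind(start = sub$start - 1, end = sub$end), feat_tx(sub$parent))
  }
  exon_df <- df[is_exon, , drop = FALSE]
  cds_df <- df[is_cds, , drop = FALSE]
  exon_gene <- feat_gene(exon_df$parent)
  cds_gene <- feat_gene(cds_df$parent)

  n <- nrow(genes_raw)
  exons <- vector("list", n)
  cds <- vector("list", n)
  for (i in seq_len(n)) {
    gid <- genes_raw$ID[i]
    ex <- exon_df[exon_gene == gid, , drop = FALSE]
    if (nrow(ex) == 0) {
      exons[[i]] <- cbind(start = genes_raw$start[i] - 1, end = genes_raw$end[i])
      next
    }
    tx_of <- feat_tx(ex$parent)
    by_tx <- split(seq_len(nrow(ex)), tx_of)
    tx_len <- vapply(by_tx, function(ii) sum(ex$end[ii] - ex$start[ii] + 1), numeric(1))
    best <- names(by_tx)[order(-tx_len, names(by_tx))][1]
    sel <- ex[by_tx[[best]], , drop = FALSE]
    sel <- sel[order(sel$start), , drop = FALSE]
    exons[[i]] <- cbind(start = sel$start - 1, end = sel$end)
    cd <- cds_df[cds_gene == gid & feat_tx(cds_df$parent) == best, , drop = FALSE]
    if (nrow(cd) > 0) {
      cd <- cd[order(cd$start), , drop = FALSE]
      cds[[i]] <- cbind(start = cd$start - 1, end = cd$end)
    }
  }
  gene_models(gene_id = genes_raw$ID,
              scaffold_id = as.character(genes_raw$seqnames),
              start = genes_raw$start - 1, end = genes_raw$end,
              strand = ifelse(as.character(genes_raw$strand) == "-", "-", "+"),
              exons = exons, cds = cds)
}

#' Write gene models to GFF3
#'
#' Emits one `gene`, one `mRNA` (`<gene_id>.t1`) and the stored exon (and
#' CDS, when present) features per gene, converting internal 0-based
#' half-open coordinates back to 1-based inclusive.
#'
#' @param genes gene-model table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(genes, path) {
  assert_cols(genes, c("gene_id", "scaffold_id", "start", "end", "strand"),
              "gene table")
  rows <- character(0)
  fmt <- function(seqid, src, type, s0, e0, strand, attrs) {
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
            seqid, src, type, as.integer(s0) + 1L, as.integer(e0), strand, attrs)
  }
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    tid <- paste0(g$gene_id, ".t1")
    rows <- c(rows,
              fmt(g$scaffold_id, "hgtscreen", "gene", g$start, g$end, g$strand,
                  paste0("ID=", g$gene_id)),
              fmt(g$scaffold_id, "hgtscreen", "mRNA", g$start, g$end, g$strand,
                  paste0("ID=", tid, ";Parent=", g$gene_id)))
    ex <- genes$exons[[i]]
    for (j in seq_len(nrow(ex)))
      rows <- c(rows, fmt(g$scaffold_id, "hgtscreen", "exon",
                          ex[j, 1], ex[j, 2], g$strand, paste0("Parent=", tid)))
    cd <- genes$cds[[i]]
    if (!is.null(cd))
      for (j in seq_len(nrow(cd)))
        rows <- c(rows, fmt(g$scaffold_id, "hgtscreen", "CDS",
                            cd[j, 1], cd[j, 2], g$strand, paste0("Parent=", tid)))
  }
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}

# ---- FASTA I/O --------------------------------------------------------------

#' Read scaffold sequences from FASTA
#' @param path FASTA path.
#' @return a `Biostrings::DNAStringSet`.
#' @export
read_scaffold_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Write scaffold sequences to FASTA (60-column wrap)
#' @param seqs a named `DNAStringSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scaffold_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

# ---- assembly metrics -------------------------------------------------------

#' Scaffold N50
#'
#' The N50 is the length L such that scaffolds of length >= L together
#' contain at least half of the assembly.
#'
#' @param lengths positive scaffold lengths (bp).
#' @return N50 in bp.
#' @examples
#' compute_n50(c(2, 3, 4, 5, 6)) # 5
#' @export
compute_n50 <- function(lengths) {
  if (length(lengths) == 0) stop_domain("compute_n50: empty length set")
  if (any(lengths <= 0)) stop_domain("compute_n50: lengths must be positive")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Mono:multi exonic gene ratio
#'
#' Number of single-exon genes divided by the number of multi-exon genes,
#' a standard diagnostic of fragmented annotation, reported to two
#' decimals. With no multi-exonic genes the ratio is `Inf` (with a
#' warning) rather than an error, so degenerate gene sets still report.
#'
#' @param genes gene-model table, or an integer vector of exon counts.
#' @return ratio rounded to 2 decimals.
#' @examples
#' mono_multi_ratio(c(1, 1, 2, 5)) # 1.00
#' @export
mono_multi_ratio <- function(genes) {
  ec <- if (is.data.frame(genes)) genes$exon_count else as.numeric(genes)
  if (length(ec) == 0) stop_domain("mono_multi_ratio: empty gene set")
  if (any(ec < 1)) stop_validation("exon counts must be >= 1")
  mono <- sum(ec == 1)
  multi <- sum(ec > 1)
  if (multi == 0) {
    warning("no multi-exonic genes; mono:multi ratio is infinite")
    return(Inf)
  }
  round_half_up(mono / multi, 2)
}

#' Percent of the assembly held by the k largest scaffolds
#'
#' @param lengths scaffold lengths (bp).
#' @param k number of largest scaffolds, `1 <= k <= length(lengths)`.
#' @param digits rounding for the percentage (default nearest integer).
#' @return percentage in `[0, 100]`.
#' @export
percent_in_top_k <- function(lengths, k, digits = 0) {
  if (length(lengths) == 0) stop_domain("percent_in_top_k: empty length set")
  if (k < 1 || k > length(lengths))
    stop_domain("percent_in_top_k: k must be in [1, ", length(lengths), "]")
  s <- sort(lengths, decreasing = TRUE)
  round_half_up(100 * sum(s[seq_len(k)]) / sum(s), digits)
}

#' Bin scaffolds by mean read coverage
#'
#' Reproduces the coverage-level categorization used during haplotig
#' purging: depth bins are left-open/right-closed at the three cutoffs
#' (defaults 0, 7, 65). Zero coverage means no read support and falls in
#' the `junk` bin; `suspect` bins flag scaffolds for review rather than
#' removal.
#'
#' @param mean_coverage numeric depths `>= 0` (vectorized).
#' @param cutoffs strictly increasing `(low, mid, high)`.
#' @return factor with levels `junk`, `suspect_low`, `normal`,
#'   `suspect_high`.
#' @export
coverage_bin <- function(mean_coverage, cutoffs = c(0, 7, 65)) {
  if (length(cutoffs) != 3 || any(diff(cutoffs) <= 0))
    stop_config("coverage cutoffs must be three strictly increasing values")
  if (any(mean_coverage < 0, na.rm = TRUE))
    stop_validation("mean_coverage must be >= 0")
  cut(mean_coverage, breaks = c(-Inf, cutoffs, Inf), right = TRUE,
      labels = c("junk", "suspect_low", "normal", "suspect_high"))
}

#' Summary metrics for an assembly
#'
#' @param scaffolds scaffold table ([scaffold_records()]).
#' @param genes optional gene-model table (for the mono:multi ratio).
#' @param top_k number of largest scaffolds for the percent-in-top-k
#'   metric (default: all, i.e. 100%).
#' @return an `"assembly_metrics"` list: `total_length`, `scaffold_count`,
#'   `n50`, `mono_multi_ratio`, `pct_top_k`, `top_k`.
#' @export
assembly_metrics <- function(scaffolds, genes = NULL, top_k = nrow(scaffolds)) {
  m <- list(total_length = sum(scaffolds$length),
            scaffold_count = nrow(scaffolds),
            n50 = compute_n50(scaffolds$length),
            mono_multi_ratio = if (!is.null(genes) && nrow(genes) > 0)
              suppressWarnings(mono_multi_ratio(genes)) else NA_real_,
            pct_top_k = percent_in_top_k(scaffolds$length, top_k),
            top_k = top_k)
  class(m) <- "assembly_metrics"
  m
}

#' @export
print.assembly_metrics <- function(x, ...) {
  cat("Assembly metrics\n")
  cat(sprintf("  scaffolds:        %d\n", x$scaffold_count))
  cat(sprintf("  total length:     %s bp\n", format(x$total_length, big.mark = ",")))
  cat(sprintf("  N50:              %s bp\n", format(x$n50, big.mark = ",")))
  cat(sprintf("  mono:multi ratio: %s\n", format(x$mono_multi_ratio)))
  cat(sprintf("  %% in top %d:      %g%%\n", x$top_k, x$pct_top_k))
  invisible(x)
}

#' Write a metrics report as tab-separated key/value pairs
#' @param metrics an `"assembly_metrics"` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(metrics, path) {
  kv <- data.frame(key = c("total_length", "scaffold_count", "n50",
                           "mono_multi_ratio", "pct_top_k", "top_k"),
                   value = c(metrics$total_length, metrics$scaffold_count,
                             metrics$n50, metrics$mono_multi_ratio,
                             metrics$pct_top_k, metrics$top_k))
  write.table(kv, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
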