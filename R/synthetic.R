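# Synthetic annotated assemblies with planted truth.
#
# The generator emulates the data structure the screening pipeline
# consumes — scaffolds, gene models, taxonomy calls, donor/recipient hit
# tables, transcript tables, orthogroup counts — with per-scaffold and
# per-gene truth labels, so every stage can be scored against a known
# answer. Sequences are random nucleotides: all structure lives in the
# annotations and hit tables, because that is all the screening
# procedure ever looks at.
#
# Scaffold classes are constructed with a margin around the removal
# thresholds: contaminant scaffolds sit at fraction >= threshold +
# margin for their length class, clean (and decoy) scaffolds at most
# threshold - margin, which makes planted recovery exact by design.

#' Parameters for the synthetic-assembly generator
#'
#' @param seed integer; fully determines every generated object.
#' @param n_scaffolds total scaffold count.
#' @param contaminant_scaffold_fraction fraction of scaffolds planted as
#'   contaminant (split evenly between the short- and long-rule classes).
#' @param n_microbial_only scaffolds with microbial + unannotated genes
#'   only (no plant gene), below the fraction thresholds.
#' @param contaminant_gene_margin separation (>= 0.05) between planted
#'   contaminant-gene fractions and the removal thresholds.
#' @param n_true_hgt genes planted as genuine transfers: 1-4 distinct
#'   donor subjects, no recipient hit, plant genes on both flanks.
#' @param n_decoy_flank decoy candidates with a valid hit profile but
#'   non-plant flanking genes (at most `decoys_per_scaffold` per decoy
#'   scaffold).
#' @param decoys_per_scaffold decoys hosted per decoy scaffold (1-3;
#'   capped so the decoy scaffold's microbial fraction stays below the
#'   long-rule threshold minus the margin).
#' @param n_decoy_donor_excess decoys with >= 5 donor subjects.
#' @param n_decoy_recipient decoys with >= 1 recipient hit.
#' @param genes_per_10kb nominal gene density (the generator lays genes
#'   on a 1 kb grid and sizes scaffolds to match their length class).
#' @param n_transcripts,internal_orf_fraction,low_fpkm_fraction,
#'   transcript_contam_fractions transcript-set shape: size, fraction of
#'   internal ORFs, fraction at or below the FPKM floor, and named
#'   per-scope contaminant fractions (defaults follow the published
#'   transcriptome mixture: fungi 15.93%, bacteria 0.64%, insecta 0.12%,
#'   amoeba 0.06%).
#' @param unannotated_transcript_fraction transcripts with no taxonomy
#'   call.
#' @param domainless_fraction_mono,domainless_fraction_multi probability
#'   that a mono-/multi-exonic gene lacks a complete protein domain
#'   (mono-exonic models are mostly spurious, hence the asymmetry).
#' @param og_n_groups,og_species,og_planted_expanded,og_planted_contracted
#'   orthogroup-table shape: group count, species names (>= 3 when
#'   dynamics are planted), and how many groups are planted expanded /
#'   contracted for the first species.
#' @return validated list of class `"generator_params"`.
#' @export
generator_params <- function(seed = 1L,
                             n_scaffolds = 40L,
                             contaminant_scaffold_fraction = 0.2,
                             n_microbial_only = 2L,
                             contaminant_gene_margin = 0.1,
                             n_true_hgt = 2L,
                             n_decoy_flank = 6L,
                             decoys_per_scaffold = 3L,
                             n_decoy_donor_excess = 2L,
                             n_decoy_recipient = 2L,
                             genes_per_10kb = 4,
                             n_transcripts = 2000L,
                             internal_orf_fraction = 0.10,
                             low_fpkm_fraction = 0.15,
                             transcript_contam_fractions = c(fungi = 0.1593,
                                                             bacteria = 0.0064,
                                                             insecta = 0.0012,
                                                             amoeba = 0.0006),
                             unannotated_transcript_fraction = 0.185,
                             domainless_fraction_mono = 0.6,
                             domainless_fraction_multi = 0.05,
                             og_n_groups = 500L,
                             og_species = c("spA", "spB", "spC"),
                             og_planted_expanded = 50L,
                             og_planted_contracted = 100L) {
  p <- as.list(environment())
  p$seed <- as.integer(seed)
  if (p$contaminant_gene_margin < 0.05)
    stop_config("contaminant_gene_margin must be >= 0.05")
  if (p$contaminant_scaffold_fraction < 0 || p$contaminant_scaffold_fraction > 1)
    stop_config("contaminant_scaffold_fraction must be in [0, 1]")
  if (0.55 + p$contaminant_gene_margin > 1)
    stop_config("margin makes the planted long-rule fraction exceed 1")
  if (p$decoys_per_scaffold < 1 || p$decoys_per_scaffold > 3)
    stop_config("decoys_per_scaffold must be 1-3 (more would push the decoy ",
                "scaffold over the long-rule contaminant fraction)")
  if ((p$og_planted_expanded > 0 || p$og_planted_contracted > 0) &&
      length(p$og_species) < 3)
    stop_config("planting expansion/contraction needs >= 3 species ",
                "(with 2 the extremes always straddle both quartiles)")
  if (p$og_planted_expanded + p$og_planted_contracted > p$og_n_groups)
    stop_config("planted orthogroup categories exceed og_n_groups")
  n_contam <- round(p$contaminant_scaffold_fraction * p$n_scaffolds)
  n_decoy_scaf <- ceiling(p$n_decoy_flank / p$decoys_per_scaffold)
  n_special <- n_contam + p$n_microbial_only + n_decoy_scaf +
    p$n_true_hgt + p$n_decoy_donor_excess + p$n_decoy_recipient + 2
  if (n_special > p$n_scaffolds)
    stop_config("n_scaffolds too small for the requested planted structure (",
                n_special, " needed)")
  class(p) <- "generator_params"
  p
}

#' The small-scale scenario replaying the published screen
#'
#' A preset of [generator_params()] that reproduces the published
#' decision structure at desk scale: 31 hit-profile candidates of which
#' 29 are decoys spread over 10 contaminated scaffolds (flanked by
#' non-plant genes) and 2 are genuine transfers flanked by plant genes —
#' so the flank stage removes exactly 10 scaffolds and retains exactly
#' 2 candidates.
#'
#' @param seed integer seed.
#' @return `"generator_params"` object.
#' @export
published_preset_params <- function(seed = 1L) {
  generator_params(seed = seed,
                   n_scaffolds = 60L,
                   contaminant_scaffold_fraction = 0.2,
                   n_microbial_only = 2L,
                   n_true_hgt = 2L,
                   n_decoy_flank = 29L,
                   decoys_per_scaffold = 3L,
                   n_decoy_donor_excess = 0L,
                   n_decoy_recipient = 0L)
}

#' @noRd
random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' @noRd
make_exons <- function(start, end, n_exons) {
  if (n_exons == 1) return(cbind(start = start, end = end))
  w <- floor((end - start) / (2 * n_exons - 1))
  s <- start + (seq_len(n_exons) - 1) * 2 * w
  cbind(start = s, end = pmin(s + w, end))
}

#' Generate an annotated synthetic assembly with planted truth
#'
#' Builds scaffolds, gene models, taxonomy calls and truth labels. Gene
#' labels are `native_plant`, `contaminant_gene`, `unannotated`,
#' `true_hgt`, `decoy_flank`, `decoy_donor_excess`, `decoy_recipient`;
#' scaffold labels are `clean`, `contaminant`, `microbial_only`,
#' `hgt_decoy`. Candidate genes (true and decoy) carry scope
#' `unannotated` — a novel transfer has no plant annotation evidence —
#' so decoy scaffolds pass the composition filters and are caught only
#' at the flank stage.
#'
#' @param params a [generator_params()].
#' @return list of class `"hgt_simulation"`: `scaffolds`, `genes`,
#'   `calls`, `sequences` (`DNAStringSet`), `truth`
#'   (`list(scaffolds, genes, ledger)`), `params`.
#' @export
generate_assembly <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  set.seed(params$seed)
  n_contam <- round(params$contaminant_scaffold_fraction * params$n_scaffolds)
  n_contam_short <- floor(n_contam / 2)
  n_contam_long <- n_contam - n_contam_short
  n_decoy_scaf <- ceiling(params$n_decoy_flank / params$decoys_per_scaffold)
  # distribute flank decoys across decoy scaffolds (last may hold fewer)
  decoy_alloc <- if (n_decoy_scaf > 0) {
    k <- rep(params$decoys_per_scaffold, n_decoy_scaf)
    k[n_decoy_scaf] <- params$n_decoy_flank - sum(k[-n_decoy_scaf])
    k
  } else integer(0)

  types <- c(rep("contam_short", n_contam_short),
             rep("contam_long", n_contam_long),
             rep("microbial_only", params$n_microbial_only),
             rep("hgt_decoy", n_decoy_scaf),
             rep("true_hgt_host", params$n_true_hgt),
             rep("donor_excess_host", params$n_decoy_donor_excess),
             rep("recipient_host", params$n_decoy_recipient),
             rep("flagged_clean", 2L))
  types <- c(types, rep("clean", params$n_scaffolds - length(types)))
  # shuffle so planted classes are not positionally ordered
  types <- sample(types)

  scaffold_id <- sprintf("scaf%03d", seq_along(types))
  gene_rows <- list()
  scaf_len <- numeric(length(types))
  scaf_label <- character(length(types))
  gene_counter <- 0L
  decoy_i <- 0L

  for (si in seq_along(types)) {
    ty <- types[si]
    if (ty == "contam_short") {
      n <- sample(5:8, 1)
      n_bad <- ceiling(n * (0.40 + params$contaminant_gene_margin + 0.1))
      labels <- sample(c(rep("contaminant_gene", n_bad),
                         rep("native_plant", n - n_bad)))
      long <- FALSE; scaf_label[si] <- "contaminant"
    } else if (ty == "contam_long") {
      n <- sample(12:16, 1)
      n_bad <- ceiling(n * (0.55 + params$contaminant_gene_margin + 0.05))
      labels <- sample(c(rep("contaminant_gene", n_bad),
                         rep("native_plant", n - n_bad)))
      long <- TRUE; scaf_label[si] <- "contaminant"
    } else if (ty == "microbial_only") {
      labels <- c("contaminant_gene", "unannotated", "contaminant_gene",
                  "unannotated", "unannotated")
      long <- TRUE; scaf_label[si] <- "microbial_only"
    } else if (ty == "hgt_decoy") {
      decoy_i <- decoy_i + 1L
      k <- decoy_alloc[decoy_i]
      labels <- c("native_plant",
                  as.vector(rbind(rep("contaminant_gene", k),
                                  rep("decoy_flank", k))),
                  "contaminant_gene", "native_plant")
      long <- TRUE; scaf_label[si] <- "hgt_decoy"
    } else if (ty %in% c("true_hgt_host", "donor_excess_host", "recipient_host")) {
      lab <- switch(ty, true_hgt_host = "true_hgt",
                    donor_excess_host = "decoy_donor_excess",
                    recipient_host = "decoy_recipient")
      n <- sample(5:9, 1)
      labels <- rep("native_plant", n)
      labels[3] <- lab
      long <- sample(c(TRUE, FALSE), 1); scaf_label[si] <- "clean"
    } else if (ty == "flagged_clean") {
      n <- sample(6:9, 1)
      labels <- rep("native_plant", n)
      labels[n] <- "contaminant_gene"
      long <- sample(c(TRUE, FALSE), 1); scaf_label[si] <- "clean"
    } else {
      n <- sample(4:9, 1)
      labels <- rep("native_plant", n)
      if (n >= 6) labels[sample(2:(n - 1), 1)] <- "unannotated"
      long <- sample(c(TRUE, FALSE), 1); scaf_label[si] <- "clean"
    }
    n <- length(labels)
    base_len <- n * 1000 + 500
    scaf_len[si] <- if (long) max(12000, base_len) + sample(0:4000, 1)
    else min(base_len, 9500)
    ids <- sprintf("g%05d", gene_counter + seq_len(n))
    gene_counter <- gene_counter + n
    start <- (seq_len(n) - 1) * 1000 + 100
    exn <- ifelse(labels == "native_plant",
                  sample(1:6, n, replace = TRUE, prob = c(1, 3, 3, 2, 1, 1)), 1L)
    gene_rows[[si]] <- data.frame(gene_id = ids, scaffold_id = scaffold_id[si],
                                  start = start, end = start + 800,
                                  strand = sample(c("+", "-"), n, replace = TRUE),
                                  n_exons = exn, label = labels,
                                  stringsAsFactors = FALSE)
  }

  gdf <- do.call(rbind, gene_rows)
  exons <- mapply(make_exons, gdf$start, gdf$end, gdf$n_exons, SIMPLIFY = FALSE)
  scaffolds <- scaffold_records(setNames(scaf_len, scaffold_id),
                                mean_coverage = round(pmax(0, rnorm(length(types), 30, 12)), 1))
  genes <- gene_models(gdf$gene_id, gdf$scaffold_id, gdf$start, gdf$end,
                       gdf$strand, exons = exons, scaffolds = scaffolds)

  lab <- gdf$label[match(genes$gene_id, gdf$gene_id)]
  contam_scope <- sample(c("bacteria", "fungi", "archaea"), nrow(genes),
                         replace = TRUE, prob = c(0.5, 0.4, 0.1))
  similarity <- ifelse(lab == "native_plant", "plant",
                       ifelse(lab == "contaminant_gene", contam_scope, NA))
  calls <- assign_scope(genes$gene_id, similarity = similarity,
                        best_evalue = ifelse(is.na(similarity), NA_real_,
                                             10^-runif(nrow(genes), 20, 80)))

  sequences <- Biostrings::DNAStringSet(vapply(scaf_len, random_seq, character(1)))
  names(sequences) <- scaffold_id

  gene_truth <- data.frame(gene_id = genes$gene_id,
                           scaffold_id = genes$scaffold_id,
                           label = lab, stringsAsFactors = FALSE)
  scaf_truth <- data.frame(scaffold_id = scaffold_id, label = scaf_label,
                           stringsAsFactors = FALSE)
  ledger <- as.data.frame(table(label = c(scaf_truth$label, gene_truth$label)),
                          stringsAsFactors = FALSE)
  names(ledger) <- c("label", "n")
  sim <- list(scaffolds = scaffolds, genes = genes, calls = calls,
              sequences = sequences,
              truth = list(scaffolds = scaf_truth, genes = gene_truth,
                           ledger = ledger),
              params = params)
  class(sim) <- "hgt_simulation"
  sim
}

#' Generate donor/recipient hit tables consistent with the truth labels
#'
#' True transfers get 1-4 distinct donor subjects at E-value <= 1e-8 and
#' no recipient hit; flank decoys get the same (they fail only on their
#' neighborhood); donor-excess decoys >= 5 donor subjects; recipient
#' decoys a valid donor profile plus >= 1 recipient hit; native plant
#' genes >= 1 recipient hit; contaminant genes >= 5 donor subjects.
#' Some unannotated genes receive non-significant hits (E-value above
#' the cutoff) and some subjects extra HSP rows, to exercise the strict
#' threshold and distinct-subject counting.
#'
#' @param sim an `"hgt_simulation"` from [generate_assembly()].
#' @return the simulation with a `hits` element (13-column hit table)
#'   and `truth$hit_profile` recording each planted profile.
#' @export
generate_hit_tables <- function(sim) {
  stopifnot(inherits(sim, "hgt_simulation"))
  set.seed(sim$params$seed + 1L)
  rows <- list()
  profile <- list()
  mk <- function(gene, db, n_subj, lo, hi, extra_hsp = FALSE) {
    if (n_subj == 0) return(NULL)
    subj <- sprintf("%s_subj_%s_%02d", db, gene, seq_len(n_subj))
    ev <- 10^-runif(n_subj, lo, hi)
    r <- data.frame(qseqid = gene, sseqid = subj,
                    pident = round(runif(n_subj, 30, 95), 1),
                    length = sample(80:400, n_subj, replace = TRUE),
                    mismatch = sample(0:50, n_subj, replace = TRUE),
                    gapopen = sample(0:5, n_subj, replace = TRUE),
                    qstart = 1L, qend = 200L, sstart = 1L, send = 200L,
                    evalue = ev,
                    bitscore = round(runif(n_subj, 60, 400), 1),
                    db_label = db, stringsAsFactors = FALSE)
    if (extra_hsp && n_subj >= 1) r <- rbind(r, r[1, ])
    r
  }
  tg <- sim$truth$genes
  for (i in seq_len(nrow(tg))) {
    g <- tg$gene_id[i]
    lab <- tg$label[i]
    if (lab %in% c("true_hgt", "decoy_flank")) {
      nd <- sample(1:4, 1)
      dbs <- sample(DONOR_LABELS, nd, replace = TRUE)
      r <- do.call(rbind, lapply(unique(dbs), function(db)
        mk(g, db, sum(dbs == db), 8, 30, extra_hsp = TRUE)))
      profile[[g]] <- data.frame(gene_id = g, donor_subjects = nd,
                                 recipient_subjects = 0L)
    } else if (lab == "decoy_donor_excess") {
      nd <- sample(5:9, 1)
      r <- mk(g, sample(DONOR_LABELS, 1), nd, 8, 30)
      profile[[g]] <- data.frame(gene_id = g, donor_subjects = nd,
                                 recipient_subjects = 0L)
    } else if (lab == "decoy_recipient") {
      nd <- sample(1:4, 1)
      r <- rbind(mk(g, sample(DONOR_LABELS, 1), nd, 8, 30),
                 mk(g, sample(RECIPIENT_LABELS, 1), 1, 8, 30))
      profile[[g]] <- data.frame(gene_id = g, donor_subjects = nd,
                                 recipient_subjects = 1L)
    } else if (lab == "native_plant") {
      nr <- sample(1:3, 1)
      nd <- sample(0:6, 1)
      r <- rbind(mk(g, sample(RECIPIENT_LABELS, 1), nr, 10, 60),
                 if (nd > 0) mk(g, sample(DONOR_LABELS, 1), nd, 6, 20))
      profile[[g]] <- data.frame(gene_id = g, donor_subjects = nd,
                                 recipient_subjects = nr)
    } else if (lab == "contaminant_gene") {
      nd <- sample(5:12, 1)
      r <- mk(g, sample(DONOR_LABELS, 1), nd, 8, 40)
      profile[[g]] <- data.frame(gene_id = g, donor_subjects = nd,
                                 recipient_subjects = 0L)
    } else { # unannotated: occasionally a weak, non-significant hit
      r <- if (runif(1) < 0.3) {
        ev <- runif(1, 2, 4) # E-value 1e-4 .. 1e-2, above the cutoff
        h <- mk(g, sample(DONOR_LABELS, 1), 1, ev, ev)
        h
      } else NULL
      profile[[g]] <- data.frame(gene_id = g, donor_subjects = 0L,
                                 recipient_subjects = 0L)
    }
    rows[[i]] <- r
  }
  hits <- do.call(rbind, c(rows, make.row.names = FALSE))
  # shuffle rows: downstream results must not depend on row order
  hits <- hits[sample(nrow(hits)), , drop = FALSE]
  rownames(hits) <- NULL
  sim$hits <- hits
  sim$truth$hit_profile <- do.call(rbind, c(profile, make.row.names = FALSE))
  sim
}

#' Generate an orthogroup count table with planted dynamics
#'
#' Planted groups use three distinct per-species counts low < mid <
#' high; with linear-interpolation quartiles of three distinct values
#' the low count always falls below Q1 and the high count above Q3, so
#' planted categories are guaranteed by construction. Expanded groups
#' give the first species the high count, contracted groups the low
#' count; the remaining groups use one identical count everywhere
#' (neutral).
#'
#' @param params a [generator_params()].
#' @return `list(counts, truth)`: the count table (og_id + one column
#'   per species) and the planted per-species category table.
#' @export
generate_orthogroup_table <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  set.seed(params$seed + 2L)
  sp <- params$og_species
  n <- params$og_n_groups
  nE <- params$og_planted_expanded
  nC <- params$og_planted_contracted
  kind <- sample(c(rep("expanded", nE), rep("contracted", nC),
                   rep("neutral", n - nE - nC)))
  counts <- matrix(0L, n, length(sp), dimnames = list(NULL, sp))
  cats <- matrix("neutral", n, length(sp), dimnames = list(NULL, sp))
  for (i in seq_len(n)) {
    if (kind[i] == "neutral") {
      counts[i, ] <- sample(1:8, 1)
    } else {
      lo <- sample(0:2, 1); mid <- sample(4:6, 1); hi <- sample(9:15, 1)
      if (kind[i] == "expanded") {
        counts[i, ] <- c(hi, mid, lo, rep(mid, length(sp) - 3))
        cats[i, c(1, 3)] <- c("expanded", "contracted")
      } else {
        counts[i, ] <- c(lo, mid, hi, rep(mid, length(sp) - 3))
        cats[i, c(1, 3)] <- c("contracted", "expanded")
      }
    }
  }
  og_id <- sprintf("OG%07d", seq_len(n))
  list(counts = data.frame(og_id = og_id, counts, stringsAsFactors = FALSE),
       truth = data.frame(og_id = og_id, cats, stringsAsFactors = FALSE))
}

#' Generate transcript-level tables (ORFs, expression, taxonomy)
#'
#' @param params a [generator_params()].
#' @return `list(orfs, expression, calls, truth)`; `truth` records the
#'   planted internal, low-expression and per-scope contaminant counts.
#' @export
generate_transcript_tables <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  set.seed(params$seed + 3L)
  n <- params$n_transcripts
  ids <- sprintf("tx%06d", seq_len(n))

  n_internal <- round(params$internal_orf_fraction * n)
  comp <- sample(c(rep("internal", n_internal),
                   sample(c("complete", "five_prime_partial", "three_prime_partial"),
                          n - n_internal, replace = TRUE, prob = c(6, 2, 2))))
  orfs <- data.frame(orf_id = ids, completeness = comp, stringsAsFactors = FALSE)

  n_low <- round(params$low_fpkm_fraction * n)
  fpkm <- runif(n, 0.51, 80)
  if (n_low > 0) {
    low_idx <- sample(n, n_low)
    fpkm[low_idx] <- runif(n_low, 0, 0.5)
    fpkm[low_idx[1]] <- 0.5 # exact-boundary case: removed under the strict rule
  }
  expr <- data.frame(transcript_id = ids, fpkm = round(fpkm, 3),
                     stringsAsFactors = FALSE)

  fr <- params$transcript_contam_fractions
  n_scope <- round(fr * n)
  n_unann <- round(params$unannotated_transcript_fraction * n)
  scopes <- c(unlist(mapply(rep, names(n_scope), n_scope)),
              rep(NA, n_unann))
  scopes <- c(scopes, rep("plant", n - length(scopes)))
  scopes <- sample(scopes)
  calls <- assign_scope(ids, similarity = scopes)

  truth <- list(n = n, n_internal = n_internal,
                n_low_fpkm = n_low,
                contaminant_counts = n_scope,
                n_unannotated = n_unann)
  list(orfs = orfs, expression = expr, calls = calls, truth = truth)
}

#' Generate a complete-domain hit table for the gene set
#'
#' @param sim an `"hgt_simulation"`.
#' @return the simulation with `domains` (gene_id/domain rows) and
#'   `truth$domain_retained` (ids of genes planted with a domain).
#' @export
generate_domain_table <- function(sim) {
  stopifnot(inherits(sim, "hgt_simulation"))
  set.seed(sim$params$seed + 4L)
  p_less <- ifelse(sim$genes$exon_count == 1,
                   sim$params$domainless_fraction_mono,
                   sim$params$domainless_fraction_multi)
  # planted candidates keep a domain: the HGT screen runs on the
  # domain-filtered gene space
  cand <- sim$truth$genes$label %in% c("true_hgt", "decoy_flank",
                                       "decoy_donor_excess", "decoy_recipient")
  has_domain <- runif(nrow(sim$genes)) >= p_less | cand
  keep_ids <- sim$genes$gene_id[has_domain]
  nd <- pmin(3, 1 + rpois(length(keep_ids), 0.7))
  sim$domains <- data.frame(gene_id = rep(keep_ids, nd),
                            domain = sprintf("PF%05d", sample(1e4, sum(nd), replace = TRUE)),
                            stringsAsFactors = FALSE)
  sim$truth$domain_retained <- keep_ids
  sim
}

#' Generate per-species best-hit tables with a planted presence pattern
#'
#' Used to test the cross-species presence screen: each reference id is
#' assigned a presence pattern over the species; present pairs get one
#' or more significant hits, a few absent pairs get a hit above the
#' cutoff.
#'
#' @param n_reference reference-set size.
#' @param pattern_counts named integer vector over patterns
#'   (`"(none)"`, single species, `"spX+spY"`, ...) summing to
#'   `n_reference`.
#' @param species species names.
#' @param seed integer seed.
#' @return `list(reference_ids, hit_tables, truth)`.
#' @export
generate_presence_tables <- function(n_reference = 273L,
                                     pattern_counts = c("(none)" = 91L,
                                                        "other1" = 15L,
                                                        "other2" = 7L,
                                                        "other1+other2" = 160L),
                                     species = c("other1", "other2"),
                                     seed = 1L) {
  if (sum(pattern_counts) != n_reference)
    stop_config("pattern counts must sum to n_reference")
  set.seed(seed + 5L)
  ids <- sprintf("ref%04d", seq_len(n_reference))
  pattern <- sample(rep(names(pattern_counts), pattern_counts))
  tables <- list()
  for (sp in species) {
    in_sp <- vapply(strsplit(pattern, "+", fixed = TRUE),
                    function(p) sp %in% p, logical(1))
    q <- ids[in_sp]
    n <- length(q)
    tab <- data.frame(qseqid = q,
                      sseqid = sprintf("%s_prot_%04d", sp, sample(9999, n)),
                      pident = round(runif(n, 40, 99), 1), length = 150L,
                      mismatch = 10L, gapopen = 1L, qstart = 1L, qend = 150L,
                      sstart = 1L, send = 150L,
                      evalue = 10^-runif(n, 6, 80),
                      bitscore = round(runif(n, 80, 500), 1),
                      db_label = "metazoa", stringsAsFactors = FALSE)
    # weak, non-significant hits for a few absent references
    ab <- sample(ids[!in_sp], min(5, sum(!in_sp)))
    if (length(ab)) {
      weak <- tab[rep(1, length(ab)), , drop = FALSE]
      weak$qseqid <- ab
      weak$evalue <- 10^-runif(length(ab), 2, 4.9)
      tab <- rbind(tab, weak)
    }
    tables[[sp]] <- tab[sample(nrow(tab)), , drop = FALSE]
  }
  list(reference_ids = ids, hit_tables = tables,
       truth = data.frame(reference_id = ids, pattern = pattern,
                          stringsAsFactors = FALSE))
}

#' Run every generator and collect one simulation object
#'
#' @param params a [generator_params()].
#' @return `"hgt_simulation"` with all elements populated (`scaffolds`,
#'   `genes`, `calls`, `sequences`, `hits`, `domains`, `orthogroups`,
#'   `transcripts`, `truth`).
#' @export
simulate_screen_data <- function(params = generator_params()) {
  sim <- generate_assembly(params)
  sim <- generate_hit_tables(sim)
  sim <- generate_domain_table(sim)
  og <- generate_orthogroup_table(params)
  sim$orthogroups <- og$counts
  sim$truth$orthogroups <- og$truth
  tx <- generate_transcript_tables(params)
  sim$transcripts <- tx[c("orfs", "expression", "calls")]
  sim$truth$transcripts <- tx$truth
  sim
}

#' @export
print.hgt_simulation <- function(x, ...) {
  cat("Synthetic annotated assembly (seed", x$params$seed, ")\n")
  cat(sprintf("  scaffolds: %d   genes: %d\n", nrow(x$scaffolds), nrow(x$genes)))
  tab <- table(x$truth$scaffolds$label)
  cat("  scaffold truth:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  tab <- table(x$truth$genes$label)
  cat("  gene truth:    ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write a simulation to disk as standard-format fixture files
#'
#' Emits `scaffolds.fasta` (60-column), `genes.gff3`, `taxonomy.tsv`,
#' `hits.tsv` (13-column, headerless), `domains.tsv`,
#' `orthogroups.tsv`, `orfs.tsv`, `expression.tsv`,
#' `transcript_taxonomy.tsv`, `truth_scaffolds.tsv`, `truth_genes.tsv`
#' and `truth_ledger.tsv` (headed by generator version, seed and key
#' parameters). Contents are a pure function of the generator seed.
#'
#' @param sim an `"hgt_simulation"` from [simulate_screen_data()].
#' @param outdir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_fixture <- function(sim, outdir) {
  stopifnot(inherits(sim, "hgt_simulation"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  write_scaffold_fasta(sim$sequences, p("scaffolds.fasta"))
  write_annotation(sim$genes, p("genes.gff3"))
  write_taxonomy_calls(sim$calls, p("taxonomy.tsv"))
  write.table(sim$hits, p("hits.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(sim$domains, p("domains.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_orthogroup_counts(sim$orthogroups, p("orthogroups.tsv"))
  write.table(sim$transcripts$orfs, p("orfs.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$transcripts$expression, p("expression.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_taxonomy_calls(sim$transcripts$calls, p("transcript_taxonomy.tsv"))
  write.table(sim$truth$scaffolds, p("truth_scaffolds.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$truth$genes, p("truth_genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  hdr <- sprintf("# hgtscreen synthetic fixture v%s seed=%d n_scaffolds=%d",
                 as.character(utils::packageVersion("hgtscreen")),
                 sim$params$seed, sim$params$n_scaffolds)
  ledger_path <- p("truth_ledger.tsv")
  writeLines(hdr, ledger_path)
  suppressWarnings(
    write.table(sim$truth$ledger, ledger_path, sep = "\t", quote = FALSE,
                row.names = FALSE, append = TRUE))
  files <- c("scaffolds.fasta", "genes.gff3", "taxonomy.tsv", "hits.tsv",
             "domains.tsv", "orthogroups.tsv", "orfs.tsv", "expression.tsv",
             "transcript_taxonomy.tsv", "truth_scaffolds.tsv",
             "truth_genes.tsv", "truth_ledger.tsv")
  invisible(vapply(files, p, character(1)))
}
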