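# Donor/recipient hit-profile candidate calling and flank validation.

mk_hits <- function(qseqid, sseqid, evalue, db_label, bitscore = 100) {
  n <- length(qseqid)
  data.frame(qseqid = qseqid, sseqid = sseqid,
             pident = rep_len(50, n), length = rep_len(100, n),
             mismatch = rep_len(5, n), gapopen = rep_len(1, n),
             qstart = rep_len(1, n), qend = rep_len(100, n),
             sstart = rep_len(1, n), send = rep_len(100, n),
             evalue = evalue, bitscore = rep_len(bitscore, n),
             db_label = db_label, stringsAsFactors = FALSE)
}

test_that("aggregation counts distinct subjects below a strict E-value cutoff", {
  hits <- rbind(
    mk_hits(rep("g1", 3), rep("b_s1", 3), 1e-10, "bacteria"), # 3 HSPs, 1 subject
    mk_hits("g2", "b_s2", 1e-5, "bacteria"),                  # exactly at cutoff
    mk_hits(rep("g3", 4), c("b_s1", "b_s2", "f_s1", "m_s1"), 1e-12,
            c("bacteria", "bacteria", "fungi", "metazoa")))
  agg <- aggregate_hits(hits)
  expect_equal(agg$donor_total[agg$gene_id == "g1"], 1L)
  expect_equal(agg$donor_total[agg$gene_id == "g2"], 0L)
  expect_equal(agg$donor_total[agg$gene_id == "g3"], 4L)
  expect_equal(agg$donor_bacteria[agg$gene_id == "g3"], 2L)
  expect_equal(agg$recipient_total, c(0L, 0L, 0L))
  expect_error(aggregate_hits(mk_hits("g", "s", 1e-9, "viruses")), "db_label")
})

test_that("candidacy needs 1-4 donor subjects and zero recipient hits", {
  agg <- data.frame(gene_id = paste0("g", 1:5),
                    donor_total = c(3L, 5L, 2L, 0L, 4L),
                    recipient_total = c(0L, 0L, 1L, 0L, 0L))
  out <- call_hgt_candidates(agg)
  expect_equal(out$verdict,
               c("candidate", "rejected_hits", "rejected_hits",
                 "rejected_hits", "candidate"))
})

test_that("aggregation is invariant to row permutation and HSP duplication", {
  hits <- sim_default$hits
  agg <- aggregate_hits(hits)
  set.seed(3)
  perm <- hits[sample(nrow(hits)), , drop = FALSE]
  dup <- rbind(perm, perm[sample(nrow(perm), 50), , drop = FALSE])
  agg2 <- aggregate_hits(dup)
  expect_equal(agg, agg2, ignore_attr = TRUE)
})

test_that("flank validation classifies every neighborhood shape", {
  ids <- paste0("g", 1:7)
  scaffolds <- scaffold_records(c(s1 = 30000, s2 = 30000, s3 = 30000))
  genes <- gene_models(ids,
                       c("s1", "s1", "s1", "s2", "s2", "s2", "s3"),
                       c(100, 1100, 2100, 100, 1100, 2100, 100),
                       c(900, 1900, 2900, 900, 1900, 2900, 900))
  calls <- assign_scope(ids, similarity = c("plant", NA, "plant",
                                            "bacteria", NA, "plant",
                                            NA))
  # g2: plant - candidate - plant
  expect_equal(validate_flanks("g2", genes, calls), "all_plant")
  # g5: bacterial upstream flank
  expect_equal(validate_flanks("g5", genes, calls), "has_nonplant")
  # g4: first on scaffold, downstream flank unannotated -> non-plant
  expect_equal(validate_flanks("g4", genes, calls), "has_nonplant")
  # g1: first on scaffold, single downstream flank unannotated
  calls2 <- calls; calls2$scope[calls2$feature_id == "g2"] <- "plant"
  expect_equal(validate_flanks("g1", genes, calls2), "terminal_partial")
  # g7: alone on its scaffold
  expect_equal(validate_flanks("g7", genes, calls), "isolated")
  expect_error(validate_flanks("missing", genes, calls), "not found")
})

test_that("finalize retains plant-flanked candidates and condemns scaffolds", {
  sim <- sim_preset
  out <- screen_hgt(sim$genes, sim$hits, sim$calls)
  truth <- sim$truth
  planted_true <- truth$genes$gene_id[truth$genes$label == "true_hgt"]
  decoy_scafs <- truth$scaffolds$scaffold_id[truth$scaffolds$label == "hgt_decoy"]
  n_cand <- sum(out$candidates$verdict %in% c("retained", "removed_flank"))
  expect_equal(n_cand, 31)
  expect_equal(length(out$scaffolds_to_remove), 10)
  expect_equal(nrow(out$retained), 2)
  expect_setequal(out$retained$gene_id, planted_true)
  expect_setequal(out$scaffolds_to_remove, decoy_scafs)
  # conservation: verdicts partition candidate genes
  expect_equal(sum(out$candidates$verdict == "retained") +
                 sum(out$candidates$verdict == "removed_flank") +
                 sum(out$candidates$verdict == "rejected_hits"),
               nrow(out$candidates))
})

test_that("no candidates and all-plant-flank cases degrade cleanly", {
  ids <- c("p1", "c1", "p2")
  scaffolds <- scaffold_records(c(s = 20000))
  genes <- gene_models(ids, "s", c(100, 1100, 2100), c(900, 1900, 2900))
  calls <- assign_scope(ids, similarity = c("plant", NA, "plant"))
  # no hits at all -> no candidates, nothing condemned
  empty <- mk_hits(character(0), character(0), numeric(0), character(0))
  out <- screen_hgt(genes, empty, calls)
  expect_equal(nrow(out$retained), 0)
  expect_equal(length(out$scaffolds_to_remove), 0)
  # single valid candidate with plant flanks -> retained, nothing condemned
  hits <- mk_hits("c1", "b_s1", 1e-20, "bacteria")
  out <- screen_hgt(genes, hits, calls)
  expect_equal(out$retained$gene_id, "c1")
  expect_equal(length(out$scaffolds_to_remove), 0)
})

test_that("tightening donor_hits_max never grows the candidate set", {
  agg <- aggregate_hits(sim_default$hits)
  prev <- NULL
  for (mx in 6:1) {
    cand <- call_hgt_candidates(agg, filter_config(donor_hits_max = mx))
    ids <- cand$gene_id[cand$verdict == "candidate"]
    if (!is.null(prev)) expect_true(all(ids %in% prev))
    prev <- ids
  }
})

test_that("planted true transfers are recovered exactly across seeds", {
  for (seed in c(2, 13)) {
    sim <- generate_hit_tables(generate_assembly(generator_params(seed = seed)))
    out <- screen_hgt(sim$genes, sim$hits, sim$calls)
    planted <- sim$truth$genes$gene_id[sim$truth$genes$label == "true_hgt"]
    expect_setequal(out$retained$gene_id, planted) # precision = recall = 1
  }
})

test_that("hit tables round-trip through the 13-column TSV reader", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(sim_default$hits, f, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  back <- read_hit_table(f)
  expect_equal(back$qseqid, sim_default$hits$qseqid)
  expect_equal(back$evalue, sim_default$hits$evalue, tolerance = 1e-10)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("a\tb\tc", bad)
  expect_error(read_hit_table(bad), "13 columns")
})
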