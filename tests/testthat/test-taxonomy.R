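# Taxonomy-scope assignment and transcript/gene-level filters.

test_that("scope assignment prefers similarity, falls back to orthology", {
  out <- assign_scope(c("a", "b", "c", "d"),
                      similarity = c("fungi", NA, NA, "plant"),
                      orthology = c("plant", "bacteria", NA, NA))
  expect_equal(out$scope, c("fungi", "bacteria", "unannotated", "plant"))
  expect_equal(out$source, c("similarity", "orthology", "none", "similarity"))
  expect_error(assign_scope("a", similarity = "viridiplantae"), "allowed")
  expect_error(assign_scope(c("a", "a")), "duplicate")
})

test_that("internal ORFs are removed, partial and complete retained", {
  orfs <- data.frame(orf_id = paste0("o", 1:4),
                     completeness = c("complete", "internal",
                                      "five_prime_partial", "three_prime_partial"))
  out <- filter_internal_orfs(orfs)
  expect_equal(out$retained$orf_id, c("o1", "o3", "o4"))
  expect_equal(out$removed$orf_id, "o2")
  all_int <- data.frame(orf_id = "x", completeness = "internal")
  expect_equal(nrow(filter_internal_orfs(all_int)$retained), 0)
  expect_error(filter_internal_orfs(data.frame(orf_id = "x", completeness = "odd")),
               "completeness")
})

test_that("expression filter is strictly greater-than the floor", {
  expr <- data.frame(transcript_id = c("t1", "t2", "t3"),
                     fpkm = c(0.5, 0.51, 0))
  out <- filter_by_expression(expr, 0.5)
  expect_equal(out$retained$transcript_id, "t2")
  expect_equal(sort(out$removed$transcript_id), c("t1", "t3"))
  expect_error(filter_by_expression(data.frame(transcript_id = "t", fpkm = -1)),
               ">= 0")
})

test_that("contaminant transcript removal reports per-scope percentages", {
  calls <- assign_scope(paste0("t", 1:10),
                        similarity = c(rep("plant", 5), "fungi", "fungi",
                                       "bacteria", "insecta", NA))
  out <- filter_contaminant_transcripts(calls)
  expect_equal(nrow(out$removed), 4)
  expect_equal(out$summary$pct[out$summary$scope == "fungi"], 20)
  expect_equal(out$summary$n[out$summary$scope == "total"], 4)
  # no contaminant scopes present
  clean <- assign_scope(c("a", "b"), similarity = c("plant", NA))
  expect_equal(nrow(filter_contaminant_transcripts(clean)$removed), 0)
})

test_that("domain filter keeps only genes with a complete domain", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3"))
  dom <- data.frame(gene_id = c("g1", "g1"), domain = c("PF1", "PF2"))
  out <- filter_genes_by_domain(genes, dom)
  expect_equal(out$retained$gene_id, "g1")
  expect_equal(sort(out$removed$gene_id), c("g2", "g3"))
  expect_warning(filter_genes_by_domain(genes,
                                        data.frame(gene_id = "gX", domain = "PF9")),
                 "not in the gene set")
})

test_that("every filter conserves rows, is idempotent, and ignores row order", {
  tx <- generate_transcript_tables(generator_params(seed = 9))
  filters <- list(
    function(x) filter_internal_orfs(x), list(tx$orfs),
    function(x) filter_by_expression(x), list(tx$expression),
    function(x) filter_contaminant_transcripts(x), list(tx$calls))
  for (i in seq(1, length(filters), by = 2)) {
    f <- filters[[i]]
    input <- filters[[i + 1]][[1]]
    out <- f(input)
    expect_equal(nrow(out$retained) + nrow(out$removed), nrow(input))
    again <- f(out$retained)
    expect_equal(again$retained, out$retained, ignore_attr = TRUE)
    expect_equal(nrow(again$removed), 0)
    set.seed(1)
    perm <- input[sample(nrow(input)), , drop = FALSE]
    out_p <- f(perm)
    expect_setequal(out_p$retained[[1]], out$retained[[1]])
  }
})

test_that("planted transcript mixtures are recovered by the filters", {
  p <- generator_params(seed = 21)
  tx <- generate_transcript_tables(p)
  orf_out <- filter_internal_orfs(tx$orfs)
  expect_equal(nrow(orf_out$removed), tx$truth$n_internal)
  expr_out <- filter_by_expression(tx$expression, 0.5)
  expect_equal(nrow(expr_out$removed), tx$truth$n_low_fpkm)
  contam_out <- filter_contaminant_transcripts(tx$calls)
  counts <- tx$truth$contaminant_counts
  for (sc in names(counts)) {
    expect_equal(contam_out$summary$n[contam_out$summary$scope == sc],
                 unname(counts[sc]))
  }
})

test_that("taxonomy-call tables round-trip through the TSV interface", {
  calls <- sim_default$calls
  f <- withr::local_tempfile(fileext = ".tsv")
  write_taxonomy_calls(calls, f)
  back <- read_taxonomy_calls(f)
  expect_equal(back$feature_id, calls$feature_id)
  expect_equal(back$scope, calls$scope)
})
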