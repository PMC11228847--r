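# Core data model, GFF3 round trip, and assembly metrics.

test_that("N50 matches the definition on worked examples", {
  expect_equal(compute_n50(7), 7)
  expect_equal(compute_n50(c(2, 3, 4, 5, 6)), 5)
  expect_equal(compute_n50(c(1, 1, 1, 1)), 1)
  expect_error(compute_n50(numeric(0)), "empty")
  expect_error(compute_n50(c(5, 0)), "positive")
})

test_that("N50 agrees with a brute-force oracle on random length sets", {
  set.seed(11)
  for (i in 1:1000) {
    lens <- sample(1:5000, sample(1:60, 1), replace = TRUE)
    expect_identical(compute_n50(lens), oracle_n50(lens))
  }
})

test_that("mono:multi ratio handles the published counts and degenerate sets", {
  expect_equal(mono_multi_ratio(c(rep(1L, 1708), rep(4L, 21853))), 0.08)
  expect_equal(mono_multi_ratio(c(2, 3, 5)), 0)
  expect_equal(mono_multi_ratio(c(1, 1, 1, 1, 1, 2, 2, 3, 4, 5)), 1)
  expect_warning(r <- mono_multi_ratio(c(1, 1)), "infinite")
  expect_identical(r, Inf)
  expect_error(mono_multi_ratio(integer(0)), "empty")
})

test_that("percent_in_top_k is monotone in k and hits 100 at k = n", {
  set.seed(12)
  lens <- sample(1e3:1e6, 40)
  pcts <- vapply(seq_along(lens), function(k) percent_in_top_k(lens, k, digits = 6),
                 numeric(1))
  expect_true(all(diff(pcts) >= 0))
  expect_equal(pcts[length(lens)], 100)
  expect_equal(percent_in_top_k(c(10, 10), 1), 50)
  expect_error(percent_in_top_k(lens, length(lens) + 1), "k must be")
})

test_that("coverage bins are left-open/right-closed at 0, 7, 65", {
  bins <- coverage_bin(c(0, 0.1, 7, 7.1, 65, 65.1, 200))
  expect_equal(as.character(bins),
               c("junk", "suspect_low", "suspect_low", "normal", "normal",
                 "suspect_high", "suspect_high"))
  expect_error(coverage_bin(10, cutoffs = c(5, 5, 65)), "increasing")
  expect_error(coverage_bin(-1), ">= 0")
})

test_that("GFF3 read applies the coordinate convention and deterministic order", {
  gff <- c("##gff-version 3",
           "s2\tx\tgene\t101\t200\t.\t+\t.\tID=g2",
           "s2\tx\texon\t101\t200\t.\t+\t.\tParent=g2",
           "s1\tx\tgene\t501\t900\t.\t-\t.\tID=g3",
           "s1\tx\tmRNA\t501\t900\t.\t-\t.\tID=g3.m;Parent=g3",
           "s1\tx\texon\t501\t600\t.\t-\t.\tParent=g3.m",
           "s1\tx\texon\t701\t900\t.\t-\t.\tParent=g3.m",
           "s1\tx\tgene\t1\t100\t.\t+\t.\tID=g1",
           "s1\tx\texon\t1\t100\t.\t+\t.\tParent=g1")
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(gff, f)
  g <- read_annotation(f)
  # 1-based inclusive (101, 200) becomes 0-based half-open (100, 200)
  expect_equal(g$start[g$gene_id == "g2"], 100)
  expect_equal(g$end[g$gene_id == "g2"], 200)
  expect_equal(g$gene_id, c("g1", "g3", "g2")) # (scaffold, start, id) order
  expect_equal(g$exon_count[g$gene_id == "g3"], 2L)
  expect_equal(g$exon_count[g$gene_id == "g1"], 1L)
  expect_equal(g$cds_length[g$gene_id == "g3"], 300)
})

test_that("shuffled GFF3 input yields identical output across reads", {
  sim <- generate_assembly(generator_params(seed = 5, n_scaffolds = 15,
                                            n_true_hgt = 1, n_decoy_flank = 2,
                                            n_decoy_donor_excess = 1,
                                            n_decoy_recipient = 1))
  f <- withr::local_tempfile(fileext = ".gff3")
  write_annotation(sim$genes, f)
  lines <- readLines(f)
  body <- lines[-1]
  f2 <- withr::local_tempfile(fileext = ".gff3")
  set.seed(1)
  # permuting gene blocks must not change the parsed result
  writeLines(c(lines[1], rev(body)), f2)
  g1 <- read_annotation(f)
  g2 <- read_annotation(f2)
  expect_identical(g1$gene_id, g2$gene_id)
  expect_identical(g1$start, g2$start)
})

test_that("GFF3 parse and validation errors are specific", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", "s1\tx\tgene\t1\t100"), f)
  expect_error(read_annotation(f), "line 2")
  writeLines(c("##gff-version 3",
               "s1\tx\tgene\t101\t200\t.\t+\t.\tID=g1",
               "s1\tx\texon\t50\t250\t.\t+\t.\tParent=g1"), f)
  expect_error(read_annotation(f), "exon outside gene span")
})

test_that("annotation write/read is a fixed point on the data model", {
  sim <- sim_default
  f <- withr::local_tempfile(fileext = ".gff3")
  write_annotation(sim$genes, f)
  g1 <- read_annotation(f)
  f2 <- withr::local_tempfile(fileext = ".gff3")
  write_annotation(g1, f2)
  g2 <- read_annotation(f2)
  expect_identical(g1[setdiff(names(g1), c("exons", "cds"))],
                   g2[setdiff(names(g2), c("exons", "cds"))])
  expect_equal(g1$exons, g2$exons, ignore_attr = TRUE)
})

test_that("gene model invariants are enforced", {
  expect_error(gene_models("g1", "s1", 10, 10), "start < end")
  expect_error(gene_models(c("g1", "g1"), "s1", c(0, 10), c(5, 20)), "duplicate")
  sc <- scaffold_records(c(s1 = 100))
  expect_error(gene_models("g1", "s1", 0, 200, scaffolds = sc), "beyond scaffold")
  expect_error(gene_models("g1", "sX", 0, 50, scaffolds = sc), "unknown scaffold")
})

test_that("scaffold records validate ids, lengths and coverage", {
  expect_error(scaffold_records(c(10, 20)), "named")
  expect_error(scaffold_records(c(a = 10, a = 20)), "duplicate")
  expect_error(scaffold_records(c(a = 0)), ">= 1")
  expect_error(scaffold_records(c(a = 10), mean_coverage = -1), ">= 0")
})
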