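# Quartile-based gene-family dynamics and annotation transfer.

test_that("quartile categorization matches hand-computed examples", {
  expect_equal(quartile_categorize(c(A = 1, B = 4, C = 10)),
               c(A = "contracted", B = "neutral", C = "expanded"))
  expect_equal(quartile_categorize(c(A = 3, B = 3, C = 3)),
               c(A = "neutral", B = "neutral", C = "neutral"))
  expect_equal(quartile_categorize(c(A = 0, B = 5)),
               c(A = "contracted", B = "expanded"))
  expect_error(quartile_categorize(c(A = -1, B = 2)), ">= 0")
})

test_that("values equal to a quartile are neutral (strict inequalities)", {
  # distinct counts 2, 4, 6, 8: Q1 = 3.5, Q3 = 6.5; a species at 4 or 6
  # sits inside the quartiles
  out <- quartile_categorize(c(A = 2, B = 4, C = 6, D = 8))
  expect_equal(unname(out), c("contracted", "neutral", "neutral", "expanded"))
})

test_that("categorization agrees with an independent quantile oracle", {
  set.seed(17)
  for (i in 1:1000) {
    counts <- sample(0:20, sample(2:8, 1), replace = TRUE)
    names(counts) <- paste0("s", seq_along(counts))
    expect_identical(quartile_categorize(counts), oracle_categorize(counts))
  }
})

test_that("categories are invariant under positive scaling of counts", {
  set.seed(18)
  for (i in 1:50) {
    counts <- sample(0:30, 4, replace = TRUE)
    names(counts) <- paste0("s", 1:4)
    for (k in c(2, 5, 10))
      expect_identical(unname(quartile_categorize(counts * k)),
                       unname(quartile_categorize(counts)))
  }
})

test_that("annotation transfers from the longest member with deterministic ties", {
  members <- data.frame(gene_id = c("x1", "y2", "z3"),
                        species = c("sA", "sB", "sC"),
                        length = c(900, 1200, 700),
                        annotation = c("k1", "k2", "k3"))
  out <- transfer_annotation(members)
  expect_equal(out$representative_gene, "y2")
  expect_equal(out$annotation, "k2")
  tie <- data.frame(gene_id = c("b", "a"), species = c("sA", "sB"),
                    length = c(1000, 1000), annotation = c("kb", "ka"))
  expect_equal(transfer_annotation(tie)$representative_gene, "a")
  noann <- data.frame(gene_id = c("long", "short"), species = c("sA", "sB"),
                      length = c(500, 100), annotation = c(NA, "ks"))
  expect_warning(out <- transfer_annotation(noann), "unannotated")
  expect_equal(out$representative_gene, "long")
  expect_true(is.na(out$annotation))
  expect_error(transfer_annotation(members[0, ]), "empty")
})

test_that("family member counting is by distinct subject under the cutoff", {
  hits <- data.frame(qseqid = c("q1", "q2", "q3", "q1"),
                     sseqid = c("s1", "s1", "s2", "s9"),
                     evalue = c(1e-9, 1e-12, 1e-20, 1e-4))
  expect_equal(count_family_members(c("q1", "q2", "q3"), hits), 2L)
  expect_equal(count_family_members("q9", hits), 0L)
})

test_that("orthogroup set summary partitions the universe", {
  m <- matrix(c(TRUE, TRUE, FALSE, FALSE,
                TRUE, FALSE, TRUE, FALSE,
                TRUE, FALSE, FALSE, FALSE), 4, 3,
              dimnames = list(paste0("og", 1:4), c("A", "B", "C")))
  s <- orthogroup_set_summary(m)
  expect_equal(sum(s$n), 4)
  expect_equal(s$n[s$species_set == "A+B+C"], 1)
  expect_equal(s$n[s$species_set == "(none)"], 1)
  # single species: unique = total
  one <- matrix(TRUE, 5, 1, dimnames = list(paste0("og", 1:5), "A"))
  s1 <- orthogroup_set_summary(one)
  expect_equal(s1$n[s1$species_set == "A"], 5)
})

test_that("planted expansion/contraction is recovered exactly from the table", {
  p <- generator_params(seed = 31, og_n_groups = 500L,
                        og_planted_expanded = 50L, og_planted_contracted = 100L)
  og <- generate_orthogroup_table(p)
  cats <- categorize_orthogroups(og$counts)
  sp1 <- p$og_species[1]
  expect_equal(sum(cats[[sp1]] == "expanded"), 50L)
  expect_equal(sum(cats[[sp1]] == "contracted"), 100L)
  # full per-species agreement with the planted truth
  for (sp in p$og_species)
    expect_equal(cats[[sp]], og$truth[[sp]])
})

test_that("orthogroup count tables round-trip and reject bad columns", {
  og <- generate_orthogroup_table(generator_params(seed = 2))$counts
  f <- withr::local_tempfile(fileext = ".tsv")
  write_orthogroup_counts(og, f)
  back <- read_orthogroup_counts(f)
  expect_equal(back, og, ignore_attr = TRUE)
  og_bad <- og
  og_bad$spA[1] <- -2
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_orthogroup_counts(og_bad, f2)
  expect_error(read_orthogroup_counts(f2), "negative")
})
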