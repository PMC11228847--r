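# Shared fixtures, built once per test run.

# a mid-sized simulation with every planted class
sim_default <- simulate_screen_data(generator_params(seed = 42L))

# the preset replaying the published decision structure
sim_preset <- simulate_screen_data(published_preset_params(seed = 42L))

# independent N50 oracle: largest L present in the set such that
# scaffolds of length >= L hold at least half the assembly
oracle_n50 <- function(lengths) {
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (L in cand) if (sum(lengths[lengths >= L]) >= sum(lengths) / 2) return(L)
}

# independent linear-interpolation quantile oracle (no stats::quantile)
oracle_quantile <- function(v, p) {
  v <- sort(v)
  n <- length(v)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(v[n])
  v[lo] + (h - lo) * (v[lo + 1] - v[lo])
}

oracle_categorize <- function(counts) {
  vals <- unique(as.numeric(counts))
  if (length(vals) < 2) return(setNames(rep("neutral", length(counts)), names(counts)))
  q1 <- oracle_quantile(vals, 0.25)
  q3 <- oracle_quantile(vals, 0.75)
  setNames(ifelse(counts < q1, "contracted",
                  ifelse(counts > q3, "expanded", "neutral")), names(counts))
}

# tiny hand-built assembly used by unit tests
tiny_assembly <- function() {
  scaffolds <- scaffold_records(c(s1 = 9000, s2 = 15000, s3 = 5000))
  genes <- gene_models(gene_id = c("gA", "gB", "gC", "gD", "gE", "gF"),
                       scaffold_id = c("s1", "s1", "s1", "s2", "s2", "s3"),
                       start = c(100, 1100, 2100, 100, 1100, 100),
                       end = c(900, 1900, 2900, 900, 1900, 900))
  calls <- assign_scope(genes$gene_id,
                        similarity = c("plant", NA, "bacteria",
                                       "plant", "fungi", "bacteria"))
  list(scaffolds = scaffolds, genes = genes, calls = calls)
}
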