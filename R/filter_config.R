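#' Thresholds governing every filtering stage
#'
#' Collects the screening thresholds used across the pipeline: alignment
#' significance, the donor-hit window for HGT candidacy, scaffold-composition
#' contamination rules, the transcript expression floor, read-coverage
#' cutoffs, and the taxonomy scopes treated as contaminant at scaffold and
#' transcript level.
#'
#' Defaults reproduce the published screen: alignments are significant below
#' an E-value of 1e-5; an HGT candidate needs between one and four distinct
#' donor-database subjects and none in the recipient (plant) databases;
#' scaffolds of at most 10 kb are removed when 40% or more of their genes are
#' archaeal/bacterial/fungal, scaffolds of at least 10 kb when 55% or more
#' are; transcripts are retained only above 0.5 FPKM; coverage bins split at
#' depths 0, 7 and 65.
#'
#' @param evalue_max significance threshold; hits count only when
#'   `evalue < evalue_max` (strict).
#' @param donor_hits_min,donor_hits_max inclusive window of distinct donor
#'   subjects (pooled across donor databases) for HGT candidacy.
#' @param short_scaffold_len length (bp) separating the short- and
#'   long-scaffold contamination rules.
#' @param short_contam_frac,long_contam_frac contaminant-gene fractions at or
#'   above which a short (resp. long) scaffold is removed.
#' @param fpkm_min expression floor; transcripts are retained when strictly
#'   above it.
#' @param coverage_cutoffs strictly increasing depth cutoffs (low, mid, high)
#'   for [coverage_bin()].
#' @param contaminant_scopes_scaffold scopes counting as contaminant in the
#'   scaffold-composition rules.
#' @param contaminant_scopes_transcript scopes removed at transcript level.
#' @return An object of class `"filter_config"` (a validated named list).
#' @examples
#' cfg <- filter_config()
#' cfg$evalue_max
#' @export
filter_config <- function(evalue_max = 1e-5,
                          donor_hits_min = 1L,
                          donor_hits_max = 4L,
                          short_scaffold_len = 10000L,
                          short_contam_frac = 0.40,
                          long_contam_frac = 0.55,
                          fpkm_min = 0.5,
                          coverage_cutoffs = c(low = 0, mid = 7, high = 65),
                          contaminant_scopes_scaffold = c("archaea", "bacteria", "fungi"),
                          contaminant_scopes_transcript = c("archaea", "bacteria",
                                                            "fungi", "insecta", "amoeba")) {
  cfg <- list(evalue_max = as.numeric(evalue_max),
              donor_hits_min = as.integer(donor_hits_min),
              donor_hits_max = as.integer(donor_hits_max),
              short_scaffold_len = as.numeric(short_scaffold_len),
              short_contam_frac = as.numeric(short_contam_frac),
              long_contam_frac = as.numeric(long_contam_frac),
              fpkm_min = as.numeric(fpkm_min),
              coverage_cutoffs = as.numeric(coverage_cutoffs),
              contaminant_scopes_scaffold = as.character(contaminant_scopes_scaffold),
              contaminant_scopes_transcript = as.character(contaminant_scopes_transcript))
  validate_filter_config(cfg)
  class(cfg) <- "filter_config"
  cfg
}

#' @noRd
validate_filter_config <- function(cfg) {
  if (!is.finite(cfg$evalue_max) || cfg$evalue_max <= 0)
    stop_config("evalue_max must be > 0 (got ", cfg$evalue_max, ")")
  if (cfg$donor_hits_min < 0 || cfg$donor_hits_min > cfg$donor_hits_max)
    stop_config("donor hit window invalid: donor_hits_min (", cfg$donor_hits_min,
                ") must be >= 0 and <= donor_hits_max (", cfg$donor_hits_max, ")")
  if (cfg$short_scaffold_len <= 0)
    stop_config("short_scaffold_len must be positive")
  fr <- c(cfg$short_contam_frac, cfg$long_contam_frac)
  if (any(!is.finite(fr)) || cfg$short_contam_frac <= 0 ||
      cfg$short_contam_frac > cfg$long_contam_frac || cfg$long_contam_frac > 1)
    stop_config("contaminant fractions must satisfy 0 < short_contam_frac <= ",
                "long_contam_frac <= 1 (got ", cfg$short_contam_frac, ", ",
                cfg$long_contam_frac, ")")
  if (cfg$fpkm_min < 0) stop_config("fpkm_min must be >= 0")
  if (length(cfg$coverage_cutoffs) != 3 || any(diff(cfg$coverage_cutoffs) <= 0))
    stop_config("coverage_cutoffs must be three strictly increasing values")
  bad <- setdiff(cfg$contaminant_scopes_scaffold, SCOPE_LEVELS)
  bad <- c(bad, setdiff(cfg$contaminant_scopes_transcript, SCOPE_LEVELS))
  if (length(bad))
    stop_config("unknown taxonomy scope(s): ", paste(unique(bad), collapse = ", "),
                "; allowed: ", paste(SCOPE_LEVELS, collapse = ", "))
  invisible(cfg)
}

#' @export
print.filter_config <- function(x, ...) {
  cat("Screening thresholds (filter_config)\n")
  cat(sprintf("  E-value max (strict):        %g\n", x$evalue_max))
  cat(sprintf("  donor subject window:        [%d, %d]\n",
              x$donor_hits_min, x$donor_hits_max))
  cat(sprintf("  scaffold rules:              <=%g bp & frac >= %.2f | >=%g bp & frac >= %.2f\n",
              x$short_scaffold_len, x$short_contam_frac,
              x$short_scaffold_len, x$long_contam_frac))
  cat(sprintf("  FPKM floor (strict >):       %.2f\n", x$fpkm_min))
  cat(sprintf("  coverage cutoffs:            %s\n",
              paste(x$coverage_cutoffs, collapse = ", ")))
  cat(sprintf("  contaminant scopes (scaff):  %s\n",
              paste(x$contaminant_scopes_scaffold, collapse = ", ")))
  cat(sprintf("  contaminant scopes (tx):     %s\n",
              paste(x$contaminant_scopes_transcript, collapse = ", ")))
  invisible(x)
}
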