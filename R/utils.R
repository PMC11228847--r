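# Internal helpers shared across modules.

#' @noRd
round_half_up <- function(x, digits = 0) {
  # base round() is round-half-to-even; percentages in reports follow the
  # conventional half-away-from-zero rule (e.g. 7/273 -> 3%).
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @noRd
stop_domain <- function(...) {
  stop(structure(class = c("hgtscreen_domain_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' @noRd
stop_validation <- function(...) {
  stop(structure(class = c("hgtscreen_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' @noRd
stop_config <- function(...) {
  stop(structure(class = c("hgtscreen_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
assert_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop_validation(what, " is missing column(s): ", paste(miss, collapse = ", "))
  invisible(df)
}

# Closed taxonomy-scope vocabulary used for gene/transcript calls.
SCOPE_LEVELS <- c("plant", "bacteria", "fungi", "archaea", "metazoa",
                  "insecta", "amoeba", "unannotated")

# Alignment database labels.
DONOR_LABELS <- c("bacteria", "fungi", "archaea", "metazoa")
RECIPIENT_LABELS <- c("streptophyta", "tracheophyta", "embryophyta",
                      "viridiplantae", "spermatophyta")
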