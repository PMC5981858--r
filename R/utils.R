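# Internal helpers shared across modules.

#' Names of the twelve tidal-breathing features, in canonical order
#'
#' The fixed column order is part of the feature-table format contract:
#' inspiratory/expiratory time (s), breathing rate (breaths/min), duty cycle,
#' peak inspiratory/expiratory flow (L/s), time to peak flow (s),
#' inspiratory/expiratory tidal volume (L), and inspiratory/expiratory
#' velocity (L/s^2).
#'
#' @return Character vector of length 12.
#' @export
feature_names <- function() {
  c("ti_s", "te_s", "br_bpm", "dcy", "pif_lps", "pef_lps",
    "tpif_s", "tpef_s", "tv_ins_L", "tv_exp_L", "vel_ins", "vel_exp")
}

# Extract the 12-feature matrix (fixed column order) from a feature table.
feature_matrix <- function(table) {
  missing <- setdiff(feature_names(), names(table))
  if (length(missing) > 0) {
    abort(paste0("feature table is missing columns: ",
                 paste(missing, collapse = ", ")),
          class = "tidybreathe_bad_table")
  }
  m <- as.matrix(table[, feature_names()])
  storage.mode(m) <- "double"
  if (anyNA(m) || any(!is.finite(m))) {
    abort("feature table contains missing or non-finite values",
          class = "tidybreathe_bad_table")
  }
  m
}

check_labels <- function(label, both_classes = TRUE) {
  if (anyNA(label) || !all(label %in% c(0, 1))) {
    abort("labels must be 0 (non-smoker) or 1 (smoker)",
          class = "tidybreathe_bad_table")
  }
  if (both_classes && length(unique(label)) < 2) {
    abort("both classes must be present", class = "tidybreathe_domain")
  }
  invisible(as.integer(label))
}

# Deterministic child seed, kept well below .Machine$integer.max.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1009L) * 104729L %% 1999999L + as.integer(offset) * 7919L %% 99991L
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
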