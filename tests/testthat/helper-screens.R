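# Shared fixture builders (everything generated in code).

tiny_design <- function(n_targets = 8, n_queries = 4, overlap = TRUE) {
  targets <- paste0("T", seq_len(n_targets))
  queries <- if (overlap) targets[seq_len(n_queries)] else
    paste0("Q", seq_len(n_queries))
  screen_design(gene_set(targets, queries))
}

# screen with one pair per archetype class I-VI plus null background
archetype_interactions <- function(magnitude = 1, direction = "positive") {
  data.frame(target = paste0("T", 1:6), query = paste0("Q", 1:6),
             class = c("I", "II", "III", "IV", "V", "VI"),
             magnitude = magnitude, direction = direction)
}

archetype_design <- function(n_targets = 12, n_queries = 6) {
  screen_design(gene_set(paste0("T", seq_len(n_targets)),
                         paste0("Q", seq_len(n_queries)), ))
}

# map a (class label, time flag) back onto the I-VI taxonomy
archetype_of <- function(class, time_dependent) {
  cls <- as.character(class)
  out <- rep(NA_character_, length(cls))
  out[cls == "aggravating_insensitive" & !time_dependent] <- "I"
  out[cls == "alleviating_insensitive" & !time_dependent] <- "II"
  out[cls == "positive_sensitive" & !time_dependent] <- "III"
  out[cls == "negative_sensitive" & !time_dependent] <- "III"
  out[cls == "aggravating_insensitive" & time_dependent] <- "IV"
  out[cls == "alleviating_insensitive" & time_dependent] <- "V"
  out[cls == "positive_sensitive" & time_dependent] <- "VI"
  out[cls == "negative_sensitive" & time_dependent] <- "VI"
  out[cls == "not_significant"] <- "null"
  out
}

# independent sweep-by-sweep median polish reference (kept deliberately
# naive; used as the oracle for the packaged implementation)
reference_median_polish <- function(M, n_sweeps = 200) {
  r <- rep(0, nrow(M)); cl <- rep(0, ncol(M)); overall <- 0
  R <- M
  for (s in seq_len(n_sweeps)) {
    for (i in seq_len(nrow(R))) {
      d <- stats::median(R[i, ], na.rm = TRUE); if (is.na(d)) d <- 0
      R[i, ] <- R[i, ] - d; r[i] <- r[i] + d
    }
    d <- stats::median(cl); cl <- cl - d; overall <- overall + d
    for (j in seq_len(ncol(R))) {
      d <- stats::median(R[, j], na.rm = TRUE); if (is.na(d)) d <- 0
      R[, j] <- R[, j] - d; cl[j] <- cl[j] + d
    }
    d <- stats::median(r); r <- r - d; overall <- overall + d
  }
  list(overall = overall, row_effects = r, col_effects = cl, residuals = R)
}

# null pi cube: every pair's true trajectory is flat zero
null_interactions <- function(n_pairs, feature = "cell_number") {
  data.frame(target = paste0("T", seq_len(n_pairs)), query = "Q1",
             feature = feature, c_true = 0, sigma_true = 0, delta_true = 0)
}
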