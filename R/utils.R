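# Internal helpers shared across modules.

# Unordered-pair key; \x1f never occurs in protein identifiers.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\x1f")
}

# Put every pair into canonical (protein_a <= protein_b) order.
canonicalize_pairs <- function(df) {
  a <- pmin(df$protein_a, df$protein_b)
  b <- pmax(df$protein_a, df$protein_b)
  df$protein_a <- a
  df$protein_b <- b
  df
}

# Validate and canonicalize a two-column pair table (a ReferenceSet).
as_pair_tbl <- function(pairs, arg = "pairs") {
  if (!is.data.frame(pairs) || ncol(pairs) < 2) {
    abort(sprintf("`%s` must be a data frame with at least two columns", arg),
          class = "binm_validation_error")
  }
  df <- as_tibble(pairs)
  if (!all(c("protein_a", "protein_b") %in% names(df))) {
    names(df)[1:2] <- c("protein_a", "protein_b")
  }
  df <- df[, c("protein_a", "protein_b")]
  df$protein_a <- trimws(as.character(df$protein_a))
  df$protein_b <- trimws(as.character(df$protein_b))
  df <- df[df$protein_a != df$protein_b, , drop = FALSE]
  df <- canonicalize_pairs(df)
  dplyr::distinct(dplyr::arrange(df, .data$protein_a, .data$protein_b))
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state;
# with seed = NULL the current stream is used as-is.
with_rng_seed <- function(seed, expr) {
  if (is.null(seed)) {
    expr
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

# Pick the score column a ranking carries: explicit choice wins, otherwise
# the BINM score, otherwise a generic `score`, otherwise the observed score.
ranking_score_col <- function(ranked, score_col = NULL) {
  if (!is.null(score_col)) {
    if (!score_col %in% names(ranked)) {
      abort(sprintf("column `%s` not found in ranking", score_col),
            class = "binm_validation_error")
    }
    return(score_col)
  }
  for (cand in c("binm_score", "score", "obs_score")) {
    if (cand %in% names(ranked)) return(cand)
  }
  abort("ranking carries no score column (expected `binm_score`, `score` or `obs_score`)",
        class = "binm_validation_error")
}

#' @importFrom rlang .data
NULL
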