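# Evaluation battery for re-scored interaction networks: discrimination
# against binary references (AUC/ROC, top-k curves), external per-pair
# scores, complex connectivity, genetic-profile references, F2-optimal
# cutoff selection, Jaccard overlap and bait-prey score comparison.

#' Ranking AUC against a binary reference set
#'
#' The probability that a randomly chosen reference pair (positive) is
#' scored higher than a randomly chosen non-reference observed edge
#' (negative), with ties credited 0.5 — the Mann-Whitney statistic
#' computed from midranks. Only observed edges enter: positives are the
#' ranked edges present in the reference, negatives are all other
#' ranked edges. Pairs absent from the network are never scored and so
#' never counted.
#'
#' @param ranked A ranking (e.g. from [rank_edges()]) carrying a score
#'   column.
#' @param reference A two-column table of unordered reference pairs.
#' @param score_col Which score column to rank by; defaults to
#'   `binm_score` when present, falling back to `score`/`obs_score`
#'   (useful for scoring the raw observed network as a baseline).
#' @return A scalar in `[0, 1]`.
#' @export
edge_auc <- function(ranked, reference, score_col = NULL) {
  col <- ranking_score_col(ranked, score_col)
  ref <- as_pair_tbl(reference, "reference")
  y <- pair_key(ranked$protein_a, ranked$protein_b) %in%
    pair_key(ref$protein_a, ref$protein_b)
  n_pos <- sum(y)
  n_neg <- sum(!y)
  if (n_pos == 0) {
    abort("no positives: no ranked edge belongs to the reference set",
          class = "binm_validation_error")
  }
  if (n_neg == 0) {
    abort("no negatives: every ranked edge belongs to the reference set",
          class = "binm_validation_error")
  }
  r <- rank(ranked[[col]])
  (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve of a ranking against a binary reference set
#'
#' False/true positive rates over all score thresholds, with tied
#' scores collapsed into single threshold steps so the trapezoidal area
#' under the curve equals [edge_auc()] exactly.
#'
#' @inheritParams edge_auc
#' @return A tibble of class `binm_roc` with columns `threshold`,
#'   `fpr`, `tpr`, starting at (0, 0).
#' @export
roc_curve <- function(ranked, reference, score_col = NULL) {
  col <- ranking_score_col(ranked, score_col)
  ref <- as_pair_tbl(reference, "reference")
  y <- pair_key(ranked$protein_a, ranked$protein_b) %in%
    pair_key(ref$protein_a, ref$protein_b)
  n_pos <- sum(y)
  n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0) {
    abort(sprintf("no %s among ranked edges", if (n_pos == 0) "positives" else "negatives"),
          class = "binm_validation_error")
  }
  s <- ranked[[col]]
  ord <- order(-s)
  s <- s[ord]
  y <- y[ord]
  last <- !duplicated(s, fromLast = TRUE)  # final index of each tie block
  tp <- cumsum(y)[last]
  fp <- cumsum(!y)[last]
  out <- tibble(
    threshold = c(Inf, s[last]),
    fpr = c(0, fp / n_neg),
    tpr = c(0, tp / n_pos)
  )
  structure(out, class = c("binm_roc", class(out)))
}

#' Trapezoidal area under a ROC curve
#'
#' @param roc A curve from [roc_curve()].
#' @return A scalar in `[0, 1]`.
#' @export
roc_auc <- function(roc) {
  stopifnot(all(c("fpr", "tpr") %in% names(roc)))
  n <- nrow(roc)
  sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-n]) / 2)
}

#' @method autoplot binm_roc
#' @export
autoplot.binm_roc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC (AUC = %.3f)", roc_auc(object)))
}

#' Reference-validated counts among top-ranked edges
#'
#' For each rank cutoff `k`, the number of top-`k` edges present in the
#' reference set — the standard validation curve for comparing scoring
#' methods at matched prediction sizes.
#'
#' @inheritParams edge_auc
#' @param ks Integer rank cutoffs within `[1, nrow(ranked)]`.
#' @return A tibble of class `binm_report` with columns `k`,
#'   `n_validated`, non-decreasing in `k`.
#' @export
topk_validated <- function(ranked, reference, ks) {
  ks <- check_ks(ks, nrow(ranked))
  ref <- as_pair_tbl(reference, "reference")
  hit <- pair_key(ranked$protein_a, ranked$protein_b) %in%
    pair_key(ref$protein_a, ref$protein_b)
  cum <- cumsum(hit)
  binm_report(tibble(k = ks, n_validated = cum[ks]),
              metric = "reference-validated interactions")
}

#' Mean external score among top-ranked edges
#'
#' For each rank cutoff `k`, the mean of an external per-pair score
#' (e.g. a structure-derived likelihood ratio) over the top-`k` edges
#' that possess one. Unscored edges are excluded from numerator and
#' denominator alike; a cutoff whose top-`k` contains no scored edge
#' yields `NA`.
#'
#' @inheritParams topk_validated
#' @param ext A table of external pair scores: columns `protein_a`,
#'   `protein_b`, `score` with nonnegative scores.
#' @return A tibble of class `binm_report` with columns `k`, `mean_score`.
#' @export
topk_mean_score <- function(ranked, ext, ks) {
  ks <- check_ks(ks, nrow(ranked))
  ext <- validate_pair_scores(ext)
  m <- match(pair_key(ranked$protein_a, ranked$protein_b),
             pair_key(ext$protein_a, ext$protein_b))
  s <- ext$score[m]
  scored <- !is.na(s)
  if (!any(scored[seq_len(max(ks))])) {
    abort("no ranked edge within the requested cutoffs carries an external score",
          class = "binm_validation_error")
  }
  cum_s <- cumsum(ifelse(scored, s, 0))
  cum_n <- cumsum(scored)
  mean_score <- ifelse(cum_n[ks] > 0, cum_s[ks] / cum_n[ks], NA_real_)
  binm_report(tibble(k = ks, mean_score = mean_score),
              metric = "mean external score")
}

validate_pair_scores <- function(ext) {
  if (!is.data.frame(ext) || ncol(ext) < 3) {
    abort("external scores must be a data frame: protein_a, protein_b, score",
          class = "binm_validation_error")
  }
  df <- as_tibble(ext)
  if (!all(c("protein_a", "protein_b", "score") %in% names(df))) {
    names(df)[1:3] <- c("protein_a", "protein_b", "score")
  }
  df$score <- as.double(df$score)
  if (any(df$score < 0, na.rm = TRUE)) {
    abort("external scores must be nonnegative", class = "binm_validation_error")
  }
  df <- df[df$protein_a != df$protein_b, , drop = FALSE]
  df <- canonicalize_pairs(df)
  dplyr::summarise(dplyr::group_by(df, .data$protein_a, .data$protein_b),
                   score = max(.data$score), .groups = "drop")
}

check_ks <- function(ks, n_edges) {
  ks <- sort(unique(as.integer(ks)))
  if (length(ks) == 0 || any(ks < 1) || any(ks > n_edges)) {
    abort(sprintf("rank cutoffs must lie in [1, %d]", n_edges),
          class = "binm_validation_error")
  }
  ks
}

binm_report <- function(df, metric) {
  attr(df, "metric") <- metric
  structure(df, class = c("binm_report", class(df)))
}

#' @method autoplot binm_report
#' @export
autoplot.binm_report <- function(object, ...) {
  xv <- names(object)[1]
  yv <- names(object)[2]
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[xv]], y = .data[[yv]])) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Rank cutoff", y = attr(object, "metric") %||% yv)
}

#' Count complexes sufficiently connected by predicted interactions
#'
#' A curated complex is "sufficiently connected" by a set of predicted
#' direct interactions if those interactions reduce the number of
#' connected components among its members to less than half the member
#' count (the unconnected baseline being one component per member).
#' Counts such complexes of at least `min_size` members.
#'
#' @param predicted A two-column table of predicted pairs (e.g. from
#'   [binary_network()]).
#' @param catalog A long complex catalog (`complex`, `member`), as read
#'   by [read_complexes()].
#' @param min_size Smallest complex size to score (default 3; with two
#'   members the halving criterion can never be met).
#' @return Integer count of sufficiently connected complexes.
#' @export
complex_connectivity <- function(predicted, catalog, min_size = 3) {
  if (!is.numeric(min_size) || min_size < 2) {
    abort("`min_size` must be at least 2", class = "binm_validation_error")
  }
  if (!is.data.frame(catalog) || !all(c("complex", "member") %in% names(catalog)) ||
      nrow(catalog) == 0) {
    abort("`catalog` must be a nonempty data frame with columns complex, member",
          class = "binm_validation_error")
  }
  pred <- as_pair_tbl(predicted, "predicted")
  members_by_cpx <- split(catalog$member, catalog$complex)
  sum(vapply(members_by_cpx, function(members) {
    members <- unique(members)
    size <- length(members)
    if (size < min_size) return(FALSE)
    sub <- pred[pred$protein_a %in% members & pred$protein_b %in% members, ]
    g <- igraph::graph_from_data_frame(sub, directed = FALSE,
                                       vertices = data.frame(name = members))
    igraph::components(g)$no < 0.5 * size
  }, logical(1)))
}

#' Build a genetic-profile reference set
#'
#' Pairs of proteins whose genetic-interaction profiles correlate at or
#' above `r_min` (Pearson, over conditions where both measurements are
#' present) define a functional reference set: strongly correlated
#' profiles are indirect evidence for physical interaction. Pairs with
#' fewer than `min_overlap` shared conditions are excluded; pairs whose
#' shared support has zero variance are skipped with a message.
#'
#' @param profiles A profile table as returned by [read_profiles()]:
#'   `protein` column plus numeric condition columns, `NA` for missing.
#' @param r_min Correlation threshold (default 0.2).
#' @param min_overlap Minimum number of co-measured conditions
#'   (default 3).
#' @return A tibble of unordered pairs (`protein_a`, `protein_b`).
#' @export
genetic_reference <- function(profiles, r_min = 0.2, min_overlap = 3) {
  if (!is.data.frame(profiles) || !"protein" %in% names(profiles) ||
      nrow(profiles) < 2) {
    abort("`profiles` must hold a `protein` column and at least two rows",
          class = "binm_validation_error")
  }
  proteins <- profiles$protein
  vals <- as.matrix(profiles[, setdiff(names(profiles), "protein"), drop = FALSE])
  storage.mode(vals) <- "double"
  rr <- suppressWarnings(cor(t(vals), use = "pairwise.complete.obs"))
  present <- !is.na(vals)
  overlap <- present %*% t(present)
  ut <- upper.tri(rr)
  eligible <- ut & overlap >= min_overlap
  n_skipped <- sum(eligible & is.na(rr))
  if (n_skipped > 0) {
    inform(sprintf("skipped %d pair(s) with zero-variance shared support", n_skipped))
  }
  keep <- which(eligible & !is.na(rr) & rr >= r_min, arr.ind = TRUE)
  as_pair_tbl(tibble(protein_a = proteins[keep[, 1]],
                     protein_b = proteins[keep[, 2]]))
}

#' F2 score of a predicted pair set against a reference
#'
#' The F-beta score with beta = 2, \eqn{F_2 = 5PR / (4P + R)}, which
#' weights recall four times as heavily as precision — appropriate when
#' the reference set of binary interactions is known to be incomplete.
#' Precision is the fraction of predicted pairs in the reference;
#' recall divides by the reference pairs present in `universe` (the
#' observed edge set) when one is given, since pairs never observed
#' cannot be recovered by re-scoring. Pass `universe = NULL` for the
#' unrestricted denominator.
#'
#' @param predicted Nonempty table of predicted pairs.
#' @param reference Table of reference pairs.
#' @param universe Optional table of all observed pairs that
#'   predictions are drawn from; `predicted` must be a subset.
#' @return A scalar in `[0, 1]`; 0 when precision and recall are both 0.
#' @export
f2_score <- function(predicted, reference, universe = NULL) {
  pred <- as_pair_tbl(predicted, "predicted")
  if (nrow(pred) == 0) {
    abort("`predicted` is empty", class = "binm_validation_error")
  }
  pk <- pair_key(pred$protein_a, pred$protein_b)
  ref <- as_pair_tbl(reference, "reference")
  rk <- pair_key(ref$protein_a, ref$protein_b)
  if (!is.null(universe)) {
    uni <- as_pair_tbl(universe, "universe")
    uk <- pair_key(uni$protein_a, uni$protein_b)
    if (!all(pk %in% uk)) {
      abort("`predicted` must be a subset of `universe`",
            class = "binm_validation_error")
    }
    rk <- intersect(rk, uk)
  }
  if (length(rk) == 0) {
    abort("reference set shares no pair with the universe",
          class = "binm_validation_error")
  }
  tp <- length(intersect(pk, rk))
  precision <- tp / length(pk)
  recall <- tp / length(rk)
  if (precision + recall == 0) return(0)
  5 * precision * recall / (4 * precision + recall)
}

#' Select a rank cutoff maximizing the F2 score
#'
#' Evaluates [f2_score()] of the top-`k` prediction at cutoffs `step,
#' 2 step, ...` up to all edges, and returns the smallest cutoff
#' attaining the maximum. The full precision/recall/F2 curve is kept
#' for inspection and plotting.
#'
#' @inheritParams edge_auc
#' @param step Cutoff grid spacing (default 1).
#' @param restrict_reference If `TRUE` (default), recall counts only
#'   reference pairs present among the ranked edges; see [f2_score()].
#' @return A `binm_cutoff` object; `glance()` gives the selected cutoff
#'   and its F2, `tidy()` the full curve.
#' @export
select_cutoff <- function(ranked, reference, step = 1,
                          restrict_reference = TRUE) {
  if (!is.numeric(step) || step < 1) {
    abort("`step` must be a positive integer", class = "binm_validation_error")
  }
  n <- nrow(ranked)
  if (step > n) {
    abort(sprintf("`step` (%d) exceeds the number of ranked edges (%d)",
                  as.integer(step), n),
          class = "binm_validation_error")
  }
  ref <- as_pair_tbl(reference, "reference")
  keys <- pair_key(ranked$protein_a, ranked$protein_b)
  rk <- unique(pair_key(ref$protein_a, ref$protein_b))
  if (restrict_reference) rk <- intersect(rk, keys)
  n_ref <- length(rk)
  if (n_ref == 0) {
    abort("reference set shares no pair with the ranked edges",
          class = "binm_validation_error")
  }
  cutoffs <- unique(c(seq(step, n, by = step), n))
  cum_hits <- cumsum(keys %in% rk)
  tp <- cum_hits[cutoffs]
  precision <- tp / cutoffs
  recall <- tp / n_ref
  f2 <- ifelse(precision + recall == 0, 0,
               5 * precision * recall / (4 * precision + recall))
  best <- which.max(f2)  # first max = smallest cutoff on ties
  structure(
    list(
      cutoff = cutoffs[best],
      f2 = f2[best],
      curve = tibble(cutoff = cutoffs, precision = precision,
                     recall = recall, f2 = f2)
    ),
    class = "binm_cutoff"
  )
}

#' @export
print.binm_cutoff <- function(x, ...) {
  cat(sprintf("<binm_cutoff> selected cutoff %d with F2 = %.4f (grid of %d cutoffs)\n",
              x$cutoff, x$f2, nrow(x$curve)))
  invisible(x)
}

#' @method tidy binm_cutoff
#' @export
tidy.binm_cutoff <- function(x, ...) {
  x$curve
}

#' @method glance binm_cutoff
#' @export
glance.binm_cutoff <- function(x, ...) {
  tibble(cutoff = x$cutoff, f2 = x$f2,
         precision = x$curve$precision[x$curve$cutoff == x$cutoff][1],
         recall = x$curve$recall[x$curve$cutoff == x$cutoff][1])
}

#' @method autoplot binm_cutoff
#' @export
autoplot.binm_cutoff <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$cutoff, y = .data$f2)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$cutoff, linetype = "dashed") +
    ggplot2::labs(x = "Rank cutoff", y = "F2 score",
                  title = sprintf("Selected cutoff %d (F2 = %.3f)",
                                  object$cutoff, object$f2))
}

#' Jaccard overlap of two pair sets
#'
#' \eqn{|A \cap B| / |A \cup B|} for two sets of unordered pairs, e.g.
#' the edge sets of two networks derived from the same purification data.
#'
#' @param a,b Two-column tables of unordered pairs.
#' @return A scalar in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  pa <- as_pair_tbl(a, "a")
  pb <- as_pair_tbl(b, "b")
  ka <- pair_key(pa$protein_a, pa$protein_b)
  kb <- pair_key(pb$protein_a, pb$protein_b)
  u <- union(ka, kb)
  if (length(u) == 0) {
    abort("both pair sets are empty", class = "binm_validation_error")
  }
  length(intersect(ka, kb)) / length(u)
}

#' Compare bait-prey and prey-prey score distributions
#'
#' Classifies each ranked edge as bait-prey (at least one endpoint was
#' used as a purification bait) or prey-prey, and applies a
#' pooled-variance two-sample Student's t-test to their scores. A
#' positive statistic means bait-prey interactions — which carry direct
#' experimental evidence — score higher on average, as expected of a
#' score that favours direct physical contacts.
#'
#' @inheritParams edge_auc
#' @param baits Character vector of bait protein identifiers (or a
#'   one-column data frame).
#' @return A one-row tibble: `t_statistic`, `p_value`, `n_bait_prey`,
#'   `n_prey_prey`, `mean_bait_prey`, `mean_prey_prey`.
#' @export
baitprey_ttest <- function(ranked, baits, score_col = NULL) {
  col <- ranking_score_col(ranked, score_col)
  if (is.data.frame(baits)) baits <- baits[[1]]
  baits <- trimws(as.character(baits))
  is_bp <- ranked$protein_a %in% baits | ranked$protein_b %in% baits
  x_bp <- ranked[[col]][is_bp]
  x_pp <- ranked[[col]][!is_bp]
  if (length(x_bp) < 2) {
    abort("bait-prey group has fewer than 2 edges", class = "binm_validation_error")
  }
  if (length(x_pp) < 2) {
    abort("prey-prey group has fewer than 2 edges", class = "binm_validation_error")
  }
  if (stats::var(x_bp) == 0 && stats::var(x_pp) == 0 &&
      mean(x_bp) == mean(x_pp)) {
    # degenerate: identical constant groups; t is 0 by definition
    return(tibble(t_statistic = 0, p_value = 1,
                  n_bait_prey = length(x_bp), n_prey_prey = length(x_pp),
                  mean_bait_prey = mean(x_bp), mean_prey_prey = mean(x_pp)))
  }
  tt <- t.test(x_bp, x_pp, var.equal = TRUE)
  tibble(
    t_statistic = unname(tt$statistic),
    p_value = tt$p.value,
    n_bait_prey = length(x_bp),
    n_prey_prey = length(x_pp),
    mean_bait_prey = mean(x_bp),
    mean_prey_prey = mean(x_pp)
  )
}

#' @importFrom rlang %||%
NULL
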