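#' Rank observed edges by their BINM score
#'
#' Lists every observed edge (positive observed weight) in descending
#' order of its fitted direct-interaction score. Ties are broken
#' lexicographically by the canonical pair labels so the ranking is
#' fully reproducible.
#'
#' @param fit A `binm_fit`.
#' @param net Optional `weighted_network` or edge table the fit was
#'   produced from; when supplied its node set must match the fit.
#' @return A tibble with columns `rank`, `protein_a`, `protein_b`,
#'   `binm_score`, `obs_score`.
#' @export
rank_edges <- function(fit, net = NULL) {
  stopifnot(inherits(fit, "binm_fit"))
  if (!is.null(net)) {
    net <- as_weighted_network(net)
    if (!identical(net$nodes, fit$nodes)) {
      abort("node set of `net` does not match the fit", class = "binm_validation_error")
    }
  }
  idx <- which(upper.tri(fit$w_obs) & fit$w_obs > 0, arr.ind = TRUE)
  df <- tibble(
    protein_a = fit$nodes[idx[, 1]],
    protein_b = fit$nodes[idx[, 2]],
    binm_score = fit$w_dir[idx],
    obs_score = fit$w_obs[idx]
  )
  df <- canonicalize_pairs(df)
  df <- dplyr::arrange(df, dplyr::desc(.data$binm_score),
                       .data$protein_a, .data$protein_b)
  dplyr::mutate(df, rank = dplyr::row_number(), .before = 1)
}

#' Predict a binary interaction network by rank cutoff
#'
#' Takes the top `cutoff` edges of a ranking as the predicted set of
#' direct physical interactions.
#'
#' @param ranked A ranking from [rank_edges()] (or any edge table in
#'   ranked order).
#' @param cutoff Number of top edges to keep, between 1 and the number
#'   of ranked edges.
#' @return A tibble of unordered pairs (`protein_a`, `protein_b`).
#' @seealso [select_cutoff()] for choosing `cutoff` against a reference.
#' @export
binary_network <- function(ranked, cutoff) {
  if (!is.data.frame(ranked) || nrow(ranked) == 0) {
    abort("`ranked` must be a nonempty ranking", class = "binm_validation_error")
  }
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff < 1 ||
      cutoff > nrow(ranked)) {
    abort(sprintf("`cutoff` must lie in [1, %d]", nrow(ranked)),
          class = "binm_validation_error")
  }
  out <- utils::head(ranked, floor(cutoff))
  tibble(protein_a = out$protein_a, protein_b = out$protein_b)
}
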