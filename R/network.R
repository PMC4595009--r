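#' Build a weighted-network object from an edge table
#'
#' Converts a tidy edge list (`protein_a`, `protein_b`, `score`) into a
#' `weighted_network`: an ordered node vector plus a dense symmetric
#' adjacency matrix with zero diagonal and unit-interval weights. This is
#' the in-memory form consumed by [fit_binm()]; most users never need to
#' build one directly, since the fitting functions accept the edge table.
#'
#' Nodes are ordered lexicographically. Isolated nodes cannot occur: every
#' node named in an edge has, by construction, at least one incident edge
#' with positive weight.
#'
#' @param edges A data frame with columns `protein_a`, `protein_b`,
#'   `score` (unordered pairs, scores in `[0, 1]`). Duplicate records of
#'   the same unordered pair are resolved by keeping the maximum score.
#' @return An object of class `weighted_network`: a list with elements
#'   `nodes` (character vector) and `weights` (named symmetric matrix).
#' @examples
#' edges <- tibble::tibble(
#'   protein_a = c("A", "B"), protein_b = c("B", "C"), score = c(0.8, 0.5)
#' )
#' net <- as_weighted_network(edges)
#' net$weights
#' @export
as_weighted_network <- function(edges) {
  if (inherits(edges, "weighted_network")) {
    return(edges)
  }
  df <- validate_edge_tbl(edges)
  nodes <- sort(unique(c(df$protein_a, df$protein_b)))
  w <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  ia <- match(df$protein_a, nodes)
  ib <- match(df$protein_b, nodes)
  w[cbind(ia, ib)] <- df$score
  w[cbind(ib, ia)] <- df$score
  structure(list(nodes = nodes, weights = w), class = "weighted_network")
}

# Coerce/validate a tidy edge table: canonical pair order, deduplicated by
# max score, self-loops dropped, scores in [0, 1], positive weight only.
validate_edge_tbl <- function(edges, arg = "edges") {
  if (!is.data.frame(edges) || ncol(edges) < 3) {
    abort(sprintf("`%s` must be a data frame with columns protein_a, protein_b, score", arg),
          class = "binm_validation_error")
  }
  df <- as_tibble(edges)
  if (!all(c("protein_a", "protein_b", "score") %in% names(df))) {
    names(df)[1:3] <- c("protein_a", "protein_b", "score")
  }
  df <- df[, c("protein_a", "protein_b", "score")]
  df$protein_a <- trimws(as.character(df$protein_a))
  df$protein_b <- trimws(as.character(df$protein_b))
  df$score <- as.double(df$score)
  if (anyNA(df$score)) {
    abort("edge scores contain missing values", class = "binm_validation_error")
  }
  if (any(df$score < 0 | df$score > 1)) {
    abort("edge scores must lie in [0, 1]", class = "binm_validation_error")
  }
  df <- df[df$protein_a != df$protein_b, , drop = FALSE]
  df <- canonicalize_pairs(df)
  df <- dplyr::summarise(
    dplyr::group_by(df, .data$protein_a, .data$protein_b),
    score = max(.data$score), .groups = "drop"
  )
  df <- df[df$score > 0, , drop = FALSE]
  if (nrow(df) == 0) {
    abort("edge table contains no edges with positive weight",
          class = "binm_validation_error")
  }
  dplyr::arrange(df, .data$protein_a, .data$protein_b)
}

#' Extract the edge table of a weighted network
#'
#' The inverse of [as_weighted_network()]: returns the strictly positive
#' upper-triangle entries as a tidy edge tibble in canonical order.
#'
#' @param net A `weighted_network` object.
#' @return A tibble with columns `protein_a`, `protein_b`, `score`.
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  w <- net$weights
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  df <- tibble(
    protein_a = net$nodes[idx[, 1]],
    protein_b = net$nodes[idx[, 2]],
    score = w[idx]
  )
  dplyr::arrange(canonicalize_pairs(df), .data$protein_a, .data$protein_b)
}

#' @export
print.weighted_network <- function(x, ...) {
  n_edges <- sum(x$weights > 0) / 2
  cat(sprintf("<weighted_network> %d proteins, %d edges\n",
              length(x$nodes), n_edges))
  invisible(x)
}
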