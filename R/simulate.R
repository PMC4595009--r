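# Synthetic benchmark generator: planted modular direct-interaction
# networks observed through the forward model
#   W_obs = clip(D(W_dir + s * W_dir^2) + noise, [0, 1]),
# so that fitting, ranking, cutoff selection and every evaluation
# metric can be exercised without external data.

#' Generate a planted modular direct-interaction network
#'
#' Draws disjoint protein complexes with sizes uniform on
#' `[size_low, size_high]`. Within each complex a random spanning tree
#' guarantees connectivity, then every remaining pair becomes a direct
#' edge independently with probability `p_intra`; edge weights are
#' uniform on `[weight_low, weight_high]`. This emulates the sparse,
#' modular structure expected of the direct physical interactions
#' inside protein complexes.
#'
#' @param n_complexes Number of planted complexes.
#' @param size_low,size_high Complex size range (members), `size_low >= 2`.
#' @param p_intra Probability that a within-complex pair beyond the
#'   spanning tree is a direct edge, in `(0, 1]`.
#' @param weight_low,weight_high Direct-edge weight range,
#'   `0 < weight_low <= weight_high <= 1`.
#' @param seed Optional integer seed; the generator is deterministic
#'   given the seed and leaves the caller's RNG state untouched.
#' @return A list with `edges` (tibble `protein_a`, `protein_b`,
#'   `score`) and `complexes` (long tibble `complex`, `member`).
#' @export
generate_direct_network <- function(n_complexes = 20, size_low = 4,
                                    size_high = 8, p_intra = 0.6,
                                    weight_low = 0.5, weight_high = 0.9,
                                    seed = NULL) {
  if (!is.numeric(n_complexes) || n_complexes < 1) {
    abort("`n_complexes` must be a positive integer", class = "binm_validation_error")
  }
  if (!is.numeric(size_low) || size_low < 2 || size_high < size_low) {
    abort("need `size_low` >= 2 and `size_high` >= `size_low`",
          class = "binm_validation_error")
  }
  if (!is.numeric(p_intra) || p_intra <= 0 || p_intra > 1) {
    abort("`p_intra` must lie in (0, 1]", class = "binm_validation_error")
  }
  if (!is.numeric(weight_low) || weight_low <= 0 || weight_high < weight_low ||
      weight_high > 1) {
    abort("need 0 < `weight_low` <= `weight_high` <= 1",
          class = "binm_validation_error")
  }
  with_rng_seed(seed, {
    sizes <- size_low +
      sample.int(size_high - size_low + 1, n_complexes, replace = TRUE) - 1L
    n <- sum(sizes)
    node_fmt <- paste0("P%0", nchar(n), "d")
    cpx_fmt <- paste0("CPX%0", nchar(n_complexes), "d")
    nodes <- sprintf(node_fmt, seq_len(n))

    edge_a <- character()
    edge_b <- character()
    cpx_name <- character()
    cpx_member <- character()
    offset <- 0
    for (c_i in seq_len(n_complexes)) {
      s <- sizes[c_i]
      ids <- nodes[offset + seq_len(s)]
      cpx_name <- c(cpx_name, rep(sprintf(cpx_fmt, c_i), s))
      cpx_member <- c(cpx_member, ids)
      # random spanning tree: attach each node to a random predecessor
      perm <- sample(ids)
      for (k in 2:s) {
        edge_a <- c(edge_a, perm[sample.int(k - 1, 1)])
        edge_b <- c(edge_b, perm[k])
      }
      # remaining within-complex pairs
      pairs <- utils::combn(ids, 2)
      in_tree <- pair_key(pairs[1, ], pairs[2, ]) %in%
        pair_key(utils::tail(edge_a, s - 1), utils::tail(edge_b, s - 1))
      extra <- !in_tree & runif(ncol(pairs)) < p_intra
      edge_a <- c(edge_a, pairs[1, extra])
      edge_b <- c(edge_b, pairs[2, extra])
      offset <- offset + s
    }
    weights <- runif(length(edge_a), weight_low, weight_high)
    edges <- canonicalize_pairs(tibble(
      protein_a = edge_a, protein_b = edge_b, score = weights
    ))
    list(
      edges = dplyr::arrange(edges, .data$protein_a, .data$protein_b),
      complexes = tibble(complex = cpx_name, member = cpx_member)
    )
  })
}

#' Observe a direct network through the co-complex forward model
#'
#' Applies the model's forward assumptions to a planted direct network:
#' the noise-free observation is
#' \eqn{D(W_{dir} + s \, W_{dir}^2)} — each pair's direct weight plus
#' the associations induced through common neighbours — after which
#' symmetric Gaussian noise is added to the nonzero entries and the
#' result is clipped to `[0, 1]`. Entries that are zero in the forward
#' model stay zero, so the observed support is exactly the union of
#' direct edges and length-2 indirect paths (no spurious edges).
#'
#' @param truth Planted direct network: an edge table or
#'   `weighted_network`.
#' @param noise_sd Standard deviation of the Gaussian noise on observed
#'   scores (`>= 0`).
#' @param indirect_scale Multiplier `s` on the indirect term; the model
#'   assumes 1, other values stress-test misspecification.
#' @param seed Optional integer seed.
#' @return An observed edge tibble (`protein_a`, `protein_b`, `score`).
#' @export
forward_observe <- function(truth, noise_sd = 0.02, indirect_scale = 1,
                            seed = NULL) {
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    abort("`noise_sd` must be nonnegative", class = "binm_validation_error")
  }
  net <- as_weighted_network(truth)
  w <- net$weights
  m <- off_diagonal(w + indirect_scale * (w %*% w))
  with_rng_seed(seed, {
    if (noise_sd > 0) {
      n <- nrow(m)
      noise <- matrix(0, n, n)
      ut <- upper.tri(m) & m > 0
      noise[ut] <- rnorm(sum(ut), 0, noise_sd)
      noise <- noise + t(noise)
      m[m > 0] <- m[m > 0] + noise[m > 0]
    }
    m <- pmin(pmax(m, 0), 1)
    network_edges(structure(list(nodes = net$nodes, weights = m),
                            class = "weighted_network"))
  })
}

#' Sample an incomplete reference set from the planted truth
#'
#' Gold standards of binary interactions are incomplete; this samples a
#' uniform random subset of the planted direct edges to emulate that.
#'
#' @param truth Planted direct network (edge table or
#'   `weighted_network`) with at least one edge.
#' @param coverage Fraction of planted edges to include, in `(0, 1]`;
#'   the subset size is `round(coverage * n_edges)`.
#' @param seed Optional integer seed.
#' @return A tibble of unordered pairs.
#' @export
planted_reference <- function(truth, coverage = 1, seed = NULL) {
  if (!is.numeric(coverage) || coverage <= 0 || coverage > 1) {
    abort("`coverage` must lie in (0, 1]", class = "binm_validation_error")
  }
  edges <- if (inherits(truth, "weighted_network")) network_edges(truth) else
    validate_edge_tbl(truth)
  k <- round(coverage * nrow(edges))
  with_rng_seed(seed, {
    sel <- sort(sample.int(nrow(edges), k))
    as_pair_tbl(edges[sel, c("protein_a", "protein_b")])
  })
}

#' Simulate a complete planted AP-MS benchmark instance
#'
#' Convenience wrapper chaining [generate_direct_network()],
#' [forward_observe()] and [planted_reference()] under a single seed.
#'
#' @inheritParams generate_direct_network
#' @inheritParams forward_observe
#' @param coverage Reference coverage passed to [planted_reference()].
#' @param seed Integer seed governing the whole instance.
#' @return A `binm_sim` object: list with `truth` (planted edge table),
#'   `observed` (observed edge table), `complexes`, `reference` and
#'   `meta` (all generation parameters).
#' @examples
#' sim <- simulate_apms(n_complexes = 3, seed = 1)
#' fit <- fit_binm(sim$observed)
#' edge_auc(rank_edges(fit), sim$truth)
#' @export
simulate_apms <- function(n_complexes = 20, size_low = 4, size_high = 8,
                          p_intra = 0.6, weight_low = 0.5,
                          weight_high = 0.9, noise_sd = 0.02,
                          indirect_scale = 1, coverage = 1, seed = NULL) {
  meta <- list(
    n_complexes = n_complexes, size_low = size_low, size_high = size_high,
    p_intra = p_intra, weight_low = weight_low, weight_high = weight_high,
    noise_sd = noise_sd, indirect_scale = indirect_scale,
    coverage = coverage, seed = seed,
    noise_model = "gaussian on nonzero forward-model entries, clipped to [0,1]"
  )
  out <- with_rng_seed(seed, {
    planted <- generate_direct_network(
      n_complexes, size_low, size_high, p_intra, weight_low, weight_high,
      seed = NULL
    )
    observed <- forward_observe(planted$edges, noise_sd, indirect_scale,
                                seed = NULL)
    reference <- planted_reference(planted$edges, coverage, seed = NULL)
    list(truth = planted$edges, observed = observed,
         complexes = planted$complexes, reference = reference)
  })
  structure(c(out, list(meta = meta)), class = "binm_sim")
}

#' @export
print.binm_sim <- function(x, ...) {
  cat(sprintf(
    "<binm_sim> %d complexes | %d direct edges | %d observed edges | noise_sd = %g | seed = %s\n",
    length(unique(x$complexes$complex)), nrow(x$truth), nrow(x$observed),
    x$meta$noise_sd, x$meta$seed %||% "NULL"
  ))
  invisible(x)
}

#' Write a simulated instance to a directory
#'
#' Writes `observed_edges.tsv`, `true_edges.tsv`, `complexes.tsv`,
#' `reference_pairs.tsv` in the package's file formats plus a
#' `metadata.json` sidecar recording every generation parameter, so the
#' bundle is re-loadable with the `read_*` functions and fully
#' reproducible.
#'
#' @param sim A `binm_sim` object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "binm_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(sim$observed, file.path(dir, "observed_edges.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$truth, file.path(dir, "true_edges.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$reference, file.path(dir, "reference_pairs.tsv"),
                   col_names = FALSE, progress = FALSE)
  cpx_lines <- vapply(
    split(sim$complexes$member, sim$complexes$complex),
    paste, character(1), collapse = "\t"
  )
  readr::write_lines(paste(names(cpx_lines), cpx_lines, sep = "\t"),
                     file.path(dir, "complexes.tsv"))
  jsonlite::write_json(
    c(list(tool = "binm", version = as.character(utils::packageVersion("binm"))),
      sim$meta),
    file.path(dir, "metadata.json"),
    auto_unbox = TRUE, null = "null", pretty = TRUE
  )
  invisible(dir)
}
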