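# Shared fixtures and independent oracles for the test suite.

edges_df <- function(a, b, s) {
  tibble::tibble(protein_a = a, protein_b = b, score = s)
}

pairs_df <- function(a, b) {
  tibble::tibble(protein_a = a, protein_b = b)
}

# Single-edge two-node network with observed weight w.
two_node_edges <- function(w = 0.8) {
  edges_df("A", "B", w)
}

# Symmetric zero-diagonal matrix from upper-triangle values (row-major).
sym_mat <- function(n, upper_vals) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- 0
  m[lower.tri(m)] <- 0
  ut <- which(upper.tri(m), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  m[ut] <- upper_vals
  m + t(m)
}

# Random sparse symmetric weight matrix in [0,1] with zero diagonal.
random_obs <- function(n, density = 0.5) {
  m <- matrix(stats::runif(n * n), n, n)
  m[m < (1 - density)] <- 0
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

# Wrap a symmetric weight matrix as a weighted_network for fitting.
mat_network <- function(m) {
  nodes <- sprintf("N%02d", seq_len(nrow(m)))
  dimnames(m) <- list(nodes, nodes)
  structure(list(nodes = nodes, weights = m), class = "weighted_network")
}

# Scalar-loop evaluation of the fit objective, independent of the
# package's matrix implementation.
objective_oracle <- function(w_obs, w_dir, lambda) {
  n <- nrow(w_obs)
  loss <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      indirect <- 0
      for (k in seq_len(n)) indirect <- indirect + w_dir[i, k] * w_dir[k, j]
      loss <- loss + (w_obs[i, j] - w_dir[i, j] - indirect)^2
    }
  }
  loss + lambda * sum(w_dir^2)
}

# Brute-force pairwise AUC: concordant pairs / (n_pos * n_neg), ties 0.5.
auc_oracle <- function(scores, is_pos) {
  pos <- scores[is_pos]
  neg <- scores[!is_pos]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Projected gradient descent on the fit objective with backtracking,
# restricted to the observed support: an independent optimizer used to
# certify the quality of the multiplicative update's solution.
pgd_oracle <- function(w_obs, lambda = 1, iters = 5000, eta0 = 0.01) {
  w <- w_obs
  diag(w) <- 0
  support <- w_obs > 0
  eta <- eta0
  obj <- function(m) {
    r <- w_obs - m - m %*% m
    diag(r) <- 0
    sum(r^2) + lambda * sum(m^2)
  }
  j_cur <- obj(w)
  for (t in seq_len(iters)) {
    r <- w_obs - w - w %*% w
    diag(r) <- 0
    g <- 2 * (lambda * w - r - r %*% w - w %*% r)
    w_new <- pmax(w - eta * g, 0)
    w_new[!support] <- 0
    diag(w_new) <- 0
    j_new <- obj(w_new)
    if (is.finite(j_new) && j_new <= j_cur) {
      w <- w_new
      j_cur <- j_new
      eta <- eta * 1.1
    } else {
      eta <- eta / 2
      if (eta < 1e-14) break
    }
  }
  list(w = w, objective = j_cur)
}

# Pooled-variance two-sample t statistic, textbook formula.
pooled_t_oracle <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
}

write_tmp <- function(lines, ext = ".tsv") {
  f <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
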