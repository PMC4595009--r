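ranked_fixture <- function(a, b, s) {
  tibble::tibble(rank = seq_along(s), protein_a = a, protein_b = b,
                 binm_score = s, obs_score = s)
}

test_that("AUC handles perfect separation, all ties, and matches brute force", {
  rk <- ranked_fixture(c("A", "A", "B", "C"), c("B", "C", "C", "D"),
                       c(0.9, 0.8, 0.2, 0.1))
  ref <- pairs_df(c("A", "A"), c("B", "C"))
  expect_equal(edge_auc(rk, ref), 1.0)

  tied <- ranked_fixture(c("A", "A", "B", "C"), c("B", "C", "C", "D"),
                         rep(0.5, 4))
  expect_equal(edge_auc(tied, ref), 0.5)

  withr::with_seed(31, {
    for (i in 1:20) {
      n <- sample(5:15, 1)
      s <- round(stats::runif(n), 1)  # coarse grid to force some ties
      pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
      if (!any(pos) || all(pos)) next
      a <- sprintf("L%02d", 1:n)
      b <- sprintf("R%02d", 1:n)
      rk_i <- ranked_fixture(a, b, s)
      ref_i <- pairs_df(a[pos], b[pos])
      expect_equal(edge_auc(rk_i, ref_i), auc_oracle(s, pos))
    }
  })

  expect_error(edge_auc(rk, pairs_df("X", "Y")), "no positives",
               class = "binm_validation_error")
  all_ref <- pairs_df(rk$protein_a, rk$protein_b)
  expect_error(edge_auc(rk, all_ref), "no negatives",
               class = "binm_validation_error")
})

test_that("ROC curve passes through the corners and its area equals the AUC", {
  rk <- ranked_fixture(c("A", "A", "B", "C"), c("B", "C", "C", "D"),
                       c(0.9, 0.8, 0.2, 0.1))
  ref <- pairs_df(c("A", "A"), c("B", "C"))
  roc <- roc_curve(rk, ref)
  expect_equal(roc$fpr[1], 0)
  expect_equal(roc$tpr[1], 0)
  expect_true(any(roc$fpr == 0 & roc$tpr == 1))  # perfect ranking
  expect_equal(roc_auc(roc), 1.0)

  # reversed ranking has area 0
  rev_ref <- pairs_df(c("B", "C"), c("C", "D"))
  expect_equal(roc_auc(roc_curve(rk, rev_ref)), 0)

  withr::with_seed(37, {
    for (i in 1:20) {
      n <- sample(5:20, 1)
      s <- round(stats::runif(n), 1)
      pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
      if (!any(pos) || all(pos)) next
      rk_i <- ranked_fixture(sprintf("L%02d", 1:n), sprintf("R%02d", 1:n), s)
      ref_i <- pairs_df(rk_i$protein_a[pos], rk_i$protein_b[pos])
      expect_equal(roc_auc(roc_curve(rk_i, ref_i)), edge_auc(rk_i, ref_i),
                   tolerance = 1e-10)
    }
  })
})

test_that("top-k validation counts are monotone and match set intersection", {
  withr::with_seed(41, {
    n <- 10
    s <- sort(stats::runif(n), decreasing = TRUE)
    rk <- ranked_fixture(sprintf("L%02d", 1:n), sprintf("R%02d", 1:n), s)
    pos <- sample(n, 4)
    ref <- pairs_df(rk$protein_a[pos], rk$protein_b[pos])
    rep_ <- topk_validated(rk, ref, 1:n)
    expect_true(all(diff(rep_$n_validated) >= 0))
    expect_equal(rep_$n_validated[n], 4)
    # exhaustive per-k intersection
    keys <- paste(rk$protein_a, rk$protein_b)
    ref_keys <- paste(ref$protein_a, ref$protein_b)
    for (k in 1:n) {
      expect_equal(rep_$n_validated[k], length(intersect(keys[1:k], ref_keys)))
    }
  })
  rk1 <- ranked_fixture("A", "B", 0.9)
  expect_equal(topk_validated(rk1, pairs_df("A", "B"), 1)$n_validated, 1)
  expect_error(topk_validated(rk1, pairs_df("A", "B"), 2),
               class = "binm_validation_error")
})

test_that("top-k mean external score excludes unscored pairs", {
  rk <- ranked_fixture(c("A", "A", "B", "C", "D", "E"),
                       c("B", "C", "C", "D", "E", "F"),
                       c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4))
  # all scored equally
  ext_eq <- tibble::tibble(protein_a = rk$protein_a, protein_b = rk$protein_b,
                           score = 2)
  expect_equal(topk_mean_score(rk, ext_eq, c(2, 6))$mean_score, c(2, 2))

  # half unscored: mean over the scored half only
  ext_half <- ext_eq[c(1, 3, 5), ]
  ext_half$score <- c(1, 2, 3)
  out <- topk_mean_score(rk, ext_half, c(4, 6))
  expect_equal(out$mean_score, c((1 + 2) / 2, (1 + 2 + 3) / 3))

  # hand-computed mixed fixture
  ext_mix <- tibble::tibble(
    protein_a = c("A", "A", "B", "C"), protein_b = c("B", "C", "C", "D"),
    score = c(4, 0, 6, 10)
  )
  expect_equal(topk_mean_score(rk, ext_mix, 4)$mean_score, (4 + 0 + 6 + 10) / 4)
})

test_that("complex connectivity applies the component-halving rule", {
  catalog <- tibble::tibble(
    complex = c(rep("path4", 4), rep("edge3", 3), rep("none3", 3)),
    member = c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J")
  )
  pred <- pairs_df(c("A", "B", "C", "E"), c("B", "C", "D", "F"))
  # path4: 1 component < 2 -> counted; edge3: 2 components, not < 1.5;
  # none3: no predicted edges, never counted
  expect_equal(complex_connectivity(pred, catalog), 1)

  # adding edges can only help (monotone)
  pred2 <- dplyr::bind_rows(pred, pairs_df("F", "G"))
  expect_gte(complex_connectivity(pred2, catalog),
             complex_connectivity(pred, catalog))
  expect_equal(complex_connectivity(pred2, catalog), 2)

  expect_error(complex_connectivity(pred, catalog, min_size = 1),
               class = "binm_validation_error")
})

test_that("genetic reference thresholds pairwise-complete Pearson correlations", {
  prof <- tibble::tibble(
    protein = c("p1", "p2", "p3"),
    c1 = c(1, 1, 3), c2 = c(2, 2, 2), c3 = c(3, 3, 1)
  )
  ref <- genetic_reference(prof, r_min = 0.2)
  # p1,p2 identical (r = 1); p3 anti-correlated with both (r = -1)
  expect_equal(nrow(ref), 1)
  expect_equal(c(ref$protein_a, ref$protein_b), c("p1", "p2"))

  # scalar-loop oracle over a 5-protein fixture with missing values
  withr::with_seed(43, {
    vals <- matrix(stats::rnorm(5 * 8), 5, 8)
    vals[sample(length(vals), 6)] <- NA
    prof5 <- dplyr::bind_cols(
      tibble::tibble(protein = sprintf("p%d", 1:5)),
      tibble::as_tibble(`colnames<-`(vals, sprintf("c%d", 1:8)))
    )
    expected <- list()
    for (i in 1:4) {
      for (j in (i + 1):5) {
        ok <- !is.na(vals[i, ]) & !is.na(vals[j, ])
        if (sum(ok) < 3) next
        r <- suppressWarnings(stats::cor(vals[i, ok], vals[j, ok]))
        if (!is.na(r) && r >= 0.2) {
          expected[[length(expected) + 1]] <- sprintf("p%d p%d", i, j)
        }
      }
    }
    got <- genetic_reference(prof5, r_min = 0.2, min_overlap = 3)
    expect_setequal(paste(got$protein_a, got$protein_b), unlist(expected))
  })

  # r_min extremes
  all_pairs <- genetic_reference(prof, r_min = -1)
  expect_equal(nrow(all_pairs), 3)
  expect_equal(nrow(genetic_reference(prof, r_min = 1.5)), 0)
})

test_that("F2 weights recall over precision as the F-beta identity requires", {
  # P = R = p  =>  F2 = p
  pred <- pairs_df(c("A", "B"), c("B", "C"))
  ref <- pairs_df(c("A", "X"), c("B", "Y"))
  # P = 1/2, R = 1/2 (unrestricted)
  expect_equal(f2_score(pred, ref), 0.5)

  # P = 1, R = 0.5 -> 5 * 0.5 / 4.5
  pred1 <- pairs_df("A", "B")
  expect_equal(f2_score(pred1, ref), 5 * 1 * 0.5 / (4 * 1 + 0.5))

  # disjoint prediction scores zero
  expect_equal(f2_score(pairs_df("M", "N"), ref), 0)

  # restricted recall denominator
  uni <- pairs_df(c("A", "M"), c("B", "N"))
  expect_equal(f2_score(pred1, ref, universe = uni), 1)  # R = 1/1, P = 1

  expect_error(f2_score(pred[0, ], ref), class = "binm_validation_error")
  expect_error(f2_score(pairs_df("Q", "R"), ref, universe = uni),
               class = "binm_validation_error")
})

test_that("cutoff selection maximizes F2 and prefers the smallest tie", {
  s <- seq(1, 0.1, length.out = 10)
  rk <- ranked_fixture(sprintf("L%02d", 1:10), sprintf("R%02d", 1:10), s)
  ref <- pairs_df(rk$protein_a[1:3], rk$protein_b[1:3])
  sel <- select_cutoff(rk, ref, step = 1)
  expect_equal(sel$cutoff, 3)
  expect_equal(sel$f2, 1)
  expect_equal(glance(sel)$cutoff, 3)
  expect_equal(nrow(tidy(sel)), 10)

  expect_error(select_cutoff(rk, pairs_df("X", "Y"), step = 1),
               class = "binm_validation_error")
  expect_error(select_cutoff(rk, ref, step = 11), class = "binm_validation_error")
})

test_that("jaccard is symmetric, 1 iff equal, and matches printed-network arithmetic", {
  a <- pairs_df(c("A", "B"), c("B", "C"))
  b <- pairs_df(c("B", "C"), c("C", "D"))
  expect_equal(jaccard(a, a), 1)
  expect_equal(jaccard(a, b), jaccard(b, a))
  expect_lt(jaccard(a, b), 1)

  # overlap of two co-complex networks with 9070 and 10096 edges sharing
  # 4910: 4910 / 14256; their top-2562/top-3018 binary networks sharing
  # 1902: 1902 / 3678
  mk <- function(n, shared, prefix) {
    pairs_df(c(sprintf("S%05d", seq_len(shared)),
               sprintf("%s%05d", prefix, seq_len(n - shared))),
             c(sprintf("T%05d", seq_len(shared)),
               sprintf("%sx%05d", prefix, seq_len(n - shared))))
  }
  expect_equal(jaccard(mk(9070, 4910, "C"), mk(10096, 4910, "F")),
               4910 / 14256, tolerance = 1e-12)
  expect_equal(round(4910 / 14256, 2), 0.34)
  expect_equal(jaccard(mk(2562, 1902, "C"), mk(3018, 1902, "F")),
               1902 / 3678, tolerance = 1e-12)
  expect_equal(round(1902 / 3678, 2), 0.52)

  expect_error(jaccard(a[0, ], b[0, ]), class = "binm_validation_error")
})

test_that("bait-prey t-test uses the pooled-variance Student statistic", {
  rk <- ranked_fixture(c("b1", "b1", "x", "y"), c("x", "y", "y", "z"),
                       c(0.9, 0.8, 0.1, 0.2))
  out <- baitprey_ttest(rk, baits = "b1")
  expect_gt(out$t_statistic, 0)
  expect_lt(out$p_value, 0.05)
  expect_equal(out$n_bait_prey, 2)

  # identical constant groups give t = 0
  rk0 <- ranked_fixture(c("b1", "b1", "x", "y"), c("x", "y", "y", "z"),
                        rep(0.5, 4))
  expect_equal(baitprey_ttest(rk0, "b1")$t_statistic, 0)

  # 20-edge fixture against the textbook pooled formula
  withr::with_seed(47, {
    n <- 20
    is_bp <- rep(c(TRUE, FALSE), each = 10)
    s <- stats::runif(n)
    rk20 <- ranked_fixture(
      ifelse(is_bp, "bait", sprintf("u%02d", 1:n)),
      sprintf("v%02d", 1:n), s
    )
    out20 <- baitprey_ttest(rk20, "bait")
    expect_equal(out20$t_statistic, pooled_t_oracle(s[is_bp], s[!is_bp]))
  })

  expect_error(baitprey_ttest(rk, baits = c("b1", "x", "y")),
               "prey-prey", class = "binm_validation_error")
})
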