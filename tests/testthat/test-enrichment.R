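## independent oracle: P(overlap >= k) by exhaustive enumeration of all
## possible foregrounds of size n from a universe of size N with m marked
enum_hyper_tail <- function(k, m, n, N) {
  idx <- utils::combn(N, n)
  marked <- seq_len(m)
  mean(apply(idx, 2, function(fg) sum(fg %in% marked) >= k))
}

test_that("hypergeometric tail matches exhaustive enumeration", {
  for (N in c(7, 10, 12)) {
    for (m in c(2, floor(N / 2))) {
      for (n in c(3, floor(N / 2))) {
        for (k in 0:min(m, n)) {
          expect_equal(hypergeom_p(k, m, n, N), enum_hyper_tail(k, m, n, N),
                       tolerance = 1e-12,
                       label = sprintf("N=%d m=%d n=%d k=%d", N, m, n, k))
        }
      }
    }
  }
  ## full-overlap closed form: 1 / C(20, 5)
  expect_equal(hypergeom_p(5, 5, 5, 20), 1 / choose(20, 5),
               tolerance = 1e-12)
  expect_identical(hypergeom_p(0, 5, 5, 20), 1)
  ## foreground == universe: overlap is forced, p = 1
  expect_equal(hypergeom_p(5, 5, 20, 20), 1, tolerance = 1e-12)
  expect_error(hypergeom_p(6, 5, 5, 20), "impossible")
})

test_that("BH adjustment follows the hand-applied step-up rule", {
  expect_identical(bh_adjust(0.037), 0.037)
  expect_identical(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))

  step_up <- function(p) {          # independent hand implementation
    n <- length(p); o <- order(p)
    q <- p[o] * n / seq_len(n)
    q <- rev(cummin(rev(q)))
    pmin(q, 1)[order(o)]
  }
  set.seed(30)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_adjust(p), step_up(p), tolerance = 1e-12)
  }
  ## permutation equivariance
  p <- runif(15); perm <- sample(15)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]), tolerance = 1e-12)
})

## a signature whose ranking we fully control
synthetic_signature <- function(ranked_ids, stats = NULL) {
  if (is.null(stats)) stats <- seq(1, 0, length.out = length(ranked_ids))
  delta <- stats::setNames(stats, ranked_ids)
  structure(list(network_index = 1L, node_index = 1L, delta_y = delta,
                 ranked_genes = ranked_ids), class = "node_signature")
}

test_that("node enrichment reports planted tails at closed-form p-values", {
  universe <- sprintf("g%03d", 1:300)
  module <- universe[1:20]                 # occupies the top of the ranking
  sig <- synthetic_signature(universe)
  coll <- gene_set_collection(list(planted = module,
                                   decoy = universe[150:180]),
                              universe = universe)
  res <- enrich_node(sig, coll, top_k = 50, threshold = 1e-8)
  expect_identical(res$set, "planted")
  expect_identical(res$direction, "activating")
  expect_identical(res$effect, 20L)
  ## closed-form full-overlap tail; BH over the node's 4 tests (the decoy
  ## and the opposite tail overlap nothing, so their p-values are 1)
  p_exact <- hypergeom_p(20, 20, 50, 300)
  expect_equal(res$p, p_exact, tolerance = 1e-12)
  expect_equal(res$q, bh_adjust(c(p_exact, 1, 1, 1))[1], tolerance = 1e-12)

  ## suppressing tail: module at the bottom of the ranking
  sig2 <- synthetic_signature(rev(universe))
  res2 <- enrich_node(sig2, coll, top_k = 50, threshold = 1e-8)
  expect_identical(res2$set, "planted")
  expect_identical(res2$direction, "suppressing")

  ## thresholding: nothing at 1e-8 from a random ranking
  set.seed(31)
  res3 <- enrich_node(synthetic_signature(sample(universe)), coll,
                      top_k = 50, threshold = 1e-8)
  expect_identical(nrow(res3), 0L)
  expect_error(enrich_node(sig, coll, top_k = 400), "universe")
})

test_that("GSEA score is extremal, antisymmetric and null-calibrated", {
  ids <- sprintf("g%03d", 1:100)
  stats <- sort(abs(stats::rnorm(100, sd = 2)), decreasing = TRUE)
  sig <- synthetic_signature(ids, stats)

  ## a set occupying the exact top of the ranking attains ES = 1
  g <- gsea_preranked(sig, ids[1:10], n_perm = 100, seed = 1)
  expect_equal(g$es, 1, tolerance = 1e-12)
  expect_lte(g$p, 0.05)

  ## reversing the ranking flips the score's sign
  set.seed(40)
  random_set <- sample(ids, 15)
  fwd <- gsea_preranked(sig, random_set, n_perm = 100, seed = 2)
  rev_sig <- synthetic_signature(rev(ids), rev(stats))
  bwd <- gsea_preranked(rev_sig, random_set, n_perm = 100, seed = 2)
  expect_equal(fwd$es, -bwd$es, tolerance = 1e-12)
  expect_true(abs(fwd$es) <= 1 && abs(bwd$es) <= 1)

  ## null calibration: random sets give uniform p on average
  set.seed(41)
  ps <- replicate(200, gsea_preranked(sig, sample(ids, 12), n_perm = 100,
                                      seed = sample.int(1e6, 1))$p)
  expect_gt(mean(ps), 0.45)
  expect_lt(mean(ps), 0.55)
})

test_that("GSEA running sum agrees with the fgsea reference", {
  skip_if_not_installed("fgsea")
  ids <- sprintf("g%03d", 1:120)
  stats <- sort(stats::rnorm(120), decreasing = TRUE)
  set.seed(50)
  for (i in 1:5) {
    genes <- sample(ids, sample(5:20, 1))
    mine <- daeprobe:::gsea_es(stats::setNames(stats, ids), ids %in% genes)
    ref <- fgsea::calcGseaStat(stats::setNames(stats, ids),
                               selectedStats = which(ids %in% genes),
                               gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-12)
  }
})

test_that("recovery summaries match an independent recount", {
  none <- summarize_recovery(daeprobe:::empty_enrichment(), 100, 2)
  expect_identical(none$total_recovered, 0L)
  expect_identical(none$unique_recovered, 0L)
  expect_identical(none$per_network_counts, c(0L, 0L))

  res <- data.frame(
    network = c(1, 1, 1, 2, 2, 3),
    node = c(1, 2, 3, 1, 2, 4),
    set = c("a", "a", "b", "a", "c", "a"),
    direction = "activating", p = 1e-12, q = 1e-10,
    stringsAsFactors = FALSE)
  s <- summarize_recovery(res, n_nodes = 200, n_networks = 3)
  ## oracle recount: flat tallies over the result rows
  expect_identical(s$total_recovered, nrow(res))
  expect_identical(s$unique_recovered, length(unique(res$set)))
  expect_equal(s$frequency[["a"]], sum(res$set == "a") / 200)
  expect_identical(s$per_network_counts,
                   as.integer(table(factor(res$network, levels = 1:3))))

  ## the display-floor arithmetic: 150 of 5000 nodes is a 3% frequency
  res150 <- data.frame(network = 1, node = 1:150, set = "s",
                       direction = "activating", p = 0, q = 0)
  expect_equal(summarize_recovery(res150, 5000, 100)$frequency[["s"]], 0.03)
})

test_that("rank-sum comparisons use exact small-sample enumeration", {
  ## identical samples: no evidence either way
  p_same <- compare_architectures(c(4, 9, 14, 22), c(4, 9, 14, 22),
                                  "two_sided")$p
  expect_gte(p_same, 0.99)

  ## A = {5,6,7} vs B = {1,2,3}, one-sided: the most extreme of C(6,3)
  ## equally likely rank assignments
  cmp <- compare_architectures(c(5, 6, 7), c(1, 2, 3), "a_greater")
  expect_equal(cmp$p, 1 / choose(6, 3), tolerance = 1e-12)

  ## exact enumeration oracle over all rank assignments, n <= 8
  enum_rank_p <- function(a, b) {
    pooled <- c(a, b); r <- rank(pooled)
    obs <- sum(r[seq_along(a)])
    combos <- utils::combn(length(pooled), length(a))
    ws <- apply(combos, 2, function(i) sum(r[i]))
    mean(ws >= obs)
  }
  set.seed(60)
  for (i in 1:5) {
    vals <- sample(1000, 8)           # tie-free by construction
    a <- vals[1:4]; b <- vals[5:8]
    expect_equal(compare_architectures(a, b, "a_greater")$p,
                 enum_rank_p(a, b), tolerance = 1e-12)
  }
  expect_error(compare_architectures(numeric(0), 1:3), "non-empty")
})

test_that("the ensemble-wide error-control arithmetic holds", {
  expect_equal(expected_false_discoveries(5000, 110 + 110 + 408 + 816, 1e-8),
               5000 * 1444 * 1e-8, tolerance = 1e-15)
  expect_lt(expected_false_discoveries(5000, 1444, 1e-8), 1)
})
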