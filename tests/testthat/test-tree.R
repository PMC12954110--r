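random_distance <- function(k, seed) {
  set.seed(seed)
  d <- matrix(0, k, k, dimnames = list(LETTERS[1:k], LETTERS[1:k]))
  d[upper.tri(d)] <- runif(k * (k - 1) / 2)
  d + t(d)
}

random_ao_matrix <- function(k, seed) {
  d <- random_distance(k, seed)
  null <- null_distribution(20, 100, seed = 1)
  structure(list(cluster_ids = rownames(d), similarity = 1 - d,
                 zscore = (1 - d - null$mean) / null$sd, null = null),
            class = "ao_matrix")
}

test_that("two clusters merge once at height 1 - AO", {
  ao <- pairwise_ao(list(A = c("g1", "g2", "g3"), B = c("g2", "g1", "g3")),
                    m_shuffles = 50, seed = 1)
  tree <- linkage_from_ao(ao)
  expect_equal(nrow(tree$merges), 1L)
  expect_equal(tree$merges$height, 1 - 2 / 3, tolerance = 1e-12)
  expect_error(linkage_from_ao(pairwise_ao(list(A = c("g1", "g2")),
                                           m_shuffles = 50)),
               "at least 2")
})

test_that("identical clusters merge first at height zero", {
  rankings <- list(A = paste0("g", 1:6), B = paste0("g", 1:6),
                   C = paste0("g", 6:1))
  tree <- linkage_from_ao(pairwise_ao(rankings, m_shuffles = 50, seed = 1))
  expect_identical(c(tree$merges$a[1], tree$merges$b[1]), c("A", "B"))
  expect_equal(tree$merges$height[1], 0)
})

test_that("agglomeration matches stats::hclust on tie-free matrices", {
  for (seed in 1:30) {
    k <- sample(3:6, 1)
    d <- random_distance(k, seed + 100)
    for (method in c("average", "complete", "single")) {
      tree <- linkage_from_distance(d, method)
      ref <- stats::hclust(stats::as.dist(d), method = method)
      expect_equal(sort(tree$height), sort(ref$height), tolerance = 1e-12)
      for (kk in seq_len(k)) {
        mine <- tree_partition(tree, kk)
        theirs <- split(rownames(d), stats::cutree(ref, k = kk))
        expect_true(same_partition(mine, theirs))
      }
    }
  }
})

test_that("merge heights are non-decreasing (monotone linkages)", {
  for (seed in 1:10) {
    tree <- linkage_from_distance(random_distance(6, seed), "average")
    expect_true(all(diff(tree$merges$height) >= -1e-12))
  }
})

test_that("ties break toward the lexicographically smallest pair", {
  d <- matrix(c(0, 1, 1, 1,
                1, 0, 0.5, 1,
                1, 0.5, 0, 1,
                1, 1, 1, 0), 4, 4,
              dimnames = list(c("D", "C", "B", "A"), c("D", "C", "B", "A")))
  # distances C-B and (via the remaining 1s) several pairs tie at 1 later;
  # the first merge is the unique minimum, later ties resolve by label
  tree <- linkage_from_distance(d, "single")
  expect_identical(c(tree$merges$a[1], tree$merges$b[1]), c("B", "C"))
  expect_identical(tree$merges$a[2], "A")  # A+? before D at the tied height
})

test_that("merge_to_k keeps cells, nests partitions, honors the z order", {
  sim <- simulate_dataset(simulation_config(
    n_populations = 4L, cells_per_population = 30L, n_genes = 300L,
    markers_per_population = 10L, sibling_pairs = list(),
    split_populations = 2L, seed = 5L))
  labels <- split_clusters(sim, seed = 6L)
  data <- labeled_dataset(sim$counts, labels, sim$truth)
  res <- run_ao_pipeline(data, n_markers = 10, m_shuffles = 200, seed = 7)
  k <- length(unique(labels))
  expect_identical(as.character(merge_to_k(labels, res$tree, k)), labels)
  expect_length(unique(merge_to_k(labels, res$tree, 1)), 1L)
  expect_error(merge_to_k(labels, res$tree, 0), "k must lie")
  # first merged pair is an argmax of the z-score matrix
  m1 <- res$tree$merges[1, ]
  z <- res$ao$zscore
  diag(z) <- -Inf
  expect_equal(res$ao$zscore[m1$a, m1$b], max(z))
  # partitions refine as k decreases; cells never change count
  for (kk in k:2) {
    fine <- merge_to_k(labels, res$tree, kk)
    coarse <- merge_to_k(labels, res$tree, kk - 1)
    expect_length(fine, length(labels))
    tab <- table(fine, coarse)
    expect_true(all(rowSums(tab > 0) == 1))  # each fine group in one coarse
  }
  # merging to the truth count reunites the split population
  merged <- merge_to_k(labels, res$tree, 4, ao = res$ao)
  expect_equal(unname(agreement_metrics(sim$truth, merged)["ari"]), 1)
  log <- attr(merged, "merge_log")
  expect_identical(sort(c(log$merged_a[1], log$merged_b[1])),
                   c("P2a", "P2b"))
  expect_true(all(is.finite(log$zscore)))
})

test_that("cutting the fixed tree equals stepwise nearest-pair merging", {
  for (seed in 1:5) {
    d <- random_distance(6, seed + 500)
    tree <- linkage_from_distance(d, "average")
    labels <- rep(rownames(d), each = 2)
    for (k in c(4, 2)) {
      via_cut <- unname(cut_tree_k(tree, k)[labels])
      via_merge <- as.character(merge_to_k(labels, tree, k))
      expect_identical(via_cut, via_merge)
    }
  }
})

test_that("recomputing merging agrees with the fixed tree when separation is clear", {
  sim <- simulate_dataset(simulation_config(
    n_populations = 3L, cells_per_population = 40L, n_genes = 300L,
    markers_per_population = 10L, sibling_pairs = list(),
    split_populations = 1L, seed = 11L))
  labels <- split_clusters(sim, seed = 12L)
  data <- labeled_dataset(sim$counts, labels, sim$truth)
  res <- run_ao_pipeline(data, n_markers = 10, k_target = 3,
                         m_shuffles = 200, seed = 13)
  rec <- merge_with_recompute(data, 3, n_markers = 10, m_shuffles = 200,
                              seed = 13)
  expect_identical(as.character(merge_with_recompute(data,
                                                     length(unique(labels)),
                                                     n_markers = 10)),
                   labels)
  expect_equal(unname(agreement_metrics(res$merged_labels, rec)["ari"]), 1)
})

test_that("Newick export round-trips through ape with the right shape", {
  ao <- pairwise_ao(list(A = c("g1", "g2", "g3"), B = c("g2", "g1", "g3")),
                    m_shuffles = 50, seed = 1)
  two <- linkage_from_ao(ao)
  h <- format(two$merges$height[1], digits = 10)
  expect_identical(to_newick(two), sprintf("(A:%s,B:%s);", h, h))
  # 4-leaf caterpillar: chained merges
  d <- matrix(c(0, 1, 4, 8,
                1, 0, 4, 8,
                4, 4, 0, 8,
                8, 8, 8, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  cat_tree <- linkage_from_distance(d, "complete")
  # children are ordered lexicographically by merged label, so the merged
  # (A+B, C) node precedes leaf D
  expect_identical(to_newick(cat_tree, digits = 4),
                   "(((A:1,B:1):3,C:4):4,D:8);")
  # topology round-trip via an independent Newick parser
  for (seed in 1:5) {
    tree <- linkage_from_distance(random_distance(6, seed + 900), "average")
    phy <- ape::read.tree(text = to_newick(tree))
    expect_identical(sort(phy$tip.label), sort(tree$leaf_ids))
    ref <- ape::as.phylo(as.hclust(tree))
    expect_equal(ape::dist.topo(ape::unroot(phy), ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
    # ultrametric layout: leaf depths all equal the root height
    depths <- ape::node.depth.edgelength(phy)[seq_along(phy$tip.label)]
    expect_equal(depths, rep(max(tree$height), 6), tolerance = 1e-9)
  }
})
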