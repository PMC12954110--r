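test_that("agreement metrics hit the textbook anchor points", {
  truth <- rep(c("x", "y"), each = 10)
  expect_equal(unname(agreement_metrics(truth, truth)),
               c(1, 1, 1))
  relabeled <- ifelse(truth == "x", "q", "p")
  expect_equal(unname(agreement_metrics(truth, relabeled)), c(1, 1, 1))
  # one predicted cluster over balanced truth: chance-adjusted indices ~ 0
  one <- rep("all", 20)
  m <- agreement_metrics(truth, one)
  expect_equal(unname(m["ari"]), 0)
  expect_equal(unname(m["ami"]), 0, tolerance = 1e-12)
  expect_error(agreement_metrics(truth, one[-1]), "equal length")
})

test_that("the 6-cell toy matches exhaustive pair counting", {
  truth <- c("A", "A", "B", "B", "B", "C")
  pred <- c("1", "1", "2", "2", "3", "3")
  m <- agreement_metrics(truth, pred)
  expect_equal(unname(m["ari"]), ari_brute(truth, pred), tolerance = 1e-12)
  expect_equal(unname(m["fms"]), fms_brute(truth, pred), tolerance = 1e-12)
  expect_equal(unname(m["ami"]), ami_brute(truth, pred), tolerance = 1e-12)
})

test_that("agreement metrics match brute force on random partitions", {
  set.seed(31)
  for (rep in 1:30) {
    n <- sample(6:30, 1)
    truth <- sample(letters[1:sample(2:5, 1)], n, replace = TRUE)
    pred <- sample(LETTERS[1:sample(2:5, 1)], n, replace = TRUE)
    # regenerate until both label sets are non-trivial
    m <- agreement_metrics(truth, pred)
    expect_equal(unname(m["ari"]), ari_brute(truth, pred),
                 tolerance = 1e-12)
    expect_equal(unname(m["fms"]), fms_brute(truth, pred),
                 tolerance = 1e-12)
    expect_equal(unname(m["ami"]), ami_brute(truth, pred),
                 tolerance = 1e-10)
    expect_equal(unname(m["ari"]),
                 mclust::adjustedRandIndex(truth, pred), tolerance = 1e-12)
  }
})

test_that("random labelings of many cells score near zero", {
  set.seed(17)
  truth <- sample(letters[1:5], 600, replace = TRUE)
  pred <- sample(LETTERS[1:7], 600, replace = TRUE)
  m <- agreement_metrics(truth, pred)
  expect_lt(abs(m["ari"]), 0.05)
  expect_lt(abs(m["ami"]), 0.05)
})

test_that("purity covers the worked examples and the refinement property", {
  truth <- c("A", "A", "A", "B")
  expect_equal(average_cluster_purity(truth, rep("c1", 4)), 0.75)
  truth2 <- c(rep("A", 3), "B", rep("C", 6))
  pred2 <- c(rep("c1", 4), rep("c2", 6))
  expect_equal(average_cluster_purity(truth2, pred2), 0.9)  # (3 + 6)/10
  expect_equal(average_cluster_purity(truth2, pred2, weighted = FALSE),
               mean(c(0.75, 1)))
  # purity 1 iff prediction refines truth; splitting never lowers it
  set.seed(23)
  truth3 <- sample(c("A", "B"), 40, replace = TRUE)
  pred3 <- truth3
  expect_equal(average_cluster_purity(truth3, pred3), 1)
  split <- pred3
  split[sample(which(pred3 == "A"), 5)] <- "A2"
  expect_equal(average_cluster_purity(truth3, split), 1)
  noisy <- pred3
  noisy[1:5] <- "B"
  p0 <- average_cluster_purity(truth3, noisy)
  expect_lt(p0, 1)
  finer <- noisy
  finer[sample(which(noisy == "B"), 6)] <- "B2"
  expect_gte(average_cluster_purity(truth3, finer), p0)
})

test_that("centroid distances vanish on perfect recovery", {
  ds <- toy_dataset(n_per = 8)
  res <- centroid_expression_distance(ds, ds$truth)
  expect_equal(unname(res$per_cluster), c(0, 0))
  expect_equal(res$mean, 0)
  # a cluster equal to one truth population keeps distance 0 even if the
  # other is corrupted
  pred <- ds$truth
  pred[pred == "B"] <- sample(c("B", "C"), sum(pred == "B"), replace = TRUE)
  res2 <- centroid_expression_distance(ds, pred)
  expect_equal(unname(res2$per_cluster["A"]), 0)
})

test_that("centroid distances equal hand arithmetic on a mislabeled cell", {
  counts <- rbind(c(9, 1, 5), c(10, 2, 4), c(1, 9, 5), c(2, 10, 6),
                  c(1, 10, 4), c(2, 9, 6))
  colnames(counts) <- c("g1", "g2", "g3")
  truth <- c("A", "A", "B", "B", "B", "B")
  pred <- c("A", "B", "B", "B", "B", "B")  # cell 2 mislabeled
  ds <- labeled_dataset(counts, truth, truth)
  z <- scale(lognormalize(ds))
  cent <- function(rows) colMeans(z[rows, , drop = FALSE])
  expected <- c(A = sqrt(sum((cent(1) - cent(1:2))^2)),
                B = sqrt(sum((cent(2:6) - cent(3:6))^2)))
  res <- centroid_expression_distance(ds, pred)
  expect_equal(res$per_cluster, expected, tolerance = 1e-12)
  expect_equal(res$mean, mean(expected), tolerance = 1e-12)
})

test_that("baseline distances match naive per-pair computation", {
  ds <- toy_dataset(n_per = 8)
  tables <- rank_all_clusters(ds)
  normed <- lognormalize(ds)
  union <- top_k_union(tables, 4)
  feat <- t(vapply(names(tables), function(id)
    colMeans(normed[ds$cluster == id, union, drop = FALSE]),
    numeric(length(union))))
  for (metric in c("pearson", "spearman", "kendall")) {
    d <- baseline_distance_matrix(ds, tables, metric, n_markers = 4)
    expect_equal(d["A", "B"],
                 1 - cor(feat["A", ], feat["B", ], method = metric),
                 tolerance = 1e-12)
    expect_equal(diag(d), c(A = 0, B = 0))
  }
  d_euc <- baseline_distance_matrix(ds, tables, "euclidean", n_markers = 4)
  expect_equal(d_euc["A", "B"], sqrt(sum((feat["A", ] - feat["B", ])^2)),
               tolerance = 1e-12)
  d_ov <- baseline_distance_matrix(ds, tables, "direct_overlap",
                                   n_markers = 4)
  expect_equal(d_ov["A", "B"],
               1 - length(intersect(tables$A$gene[1:4],
                                    tables$B$gene[1:4])) / 4,
               tolerance = 1e-12)
  d_ao <- baseline_distance_matrix(ds, tables, "ao", n_markers = 4)
  rk <- rankings_on_union(tables, union)
  expect_equal(d_ao["A", "B"], 1 - ao_brute(rk$A, rk$B), tolerance = 1e-12)
  expect_error(baseline_distance_matrix(ds, tables, "cosine"))
})

test_that("identical centroids give zero correlation/Euclidean distance", {
  counts <- matrix(rep(c(5, 1, 3, 7), each = 8), nrow = 8)
  colnames(counts) <- paste0("g", 1:4)
  ds <- labeled_dataset(counts, rep(c("A", "B"), 4))
  tables <- rank_all_clusters(ds)
  for (metric in c("pearson", "spearman", "euclidean")) {
    d <- baseline_distance_matrix(ds, tables, metric, n_markers = 2)
    expect_equal(d["A", "B"], 0, tolerance = 1e-12)
  }
  # disjoint top-k sets -> direct-overlap distance 1
  ds2 <- toy_dataset(n_per = 6)
  tb2 <- rank_all_clusters(ds2)
  d2 <- baseline_distance_matrix(ds2, tb2, "direct_overlap", n_markers = 1)
  expect_equal(d2["A", "B"], 1)
})

test_that("principal-component features produce valid distance matrices", {
  sim <- simulate_dataset(simulation_config(
    n_populations = 3L, cells_per_population = 20L, n_genes = 150L,
    markers_per_population = 8L, sibling_pairs = list(),
    split_populations = integer(0), seed = 41L))
  tables <- rank_all_clusters(sim)
  d <- baseline_distance_matrix(sim, tables, "pearson",
                                features = "principal_components",
                                n_pcs = 10)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_true(all(d[upper.tri(d)] > 0))
})

test_that("Stouffer combination follows sum/sqrt(n)", {
  expect_equal(stouffer_composite(c(0, 0, 0)), 0)
  expect_equal(stouffer_composite(2.5), 2.5)
  expect_equal(stouffer_composite(c(1, 1, 1, 1)), 2)
  expect_error(stouffer_composite(numeric(0)), "at least one")
})

test_that("reference composite-z profiles match hand arithmetic", {
  ref <- rbind(g1 = c(10, 2, 2, 2),
               g2 = c(8, 8, 2, 2),
               g3 = c(1, 1, 1, 9),
               flat = c(3, 3, 3, 3))
  colnames(ref) <- paste0("pop", 1:4)
  expect_warning(
    prof <- score_marker_set_on_reference(c("g1", "g2", "g3"), ref),
    "constant")
  z <- t(apply(ref[1:3, ], 1, function(v) (v - mean(v)) / sd(v)))
  expect_equal(prof, colSums(z) / sqrt(3), tolerance = 1e-12)
  # single-gene set: profile is that gene's z-scored row
  expect_warning(one <- score_marker_set_on_reference("g1", ref))
  expect_equal(one, z["g1", ], tolerance = 1e-12)
  expect_error(suppressWarnings(
    score_marker_set_on_reference("nope", ref)), "no marker genes")
})
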