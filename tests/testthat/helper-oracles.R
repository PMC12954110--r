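# Independent brute-force oracles, deliberately written with the most
# naive algorithms available so they share no code path with the package.

# AO as a literal loop over depths with set intersection.
ao_brute <- function(a, b) {
  n <- length(a)
  stopifnot(length(b) == n)
  mean(vapply(seq_len(n), function(d) {
    length(intersect(a[seq_len(d)], b[seq_len(d)])) / d
  }, numeric(1)))
}

# ARI and FMS from exhaustive enumeration of all cell pairs.
pair_classify <- function(truth, pred) {
  n <- length(truth)
  tp <- fp <- fn <- tn <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      same_t <- truth[i] == truth[j]
      same_p <- pred[i] == pred[j]
      if (same_t && same_p) tp <- tp + 1
      else if (!same_t && same_p) fp <- fp + 1
      else if (same_t && !same_p) fn <- fn + 1
      else tn <- tn + 1
    }
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

ari_brute <- function(truth, pred) {
  pc <- pair_classify(truth, pred)
  n_pairs <- sum(pc)
  sum_ij <- pc["tp"]
  sum_a <- pc["tp"] + pc["fn"]   # same-truth pairs
  sum_b <- pc["tp"] + pc["fp"]   # same-pred pairs
  expected <- sum_a * sum_b / n_pairs
  denom <- (sum_a + sum_b) / 2 - expected
  if (abs(denom) < 1e-15) return(1)
  unname((sum_ij - expected) / denom)
}

fms_brute <- function(truth, pred) {
  pc <- pair_classify(truth, pred)
  unname(pc["tp"] / sqrt((pc["tp"] + pc["fp"]) * (pc["tp"] + pc["fn"])))
}

# AMI via naive loops; the hypergeometric weights come from stats::dhyper
# rather than the package's lgamma expression.
ami_brute <- function(truth, pred) {
  tab <- table(truth, pred)
  n <- sum(tab)
  a <- rowSums(tab)
  b <- colSums(tab)
  ent <- function(cnt) {
    p <- cnt[cnt > 0] / sum(cnt)
    -sum(p * log(p))
  }
  hu <- ent(a); hv <- ent(b)
  if (hu == 0 && hv == 0) return(1)
  mi <- 0
  for (i in seq_along(a)) for (j in seq_along(b)) {
    nij <- tab[i, j]
    if (nij > 0) mi <- mi + nij / n * log(n * nij / (a[i] * b[j]))
  }
  emi <- 0
  for (i in seq_along(a)) for (j in seq_along(b)) {
    for (nij in seq(max(1, a[i] + b[j] - n), min(a[i], b[j]))) {
      p <- stats::dhyper(nij, a[i], n - a[i], b[j])
      emi <- emi + p * nij / n * log(n * nij / (a[i] * b[j]))
    }
  }
  denom <- (hu + hv) / 2 - emi
  if (abs(denom) < 1e-15) return(1)
  unname((mi - emi) / denom)
}

# Exact two-sample rank-sum z via direct U-statistic enumeration over all
# (x, y) value pairs, with the tie-corrected normal variance.
wilcox_z_brute <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) {
    u <- u + (xi > yj) + 0.5 * (xi == yj)
  }
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  t <- table(c(x, y))
  sig2 <- n1 * n2 / 12 * ((n + 1) - sum(t^3 - t) / (n * (n - 1)))
  if (sig2 <= 0) return(0)
  (u - n1 * n2 / 2) / sqrt(sig2)
}

# Partition of tree leaves at k groups, replaying the recorded merges.
tree_partition <- function(tree, k) {
  g <- aoclust::cut_tree_k(tree, k)
  # canonical form: map group labels to the sorted leaf sets they contain
  split(names(g), unname(g))
}

same_partition <- function(p1, p2) {
  norm <- function(p) {
    s <- lapply(p, sort)
    s[order(vapply(s, paste, character(1), collapse = "|"))]
  }
  identical(unname(norm(p1)), unname(norm(p2)))
}

# A tiny deterministic two-population dataset for marker/evaluation tests.
toy_dataset <- function(n_per = 6L, seed = 42L) {
  set.seed(seed)
  counts <- matrix(rpois(2 * n_per * 6, lambda = 5), ncol = 6,
                   dimnames = list(NULL, paste0("g", 1:6)))
  counts[seq_len(n_per), 1] <- counts[seq_len(n_per), 1] + 30      # g1 up in A
  counts[seq_len(n_per) + n_per, 2] <- counts[seq_len(n_per) + n_per, 2] + 30
  labeled_dataset(counts, rep(c("A", "B"), each = n_per),
                  rep(c("A", "B"), each = n_per))
}
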