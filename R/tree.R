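#' @rdname linkage_from_ao
#' @param d symmetric distance matrix with zero diagonal (dimnames give the
#'   cluster identifiers).
#' @export
linkage_from_distance <- function(d, method = c("average", "complete",
                                                "single")) {
  method <- match.arg(method)
  d <- as.matrix(d)
  k <- nrow(d)
  if (k < 2L) stop("need at least 2 clusters to build a tree", call. = FALSE)
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- sprintf("C%d", seq_len(k))
  }
  if (!isTRUE(all.equal(d, t(d))) || any(diag(d) != 0)) {
    stop("distance matrix must be symmetric with zero diagonal",
         call. = FALSE)
  }
  leaf_ids <- rownames(d)

  ## Naive agglomeration with Lance-Williams updates; among tied minimum
  ## distances the pair whose sorted (label_a, label_b) is lexicographically
  ## smallest is merged, making the tree deterministic across platforms.
  active <- seq_len(k)
  labels <- leaf_ids            # current label of each active node
  sizes <- rep(1L, k)
  members <- as.list(seq_len(k))        # leaf indices under each node
  node_idx <- -seq_len(k)               # hclust convention: leaves negative
  merge <- matrix(0L, k - 1L, 2L)
  height <- numeric(k - 1L)
  merges <- vector("list", k - 1L)
  work <- d

  for (step in seq_len(k - 1L)) {
    na <- length(active)
    best <- NULL
    best_d <- Inf
    for (i in seq_len(na - 1L)) {
      for (j in seq(i + 1L, na)) {
        dij <- work[i, j]
        pair <- sort(c(labels[i], labels[j]))
        if (dij < best_d - 1e-15 ||
            (abs(dij - best_d) <= 1e-15 && !is.null(best) &&
             (pair[1L] < best$pair[1L] ||
              (pair[1L] == best$pair[1L] && pair[2L] < best$pair[2L])))) {
          best <- list(i = i, j = j, pair = pair)
          best_d <- dij
        }
      }
    }
    i <- best$i; j <- best$j
    h <- work[i, j]
    new_label <- paste(best$pair, collapse = "+")
    merges[[step]] <- data.frame(
      step = step, a = best$pair[1L], b = best$pair[2L], height = h,
      node = new_label, stringsAsFactors = FALSE)
    ## child with the lexicographically smaller label first
    merge[step, ] <- if (labels[i] == best$pair[1L]) {
      c(node_idx[i], node_idx[j])
    } else {
      c(node_idx[j], node_idx[i])
    }
    height[step] <- h
    ## Lance-Williams distance of the merged node to every other node
    others <- setdiff(seq_len(na), c(i, j))
    dnew <- vapply(others, function(o) {
      switch(method,
             average = (sizes[i] * work[i, o] + sizes[j] * work[j, o]) /
               (sizes[i] + sizes[j]),
             complete = max(work[i, o], work[j, o]),
             single = min(work[i, o], work[j, o]))
    }, numeric(1))
    keep <- c(others, i)
    work <- work[keep, keep, drop = FALSE]
    ni <- length(others) + 1L
    work[ni, seq_along(others)] <- dnew
    work[seq_along(others), ni] <- dnew
    work[ni, ni] <- 0
    labels <- c(labels[others], new_label)
    sizes <- c(sizes[others], sizes[i] + sizes[j])
    members <- c(members[others], list(sort(c(members[[i]], members[[j]]))))
    node_idx <- c(node_idx[others], step)
    active <- seq_len(ni)
  }

  structure(
    list(leaf_ids = leaf_ids, method = method,
         merges = do.call(rbind, merges),
         merge = merge, height = height),
    class = "cluster_tree"
  )
}

#' Hierarchical clustering of clusters from AO similarities
#'
#' Agglomerates single-cell clusters on the distance `1 - AO` (high overlap
#' means low distance). The default average linkage (UPGMA) is monotone, so
#' merge heights are non-decreasing. Because every pairwise z-score shares
#' one null, the first merged pair is always the pair with the highest AO
#' z-score.
#'
#' @param ao an `"ao_matrix"` from [pairwise_ao()].
#' @param method linkage: `"average"` (default), `"complete"` or `"single"`.
#' @return an object of class `"cluster_tree"`: merge table
#'   (`step`, `a`, `b`, `height`, `node`), hclust-style `merge`/`height`
#'   encodings and the leaf identifiers.
#' @export
linkage_from_ao <- function(ao, method = c("average", "complete", "single")) {
  stopifnot(inherits(ao, "ao_matrix"))
  d <- 1 - ao$similarity
  diag(d) <- 0
  linkage_from_distance(d, match.arg(method))
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat("Cluster tree over", length(x$leaf_ids), "leaves (", x$method,
      "linkage)\n")
  print(x$merges, row.names = FALSE)
  invisible(x)
}

## Leaf ordering compatible with the merge matrix (for as.hclust).
tree_order <- function(merge) {
  walk <- function(node) {
    if (node < 0L) return(-node)
    c(walk(merge[node, 1L]), walk(merge[node, 2L]))
  }
  walk(nrow(merge))
}

#' @export
as.hclust.cluster_tree <- function(x, ...) {
  structure(
    list(merge = x$merge, height = x$height, order = tree_order(x$merge),
         labels = x$leaf_ids, method = x$method,
         call = match.call(), dist.method = "1 - AO"),
    class = "hclust"
  )
}

#' Group membership after the first `K - k` merges
#'
#' Replays the tree's merge order until `k` groups remain; each original
#' cluster maps to a merged group whose label concatenates its members.
#'
#' @param tree a `"cluster_tree"`.
#' @param k target number of groups, `1 <= k <= K`.
#' @return named character vector: original cluster id -> merged group
#'   label.
#' @export
cut_tree_k <- function(tree, k) {
  stopifnot(inherits(tree, "cluster_tree"))
  n <- length(tree$leaf_ids)
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > n) {
    stop("k must lie in [1, ", n, "]", call. = FALSE)
  }
  group <- stats::setNames(tree$leaf_ids, tree$leaf_ids)
  n_steps <- n - k
  for (s in seq_len(n_steps)) {
    m <- tree$merges[s, ]
    group[group %in% c(m$a, m$b)] <- m$node
  }
  group
}

#' Merge per-cell cluster labels down to a target count
#'
#' Iteratively merges the currently most similar cluster pair — the pair
#' with the highest AO z-score, following the fixed tree's merge order —
#' until `k_target` groups remain. Every cell keeps its membership; a merged
#' group's label concatenates its member labels.
#'
#' @param labels per-cell cluster labels (must match the tree's leaves).
#' @param tree a `"cluster_tree"` built on those clusters.
#' @param ao optional `"ao_matrix"`; when supplied, the returned labels
#'   carry a `"merge_log"` attribute recording each merged pair's AO and
#'   z-score.
#' @param k_target number of groups to keep, `1 <= k_target <= K`.
#' @return character vector of merged per-cell labels, with attribute
#'   `"merge_log"` (a data frame: step, merged_a, merged_b, ao, zscore).
#' @export
merge_to_k <- function(labels, tree, k_target, ao = NULL) {
  stopifnot(inherits(tree, "cluster_tree"))
  labels <- as.character(labels)
  if (!all(labels %in% tree$leaf_ids)) {
    stop("labels contain clusters absent from the tree", call. = FALSE)
  }
  group <- cut_tree_k(tree, k_target)
  n_steps <- length(tree$leaf_ids) - as.integer(k_target)
  log <- if (n_steps > 0L) {
    m <- tree$merges[seq_len(n_steps), , drop = FALSE]
    data.frame(step = m$step, merged_a = m$a, merged_b = m$b,
               ao = if (is.null(ao)) NA_real_ else
                 vapply(seq_len(nrow(m)), function(s)
                   pair_ao_value(ao, m$a[s], m$b[s]), numeric(1)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(step = integer(), merged_a = character(),
               merged_b = character(), ao = numeric())
  }
  log$zscore <- if (!is.null(ao) && nrow(log) > 0L) {
    ao_zscore(log$ao, ao$null)
  } else {
    rep(NA_real_, nrow(log))
  }
  structure(unname(group[labels]), merge_log = log)
}

## AO between two (possibly merged) groups: for merged nodes, the average
## of the member-pair similarities, consistent with average linkage.
pair_ao_value <- function(ao, a, b) {
  ma <- strsplit(a, "+", fixed = TRUE)[[1L]]
  mb <- strsplit(b, "+", fixed = TRUE)[[1L]]
  mean(ao$similarity[ma, mb, drop = FALSE])
}

#' Merge clusters with full recomputation after every step
#'
#' A stricter variant of [merge_to_k()]: after each single merge the marker
#' tables, top-k union, AO matrix and the next best pair are recomputed from
#' the data, instead of following a fixed tree.
#'
#' @param data a `"labeled_dataset"`.
#' @param k_target number of groups to keep.
#' @param n_markers top marker genes per cluster for the union (default 25).
#' @param m_shuffles,seed null-model parameters (see [null_distribution()]).
#' @return character vector of merged per-cell labels with a `"merge_log"`
#'   attribute.
#' @export
merge_with_recompute <- function(data, k_target, n_markers = 25L,
                                 m_shuffles = 1000L, seed = 1L) {
  stopifnot(inherits(data, "labeled_dataset"))
  labels <- data$cluster
  k <- length(unique(labels))
  k_target <- as.integer(k_target)
  if (is.na(k_target) || k_target < 1L || k_target > k) {
    stop("k_target must lie in [1, ", k, "]", call. = FALSE)
  }
  log <- list()
  step <- 0L
  while (length(unique(labels)) > k_target) {
    step <- step + 1L
    cur <- labeled_dataset(data$counts, labels, data$truth)
    tables <- rank_all_clusters(cur)
    union <- top_k_union(tables, min(n_markers, ncol(data$counts)))
    rankings <- rankings_on_union(tables, union)
    ao <- pairwise_ao(rankings, m_shuffles = m_shuffles, seed = seed)
    sim <- ao$similarity
    diag(sim) <- -Inf
    ids <- rownames(sim)
    best <- NULL
    for (i in seq_len(nrow(sim) - 1L)) {
      for (j in seq(i + 1L, ncol(sim))) {
        pair <- sort(c(ids[i], ids[j]))
        if (is.null(best) || sim[i, j] > best$s + 1e-15 ||
            (abs(sim[i, j] - best$s) <= 1e-15 &&
             (pair[1L] < best$pair[1L] ||
              (pair[1L] == best$pair[1L] && pair[2L] < best$pair[2L])))) {
          best <- list(s = sim[i, j], pair = pair)
        }
      }
    }
    new_label <- paste(best$pair, collapse = "+")
    log[[step]] <- data.frame(step = step, merged_a = best$pair[1L],
                              merged_b = best$pair[2L], ao = best$s,
                              zscore = ao_zscore(best$s, ao$null),
                              stringsAsFactors = FALSE)
    labels[labels %in% best$pair] <- new_label
  }
  structure(labels,
            merge_log = if (length(log)) do.call(rbind, log) else
              data.frame(step = integer(), merged_a = character(),
                         merged_b = character(), ao = numeric(),
                         zscore = numeric()))
}

#' Export a cluster tree as a Newick string
#'
#' Leaves sit at height zero; each branch length is the difference between
#' the parent merge height and the child's height, so leaf-to-root path
#' lengths equal the root merge height (ultrametric layout). Label
#' characters unsafe in Newick are replaced by `_`.
#'
#' @param tree a `"cluster_tree"`.
#' @param digits significant digits for branch lengths.
#' @return a single Newick string, terminated by `;`.
#' @export
to_newick <- function(tree, digits = 10) {
  stopifnot(inherits(tree, "cluster_tree"))
  safe <- function(x) gsub("[,:;()\\[\\]\\s]", "_", x, perl = TRUE)
  node_height <- function(node) if (node < 0L) 0 else tree$height[node]
  fmt <- function(x) format(x, digits = digits, scientific = FALSE, trim = TRUE)
  render <- function(node, parent_h) {
    h <- node_height(node)
    bl <- fmt(max(parent_h - h, 0))
    if (node < 0L) {
      paste0(safe(tree$leaf_ids[-node]), ":", bl)
    } else {
      paste0("(", render(tree$merge[node, 1L], h), ",",
             render(tree$merge[node, 2L], h), "):", bl)
    }
  }
  root <- nrow(tree$merge)
  h <- tree$height[root]
  paste0("(", render(tree$merge[root, 1L], h), ",",
         render(tree$merge[root, 2L], h), ");")
}
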