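#' Overlap of two ranked lists at a fixed depth
#'
#' The overlap at depth `d` is the size of the intersection of the two lists'
#' top-`d` elements divided by `d`.
#'
#' @param a,b ranked lists (character vectors of distinct gene identifiers).
#' @param d evaluation depth, `1 <= d <= min(length(a), length(b))`.
#' @return a fraction in `[0, 1]`.
#' @examples
#' overlap_at_depth(c("G1", "G2", "G3"), c("G2", "G1", "G3"), 2)  # 1
#' @export
overlap_at_depth <- function(a, b, d) {
  a <- as_ranked_list(a)
  b <- as_ranked_list(b)
  d <- as.integer(d)
  if (length(d) != 1L || is.na(d) || d < 1L || d > min(length(a), length(b))) {
    stop("depth d must satisfy 1 <= d <= min(length(a), length(b))",
         call. = FALSE)
  }
  length(intersect(a[seq_len(d)], b[seq_len(d)])) / d
}

## Cumulative overlap counts |top-d(a) & top-d(b)| for d = 1..N in O(N):
## gene at position j of `a` sits at position pb[j] of `b` (NA if absent),
## and enters the intersection at depth max(j, pb[j]).
overlap_profile <- function(a, b) {
  n <- length(a)
  pb <- match(a, b)
  entry <- pmax(seq_len(n), pb)
  entry <- entry[!is.na(entry) & entry <= n]
  cumsum(tabulate(entry, nbins = n))
}

#' Average overlap between two ranked lists
#'
#' The average overlap (AO) is the mean of [overlap_at_depth()] over all
#' depths `d = 1..N` of two equal-length ranked lists. It is top-weighted:
#' an element near the head of the lists participates in many depths, so
#' discordance there costs more than discordance near the tail. AO ranges
#' from 0 (no shared content) to 1 (element-wise identical lists).
#'
#' @param a,b ranked lists of equal length.
#' @return AO similarity in `[0, 1]`.
#' @examples
#' average_overlap(c("G1", "G2", "G3"), c("G2", "G1", "G3"))  # 2/3
#' average_overlap(c("A", "B"), c("C", "D"))                  # 0
#' @export
average_overlap <- function(a, b) {
  a <- as_ranked_list(a)
  b <- as_ranked_list(b)
  if (length(a) != length(b)) {
    stop("ranked lists must have equal length (got ", length(a), " and ",
         length(b), ")", call. = FALSE)
  }
  n <- length(a)
  mean(overlap_profile(a, b) / seq_len(n))
}

#' Average-overlap distance
#'
#' `1 - average_overlap(a, b)`; zero if and only if the two lists are
#' element-wise identical. This is the dissimilarity used for hierarchical
#' clustering of single-cell clusters.
#'
#' @inheritParams average_overlap
#' @return distance in `[0, 1]`.
#' @export
ao_distance <- function(a, b) {
  1 - average_overlap(a, b)
}

## Evaluate expr under a temporary RNG state seeded with `seed`,
## restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## AO between two integer permutations of 1..n (content-agnostic fast path).
ao_perm <- function(pa, pb) {
  n <- length(pa)
  pos_b <- integer(n)
  pos_b[pb] <- seq_len(n)
  entry <- pmax(seq_len(n), pos_b[pa])
  mean(cumsum(tabulate(entry, nbins = n)) / seq_len(n))
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow = nrow(sub)))
  }))
}

#' Calibrate the AO shuffle null for a given list length
#'
#' Over uniformly random permutation pairs of an `n`-element universe, AO is
#' approximately normal with mean `(n + 1) / (2 n)` (close to 0.5 for long
#' lists). This function estimates that null mean and standard deviation by
#' Monte Carlo, or exhaustively for small `n`, so observed AO values can be
#' expressed as z-scores.
#'
#' @param n list length (>= 2).
#' @param m_shuffles number of random permutation pairs to draw (>= 2).
#' @param seed integer RNG seed; the same `(n, m_shuffles, seed)` always
#'   yields the same model.
#' @param exhaustive if `TRUE`, enumerate all `n!` relative orderings instead
#'   of sampling (allowed for `n <= 7`); `seed` is then ignored.
#' @return an object of class `"ao_null"` with fields `n`, `m`, `mean`, `sd`,
#'   `seed`, `exhaustive`.
#' @examples
#' null_distribution(3, exhaustive = TRUE)$mean  # 2/3 = (3 + 1) / (2 * 3)
#' @export
null_distribution <- function(n, m_shuffles = 1000L, seed = 1L,
                              exhaustive = FALSE) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) {
    stop("null model needs list length n >= 2 (sd undefined below that)",
         call. = FALSE)
  }
  if (exhaustive) {
    if (n > 7L) stop("exhaustive enumeration supported for n <= 7 only",
                     call. = FALSE)
    ## AO of (pa, pb) depends only on the relative ordering pb relative to pa,
    ## so enumerating all permutations against the identity covers the null.
    perms <- all_permutations(n)
    id <- seq_len(n)
    vals <- apply(perms, 1L, function(p) ao_perm(id, as.integer(p)))
    m <- nrow(perms)
  } else {
    m <- as.integer(m_shuffles)
    if (is.na(m) || m < 2L) stop("m_shuffles must be >= 2", call. = FALSE)
    vals <- with_seed(seed, vapply(seq_len(m), function(i) {
      ao_perm(sample.int(n), sample.int(n))
    }, numeric(1)))
  }
  structure(
    list(n = n, m = m, mean = mean(vals), sd = stats::sd(vals),
         seed = if (exhaustive) NA_integer_ else as.integer(seed),
         exhaustive = exhaustive),
    class = "ao_null"
  )
}

#' @export
print.ao_null <- function(x, ...) {
  cat(sprintf(
    "AO shuffle null: list length %d, %s%d draws, mean %.4f, sd %.4g\n",
    x$n, if (x$exhaustive) "exhaustive " else "", x$m, x$mean, x$sd))
  invisible(x)
}

#' AO z-score against a shuffle null
#'
#' Expresses an observed AO similarity in standard deviations of the shuffle
#' null: `(ao_value - null$mean) / null$sd`. Randomly shuffled lists score 0
#' on average, similarly ranked lists score increasingly positive.
#'
#' @param ao_value observed AO similarity (or a numeric vector/matrix of
#'   them).
#' @param null an `"ao_null"` from [null_distribution()].
#' @return z-scores with the same shape as `ao_value`.
#' @export
ao_zscore <- function(ao_value, null) {
  stopifnot(inherits(null, "ao_null"))
  if (!is.finite(null$sd) || null$sd <= 0) {
    stop("degenerate null model: sd must be positive", call. = FALSE)
  }
  (ao_value - null$mean) / null$sd
}

#' Pairwise AO similarity and z-score matrices between clusters
#'
#' Computes AO for every pair of per-cluster rankings over a common gene
#' universe, and the corresponding z-scores against a shuffle null of the
#' shared list length.
#'
#' @param rankings named list of equal-length ranked lists over the same
#'   gene universe (e.g. from [rankings_on_union()]).
#' @param null optional `"ao_null"` for the shared list length; built with
#'   defaults (`m_shuffles`, `seed`) when omitted.
#' @param m_shuffles,seed forwarded to [null_distribution()] when `null` is
#'   not supplied.
#' @return an object of class `"ao_matrix"`: list with `cluster_ids`,
#'   `similarity` (K x K, unit diagonal), `zscore` (K x K) and `null`.
#' @export
pairwise_ao <- function(rankings, null = NULL, m_shuffles = 1000L, seed = 1L) {
  stopifnot(is.list(rankings), length(rankings) >= 1L,
            !is.null(names(rankings)))
  rankings <- lapply(rankings, as_ranked_list)
  ids <- names(rankings)
  n <- length(rankings[[1L]])
  lens <- vapply(rankings, length, integer(1))
  if (any(lens != n)) {
    stop("all rankings must have the same length", call. = FALSE)
  }
  universe <- sort(unclass(rankings[[1L]]))
  for (r in rankings) {
    if (!identical(sort(unclass(r)), universe)) {
      stop("all rankings must cover the same gene universe", call. = FALSE)
    }
  }
  k <- length(rankings)
  sim <- matrix(1, k, k, dimnames = list(ids, ids))
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      for (j in seq(i + 1L, k)) {
        sim[i, j] <- sim[j, i] <- average_overlap(rankings[[i]],
                                                  rankings[[j]])
      }
    }
  }
  if (is.null(null)) {
    if (n < 2L) {
      stop("z-scores are unavailable for rankings of length 1 ",
           "(null sd undefined); supply longer rankings", call. = FALSE)
    }
    null <- null_distribution(n, m_shuffles = m_shuffles, seed = seed)
  }
  stopifnot(inherits(null, "ao_null"))
  if (null$n != n) {
    stop("null model was calibrated for length ", null$n,
         " but rankings have length ", n, call. = FALSE)
  }
  structure(
    list(cluster_ids = ids, similarity = sim,
         zscore = ao_zscore(sim, null), null = null),
    class = "ao_matrix"
  )
}

#' @export
print.ao_matrix <- function(x, digits = 3, ...) {
  cat("Pairwise AO over", length(x$cluster_ids), "clusters (list length",
      x$null$n, ")\nSimilarity:\n")
  print(round(x$similarity, digits))
  cat("z-scores (null mean ", round(x$null$mean, 4), ", sd ",
      signif(x$null$sd, 4), "):\n", sep = "")
  print(round(x$zscore, digits))
  invisible(x)
}

#' Write an AO matrix to CSV files
#'
#' Writes the similarity and z-score matrices as two CSV files with cluster
#' identifiers as header row and first column.
#'
#' @param ao an `"ao_matrix"`.
#' @param similarity_path,zscore_path output paths.
#' @return the two paths, invisibly.
#' @export
write_ao_matrix <- function(ao, similarity_path, zscore_path) {
  stopifnot(inherits(ao, "ao_matrix"))
  utils::write.csv(as.data.frame(ao$similarity), similarity_path)
  utils::write.csv(as.data.frame(ao$zscore), zscore_path)
  invisible(c(similarity_path, zscore_path))
}
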