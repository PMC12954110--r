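#' Construct a ranked gene list
#'
#' A ranked list is an ordered vector of distinct gene identifiers, most
#' significant first — one cluster's differential-expression ranking over a
#' shared gene universe. Most functions in the package accept plain character
#' vectors and validate them through this constructor.
#'
#' @param items character vector of gene identifiers, ordered from rank 1 down.
#' @return a character vector of class `"ranked_list"`.
#' @examples
#' ranked_list(c("Cd3e", "Lck", "Cd8a"))
#' @export
ranked_list <- function(items) {
  items <- as.character(items)
  if (length(items) < 1L) {
    stop("a ranked list must contain at least one gene", call. = FALSE)
  }
  if (anyNA(items)) {
    stop("ranked list contains NA gene identifiers", call. = FALSE)
  }
  if (anyDuplicated(items)) {
    dup <- items[duplicated(items)][1L]
    stop("ranked list items must be distinct (duplicated: ", dup, ")",
         call. = FALSE)
  }
  structure(items, class = "ranked_list")
}

as_ranked_list <- function(x) {
  if (inherits(x, "ranked_list")) x else ranked_list(x)
}

#' @export
print.ranked_list <- function(x, ...) {
  n <- length(x)
  shown <- utils::head(unclass(x), 8L)
  cat("Ranked list of ", n, " genes: ", paste(shown, collapse = " > "),
      if (n > 8L) " ..." else "", "\n", sep = "")
  invisible(x)
}

#' Read per-cluster rankings from a TSV file
#'
#' Expects columns `cluster_id`, `rank` (1-based) and `gene`. Every cluster
#' must have a complete rank sequence 1..N.
#'
#' @param path path to a tab-separated file with a header row.
#' @return named list of [ranked_list] objects, one per cluster.
#' @seealso [write_rankings()]
#' @export
read_rankings <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("cluster_id", "rank", "gene")
  if (!all(need %in% names(df))) {
    stop("rankings file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(split(df, df$cluster_id), function(d) {
    d <- d[order(d$rank), , drop = FALSE]
    if (!identical(as.integer(d$rank), seq_len(nrow(d)))) {
      stop("ranks for cluster ", d$cluster_id[1L],
           " are not a complete 1..N sequence", call. = FALSE)
    }
    ranked_list(d$gene)
  })
  out[order(names(out))]
}

#' Write per-cluster rankings to a TSV file
#'
#' @param rankings named list of ranked lists (or character vectors).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rankings <- function(rankings, path) {
  stopifnot(is.list(rankings), !is.null(names(rankings)))
  df <- do.call(rbind, lapply(names(rankings), function(id) {
    r <- as_ranked_list(rankings[[id]])
    data.frame(cluster_id = id, rank = seq_along(r), gene = unclass(r),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
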