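#' Configuration for the synthetic scRNA-seq generator
#'
#' Describes a multi-population negative-binomial count model with planted,
#' population-specific up-regulated marker blocks. Sibling pairs share a
#' fraction of their marker blocks with Gaussian jitter on the shared
#' markers' log effect sizes, so their differential-expression rankings
#' differ but overlap — the homogeneous, T-cell-subset-like regime the
#' average-overlap statistic is designed for. Named populations can be
#' split into two pseudo-clusters to emulate over-clustering at high
#' community-detection resolution.
#'
#' @param n_populations number of true populations.
#' @param cells_per_population cells in each population.
#' @param n_genes total genes; must accommodate all marker blocks.
#' @param markers_per_population size of each population's planted marker
#'   block.
#' @param log_fold_change natural-log effect size of planted markers (a
#'   marker's mean is multiplied by `exp(log_fold_change)` in its
#'   population).
#' @param nb_dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param library_size_mean,library_size_cv mean and coefficient of
#'   variation of per-cell library sizes (log-normal).
#' @param sibling_pairs list of `list(pop_a, pop_b, shared_marker_fraction,
#'   rank_jitter_sd)` entries (1-based population indices).
#' @param split_populations integer indices of populations to split into
#'   two pseudo-clusters.
#' @param seed integer RNG seed.
#' @return an object of class `"sim_config"`.
#' @export
simulation_config <- function(n_populations = 5L,
                              cells_per_population = 200L,
                              n_genes = 2000L,
                              markers_per_population = 40L,
                              log_fold_change = 2,
                              nb_dispersion = 0.3,
                              library_size_mean = 5000,
                              library_size_cv = 0.3,
                              sibling_pairs = list(
                                list(1L, 2L, 0.8, 0.5),
                                list(3L, 4L, 0.8, 0.5)),
                              split_populations = c(1L, 3L),
                              seed = 1L) {
  cfg <- list(n_populations = as.integer(n_populations),
              cells_per_population = as.integer(cells_per_population),
              n_genes = as.integer(n_genes),
              markers_per_population = as.integer(markers_per_population),
              log_fold_change = log_fold_change,
              nb_dispersion = nb_dispersion,
              library_size_mean = library_size_mean,
              library_size_cv = library_size_cv,
              sibling_pairs = sibling_pairs,
              split_populations = as.integer(split_populations),
              seed = as.integer(seed))
  if (cfg$markers_per_population * cfg$n_populations > cfg$n_genes) {
    stop("marker blocks do not fit: markers_per_population * n_populations ",
         "must be <= n_genes", call. = FALSE)
  }
  if (cfg$n_populations < 1L || cfg$cells_per_population < 2L ||
      cfg$n_genes < 1L || cfg$markers_per_population < 1L ||
      cfg$nb_dispersion <= 0 || cfg$library_size_mean <= 0 ||
      cfg$library_size_cv < 0) {
    stop("all counts must be positive (and >= 2 cells per population)",
         call. = FALSE)
  }
  for (sp in cfg$sibling_pairs) {
    if (length(sp) != 4L) {
      stop("each sibling pair is list(pop_a, pop_b, shared_marker_fraction,",
           " rank_jitter_sd)", call. = FALSE)
    }
    if (sp[[3]] < 0 || sp[[3]] > 1) {
      stop("shared_marker_fraction must lie in [0, 1]", call. = FALSE)
    }
    if (sp[[1]] < 1 || sp[[2]] > cfg$n_populations || sp[[1]] == sp[[2]]) {
      stop("sibling pair indices must name two distinct populations",
           call. = FALSE)
    }
  }
  if (any(cfg$split_populations < 1L |
          cfg$split_populations > cfg$n_populations)) {
    stop("split_populations out of range", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Canonical homogeneous sibling-population scenario
#'
#' A deliberately hard configuration emulating closely related cell
#' subsets (T-cell-like): weak marker effects (`log_fold_change = 0.3`,
#' about a 1.35-fold change), two sibling pairs sharing 90% of their
#' marker blocks with strong rank jitter, small populations (40 cells),
#' high negative-binomial dispersion and shallow libraries. Two
#' populations are split into pseudo-clusters. In this regime top-weighted
#' rank similarity remains stable while expression-correlation and small
#' direct-overlap baselines become noisy — the benchmark-shape test bed.
#'
#' @param seed integer RNG seed.
#' @return a `"sim_config"`.
#' @export
sibling_scenario <- function(seed = 1L) {
  simulation_config(n_populations = 5L,
                    cells_per_population = 40L,
                    n_genes = 1500L,
                    markers_per_population = 40L,
                    log_fold_change = 0.3,
                    nb_dispersion = 2,
                    library_size_mean = 1200,
                    library_size_cv = 0.3,
                    sibling_pairs = list(list(1L, 2L, 0.9, 0.8),
                                         list(3L, 4L, 0.9, 0.8)),
                    split_populations = c(1L, 3L),
                    seed = seed)
}

#' Simulate a truth-known scRNA-seq dataset
#'
#' Draws baseline gene abundances log-normal, per-cell library sizes
#' log-normal, and counts negative-binomial. Each population's marker block
#' mean is multiplied by `exp(log_fold_change)`; sibling pairs share
#' `shared_marker_fraction` of their blocks, with independent Gaussian
#' jitter (sd `rank_jitter_sd`) on the shared markers' log effects in each
#' sibling, so the siblings' marker rankings overlap without coinciding.
#' Identical config and seed give bit-identical output.
#'
#' @param config a `"sim_config"` from [simulation_config()].
#' @return a `"sim_dataset"`: a [labeled_dataset()] (cluster labels = truth
#'   populations `P1..Pk`) plus `planted_markers` (ordered marker genes per
#'   population) and the generating `config`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_seed(cfg$seed, {
    np <- cfg$n_populations
    nc <- np * cfg$cells_per_population
    ng <- cfg$n_genes
    genes <- sprintf("gene%04d", seq_len(ng))
    pops <- sprintf("P%d", seq_len(np))
    truth <- rep(pops, each = cfg$cells_per_population)

    base <- stats::rlnorm(ng, meanlog = 0, sdlog = 1)

    ## disjoint marker blocks, then sibling sharing overwrites the first
    ## shared_fraction of pop_b's block with pop_a's genes
    blocks <- split(seq_len(np * cfg$markers_per_population),
                    rep(seq_len(np), each = cfg$markers_per_population))
    marker_idx <- blocks
    log_eff <- lapply(seq_len(np), function(p)
      stats::setNames(rep(cfg$log_fold_change, cfg$markers_per_population),
                      genes[blocks[[p]]]))
    for (sp in cfg$sibling_pairs) {
      pa <- sp[[1]]; pb <- sp[[2]]
      n_shared <- round(sp[[3]] * cfg$markers_per_population)
      if (n_shared > 0) {
        shared <- blocks[[pa]][seq_len(n_shared)]
        marker_idx[[pb]] <- c(shared,
                              blocks[[pb]][seq_len(cfg$markers_per_population
                                                   - n_shared)])
        jit_a <- stats::rnorm(n_shared, 0, sp[[4]])
        jit_b <- stats::rnorm(n_shared, 0, sp[[4]])
        eff_a <- log_eff[[pa]]
        eff_a[genes[shared]] <- cfg$log_fold_change + jit_a
        log_eff[[pa]] <- eff_a
        log_eff[[pb]] <- stats::setNames(
          c(cfg$log_fold_change + jit_b,
            rep(cfg$log_fold_change,
                cfg$markers_per_population - n_shared)),
          genes[marker_idx[[pb]]])
      }
    }

    ## per-population expected relative abundances
    pop_weights <- lapply(seq_len(np), function(p) {
      w <- base
      idx <- marker_idx[[p]]
      w[idx] <- w[idx] * exp(log_eff[[p]][genes[idx]])
      w / sum(w)
    })

    sdlog <- sqrt(log(1 + cfg$library_size_cv^2))
    lib <- stats::rlnorm(nc, meanlog = log(cfg$library_size_mean) -
                           sdlog^2 / 2, sdlog = sdlog)

    counts <- matrix(0L, nc, ng, dimnames = list(
      sprintf("cell%05d", seq_len(nc)), genes))
    size <- 1 / cfg$nb_dispersion
    for (p in seq_len(np)) {
      rows <- which(truth == pops[p])
      mu <- outer(lib[rows], pop_weights[[p]])
      counts[rows, ] <- stats::rnbinom(length(mu), size = size, mu = mu)
    }

    planted <- lapply(seq_len(np), function(p) {
      ## ordered by planted log effect, strongest first
      idx <- marker_idx[[p]]
      g <- genes[idx]
      g[order(-log_eff[[p]][g], g)]
    })
    names(planted) <- pops

    ds <- labeled_dataset(counts, truth, truth)
    structure(list(counts = ds$counts, cluster = ds$cluster,
                   truth = ds$truth, planted_markers = planted,
                   config = cfg),
              class = c("sim_dataset", "labeled_dataset"))
  })
}

#' Split populations into pseudo-clusters
#'
#' Randomly halves each named population's cells into two pseudo-cluster
#' labels (`P1a`/`P1b` etc.), emulating over-clustering where highly
#' similar populations split into multiple groups. Truth labels are
#' untouched.
#'
#' @param data a `"sim_dataset"` (or any `"labeled_dataset"`).
#' @param populations labels of the clusters to split (default: the
#'   simulated config's `split_populations`); each needs >= 4 cells.
#' @param seed RNG seed for the random halving.
#' @return per-cell cluster label vector with `K + length(populations)`
#'   distinct labels.
#' @export
split_clusters <- function(data, populations = NULL, seed = 1L) {
  stopifnot(inherits(data, "labeled_dataset"))
  labels <- data$cluster
  if (is.null(populations)) {
    if (!inherits(data, "sim_dataset")) {
      stop("populations must be given for non-simulated data",
           call. = FALSE)
    }
    populations <- sprintf("P%d", data$config$split_populations)
  }
  if (length(populations) == 0L) return(labels)
  with_seed(seed, {
    for (p in as.character(populations)) {
      idx <- which(labels == p)
      if (length(idx) < 4L) {
        stop("population ", p, " has fewer than 4 cells; cannot split",
             call. = FALSE)
      }
      half <- sample(idx, floor(length(idx) / 2))
      labels[half] <- paste0(p, "a")
      labels[setdiff(idx, half)] <- paste0(p, "b")
    }
    labels
  })
}

#' Perturbed ranked-list fixture
#'
#' Returns an identity ranked list of length `n` together with a copy
#' perturbed by `n_swaps` random adjacent transpositions. AO between the
#' pair decreases stochastically with `n_swaps`; with a single swap at
#' position `i` it equals `1 - 1/(n * i)` exactly.
#'
#' @param n list length (>= 2).
#' @param n_swaps number of adjacent transpositions (>= 0).
#' @param seed RNG seed.
#' @return list with `a`, `b` (ranked lists) and `positions` (the swapped
#'   positions, in order of application).
#' @export
ranked_fixture <- function(n, n_swaps, seed = 1L) {
  n <- as.integer(n)
  n_swaps <- as.integer(n_swaps)
  stopifnot(n >= 2L, n_swaps >= 0L)
  items <- sprintf("g%03d", seq_len(n))
  b <- items
  positions <- integer(0)
  if (n_swaps > 0L) {
    positions <- with_seed(seed, sample.int(n - 1L, n_swaps, replace = TRUE))
    for (i in positions) {
      b[c(i, i + 1L)] <- b[c(i + 1L, i)]
    }
  }
  list(a = ranked_list(items), b = ranked_list(b), positions = positions)
}

#' Write a dataset in Matrix Market + TSV layout
#'
#' Writes `matrix.mtx` (cells x genes sparse counts), `genes.tsv`,
#' `barcodes.tsv`, `clusters.tsv` (cell_id, label), optionally `truth.tsv`,
#' and a `provenance.json` capturing the simulation config when available.
#'
#' @param data a `"labeled_dataset"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(data, dir) {
  stopifnot(inherits(data, "labeled_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(data$counts, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(colnames(data$counts), file.path(dir, "genes.tsv"))
  writeLines(rownames(data$counts), file.path(dir, "barcodes.tsv"))
  utils::write.table(
    data.frame(cell_id = rownames(data$counts), label = data$cluster),
    file.path(dir, "clusters.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(data$truth)) {
    utils::write.table(
      data.frame(cell_id = rownames(data$counts), label = data$truth),
      file.path(dir, "truth.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (inherits(data, "sim_dataset")) {
    jsonlite::write_json(unclass(data$config),
                         file.path(dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a dataset written by [write_dataset()] (or 10x-style exports)
#'
#' Accepts either a directory with `matrix.mtx` + `genes.tsv` +
#' `barcodes.tsv`, or a dense CSV (cells x genes, header = gene IDs, first
#' column = cell IDs). Cluster (and optional truth) labels come from
#' two-column TSVs (`cell_id`, `label`).
#'
#' @param counts_path dataset directory or dense CSV file.
#' @param clusters_path two-column TSV of per-cell cluster labels; defaults
#'   to `clusters.tsv` inside a dataset directory.
#' @param truth_path optional two-column TSV of ground-truth labels.
#' @return a `"labeled_dataset"`.
#' @export
read_dataset <- function(counts_path, clusters_path = NULL,
                         truth_path = NULL) {
  if (dir.exists(counts_path)) {
    m <- as.matrix(Matrix::readMM(file.path(counts_path, "matrix.mtx")))
    colnames(m) <- readLines(file.path(counts_path, "genes.tsv"))
    rownames(m) <- readLines(file.path(counts_path, "barcodes.tsv"))
    if (is.null(clusters_path)) {
      clusters_path <- file.path(counts_path, "clusters.tsv")
    }
    if (is.null(truth_path)) {
      cand <- file.path(counts_path, "truth.tsv")
      if (file.exists(cand)) truth_path <- cand
    }
  } else {
    df <- utils::read.csv(counts_path, row.names = 1L, check.names = FALSE)
    m <- as.matrix(df)
  }
  if (is.null(clusters_path)) {
    stop("clusters_path is required for CSV input", call. = FALSE)
  }
  read_labels <- function(path) {
    lab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("cell_id", "label") %in% names(lab))) {
      stop("label file ", path, " must have columns cell_id, label",
           call. = FALSE)
    }
    if (!setequal(lab$cell_id, rownames(m))) {
      stop("label file ", path, " does not cover the dataset's cells",
           call. = FALSE)
    }
    stats::setNames(lab$label, lab$cell_id)[rownames(m)]
  }
  cl <- read_labels(clusters_path)
  tr <- if (!is.null(truth_path)) read_labels(truth_path) else NULL
  labeled_dataset(m, cl, tr)
}
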