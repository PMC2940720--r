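#' Alignment coverage filter
#'
#' Drops every non-reference row whose non-gap overlap with the reference's
#' non-gap columns is below `min_coverage` of the reference length. Ortholog
#' sets inferred automatically can contain fragmentary or distantly homologous
#' sequences; requiring 80% coverage of the human reference keeps the column
#' statistics anchored to comparable full-length orthologs. The reference row
#' is always retained.
#'
#' @param cluster An [ortholog_cluster()].
#' @param min_coverage Minimum covered fraction of reference positions
#'   (default 0.80).
#' @return The filtered `ortholog_cluster`.
#' @export
coverage_filter <- function(cluster, min_coverage = 0.80) {
  stopifnot(inherits(cluster, "ortholog_cluster"))
  ref_cols <- !is.na(cluster$column_map)
  l_ref <- sum(ref_cols)
  cov <- rowSums(cluster$mat[, ref_cols, drop = FALSE] != "-") / l_ref
  keep <- cov >= min_coverage
  keep[cluster$reference_index] <- TRUE
  subset_rows(cluster, keep)
}

#' Redundancy filter for near-identical orthologs
#'
#' Iteratively removes one member of every sequence pair whose pairwise
#' identity exceeds `max_identity`, to stop clusters dominated by very close
#' species from inflating apparent conservation. Identity is computed on the
#' alignment projection: matches over columns where at least one of the two
#' rows is non-gap. Pairs are visited in row-index order and the removed
#' member is picked by the seeded generator, so a seed fully determines the
#' output. The reference row is never removed.
#'
#' @param cluster An [ortholog_cluster()].
#' @param max_identity Identity above which a pair is redundant (default
#'   0.90, i.e. pairs *over* 90% identical are pruned).
#' @param seed Integer seed for the random choice of which member to drop.
#' @return The filtered `ortholog_cluster`.
#' @export
redundancy_filter <- function(cluster, max_identity = 0.90, seed = 1) {
  stopifnot(inherits(cluster, "ortholog_cluster"))
  set.seed(seed)
  mat <- cluster$mat
  n <- nrow(mat)
  alive <- rep(TRUE, n)
  ref <- cluster$reference_index
  for (i in seq_len(n - 1L)) {
    if (!alive[i]) next
    for (j in seq.int(i + 1L, n)) {
      if (!alive[j] || !alive[i]) next
      if (pair_identity(mat[i, ], mat[j, ]) > max_identity) {
        if (i == ref) {
          drop <- j
        } else if (j == ref) {
          drop <- i
        } else {
          drop <- if (runif(1) < 0.5) i else j
        }
        alive[drop] <- FALSE
      }
    }
  }
  subset_rows(cluster, alive)
}

#' Cluster-size gate
#'
#' Alignments with too few sequences cannot support column-pair statistics;
#' clusters below `min_size` surviving sequences are skipped by the
#' pipeline. The default of 30 orthologs is a common working cutoff; a
#' stringent analysis uses 125.
#'
#' @param cluster An [ortholog_cluster()].
#' @param min_size Minimum number of surviving sequences (default 30).
#' @return `TRUE` if the cluster passes, else `FALSE`.
#' @export
size_gate <- function(cluster, min_size = 30) {
  stopifnot(inherits(cluster, "ortholog_cluster"))
  n_sequences(cluster) >= min_size
}

#' Capped subsampling of large clusters
#'
#' Very large ortholog sets are reduced to at most `cap` sequences by
#' keeping the reference plus a seeded uniform sample of `cap - 1` of the
#' others; smaller clusters pass through unchanged.
#'
#' @param cluster An [ortholog_cluster()].
#' @param cap Maximum number of sequences (default 300).
#' @param seed Integer seed for the sample.
#' @return The (possibly subsampled) `ortholog_cluster`.
#' @export
cap_sample <- function(cluster, cap = 300, seed = 1) {
  stopifnot(inherits(cluster, "ortholog_cluster"), cap >= 1)
  n <- n_sequences(cluster)
  if (n <= cap) return(cluster)
  set.seed(seed)
  others <- setdiff(seq_len(n), cluster$reference_index)
  keep_idx <- c(cluster$reference_index, sample(others, cap - 1L))
  keep <- seq_len(n) %in% keep_idx
  subset_rows(cluster, keep)
}

#' Apply the full preprocessing chain
#'
#' Coverage filter, redundancy pruning, size gate and capped subsampling in
#' order. Returns `NULL` (with a message) when the cluster fails the size
#' gate.
#'
#' @inheritParams coverage_filter
#' @inheritParams redundancy_filter
#' @inheritParams size_gate
#' @inheritParams cap_sample
#' @return The preprocessed `ortholog_cluster`, or `NULL` if gated out.
#' @export
preprocess_cluster <- function(cluster, min_coverage = 0.80,
                               max_identity = 0.90, min_size = 30,
                               cap = 300, seed = 1) {
  cluster <- coverage_filter(cluster, min_coverage)
  cluster <- redundancy_filter(cluster, max_identity, seed = seed)
  if (!size_gate(cluster, min_size)) {
    message(sprintf("cluster %s: %d sequences after filtering (< %d), skipped",
                    cluster$protein_id, n_sequences(cluster), min_size))
    return(NULL)
  }
  cap_sample(cluster, cap, seed = seed)
}

# keep a logical subset of rows, preserving reference and column map
subset_rows <- function(cluster, keep) {
  if (!keep[cluster$reference_index]) {
    stop("internal error: reference row dropped", call. = FALSE)
  }
  if (!any(keep)) stop("no sequences left after filtering", call. = FALSE)
  ortholog_cluster(cluster$mat[keep, , drop = FALSE],
                   reference_id = rownames(cluster$mat)[cluster$reference_index],
                   protein_id = cluster$protein_id)
}
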