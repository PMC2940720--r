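#' OMES co-evolution scores for all column pairs
#'
#' Scores every pair of alignment columns that map to reference positions
#' with the OMES (Observed Minus Expected Squared) statistic. For a column
#' pair, rows gapped at either column are dropped (pairwise-complete); with
#' `n_valid` remaining rows, joint counts \eqn{N_{obs}(x,y)} and expected
#' counts \eqn{N_{ex}(x,y) = C_i(x) C_j(y) / n_{valid}} from the column
#' marginals, the score is
#' \deqn{\sum_{(x,y)\ observed} (N_{obs}(x,y) - N_{ex}(x,y))^2 / n_{valid},}
#' the chi-square-style variant in which the sum runs over residue pairs
#' actually observed. High scores flag column pairs whose residues co-vary
#' across orthologs.
#'
#' @param cluster An [ortholog_cluster()].
#' @param min_valid Minimum gap-free rows required to score a pair
#'   (default 10); pairs below it get `NA` scores and are dropped from the
#'   returned table.
#' @param min_separation Minimum sequence separation |pos_i - pos_j| for a
#'   pair to be scored (default 0 = score all pairs; the contact analysis
#'   applies its own window separately).
#' @return A tibble with columns `protein_id`, `pos_i`, `pos_j`
#'   (1-based reference positions, `pos_i < pos_j`), `score`, `n_valid`,
#'   sorted by decreasing score.
#' @export
#' @examples
#' cl <- ortholog_cluster(c(a = "AWAS", b = "AWAS", c = "SWGT", d = "SWGT"))
#' omes_pairs(cl, min_valid = 2)
omes_pairs <- function(cluster, min_valid = 10, min_separation = 0) {
  stopifnot(inherits(cluster, "ortholog_cluster"))
  cm <- column_map(cluster)
  codes <- encode_alignment(cluster$mat)
  raw <- omes_all_pairs(codes, cm$column, as.integer(min_valid))
  pos <- setNames(cm$position, cm$column)
  out <- tibble::tibble(
    protein_id = cluster$protein_id,
    pos_i = unname(pos[as.character(raw[, 1])]),
    pos_j = unname(pos[as.character(raw[, 2])]),
    score = raw[, 3],
    n_valid = as.integer(raw[, 4]))
  out <- dplyr::filter(out, !is.na(.data$score),
                       .data$pos_j - .data$pos_i > min_separation)
  dplyr::arrange(out, dplyr::desc(.data$score), .data$pos_i, .data$pos_j)
}

#' OMES score of a single column pair
#'
#' @param cluster An [ortholog_cluster()].
#' @param pos_i,pos_j Reference positions (1-based).
#' @inheritParams omes_pairs
#' @return A one-row tibble (`protein_id`, `pos_i`, `pos_j`, `score`,
#'   `n_valid`); errors if fewer than `min_valid` gap-free rows remain.
#' @export
omes_score <- function(cluster, pos_i, pos_j, min_valid = 10) {
  cm <- column_map(cluster)
  cols <- cm$column[match(c(pos_i, pos_j), cm$position)]
  if (anyNA(cols)) stop("positions must map to reference positions", call. = FALSE)
  codes <- encode_alignment(cluster$mat)
  raw <- omes_all_pairs(codes, cols, 0L)
  if (raw[1, 4] < min_valid) {
    stop(sprintf("only %d gap-free rows at pair (%d, %d); min_valid = %d",
                 as.integer(raw[1, 4]), pos_i, pos_j, min_valid), call. = FALSE)
  }
  tibble::tibble(protein_id = cluster$protein_id,
                 pos_i = min(pos_i, pos_j), pos_j = max(pos_i, pos_j),
                 score = raw[1, 3], n_valid = as.integer(raw[1, 4]))
}

#' Select the top L x k co-evolving pairs
#'
#' Keeps the `min(L * k, nrow(scores))` highest-scoring pairs, with the
#' deterministic tie-break (score descending, then `pos_i`, then `pos_j`).
#' `k = 5` is the commonly used constant; the LOD gain saturates around
#' `k` of 5-10.
#'
#' @param scores Pair-score tibble from [omes_pairs()] (single protein).
#' @param L Reference protein length.
#' @param k Selection constant; `L * k` is rounded to the nearest integer.
#' @return The selected rows of `scores`.
#' @export
select_top_pairs <- function(scores, L, k = 5) {
  stopifnot(L >= 1, k >= 0)
  n_take <- min(round(L * k), nrow(scores))
  scores <- dplyr::arrange(scores, dplyr::desc(.data$score),
                           .data$pos_i, .data$pos_j)
  head(scores, n_take)
}

#' Call correlated positions
#'
#' A reference position is *correlated* if it appears in at least one
#' selected pair.
#'
#' @param selected Selected pair tibble (columns `protein_id`, `pos_i`,
#'   `pos_j`).
#' @return A tibble `protein_id`, `position` (distinct, sorted).
#' @export
call_correlated_positions <- function(selected) {
  if (nrow(selected) == 0L) {
    return(tibble::tibble(protein_id = character(0), position = integer(0)))
  }
  dplyr::arrange(dplyr::distinct(dplyr::bind_rows(
    dplyr::select(selected, "protein_id", position = "pos_i"),
    dplyr::select(selected, "protein_id", position = "pos_j"))),
    .data$protein_id, .data$position)
}

#' Sweep the selection constant k against the global LOD
#'
#' Recomputes pair selection and the global disease-enrichment LOD for each
#' value of `k`. Correlated-position sets are nested in `k`, so the count
#' column is monotone non-decreasing. `k = 0` selects no pairs and yields an
#' undefined LOD (`NA`, flagged).
#'
#' @param scores_by_protein Pair scores for one or more proteins (output of
#'   [omes_pairs()], possibly row-bound), with an `L` lookup given by
#'   `lengths`.
#' @param lengths Named integer vector or tibble (`protein_id`, `L`) of
#'   reference lengths.
#' @param universe Residue universe tibble (`protein_id`, `position`).
#' @param labels Disease label tibble (`protein_id`, `position`).
#' @param k_values Numeric vector of k values to sweep.
#' @return A tibble `k`, `n_pairs`, `n_correlated`, `lod`, `fold`,
#'   `defined`.
#' @export
k_sweep <- function(scores_by_protein, lengths, universe, labels,
                    k_values = c(0, 1, 2, 5, 10, 20, 50)) {
  if (is.data.frame(lengths)) lengths <- setNames(lengths$L, lengths$protein_id)
  purrr::map_dfr(k_values, function(k) {
    sel <- purrr::map_dfr(
      split(scores_by_protein, scores_by_protein$protein_id),
      function(df) select_top_pairs(df, L = lengths[[df$protein_id[[1L]]]], k = k))
    cor_pos <- call_correlated_positions(sel)
    if (nrow(cor_pos) == 0L) {
      return(tibble::tibble(k = k, n_pairs = 0L, n_correlated = 0L,
                            lod = NA_real_, fold = NA_real_, defined = FALSE))
    }
    ct <- count_contingency(universe, labels, cor_pos)
    if (ct$c == 0 || ct$d == 0) {
      return(tibble::tibble(k = k, n_pairs = nrow(sel),
                            n_correlated = nrow(cor_pos),
                            lod = NA_real_, fold = NA_real_, defined = FALSE))
    }
    er <- compute_lod(ct)
    tibble::tibble(k = k, n_pairs = nrow(sel), n_correlated = nrow(cor_pos),
                   lod = er$lod, fold = er$fold, defined = er$defined)
  })
}

# encode a character alignment matrix as integers (0 gap/unknown, 1..20 aa)
encode_alignment <- function(mat) {
  codes <- match(mat, AA20)
  codes[is.na(codes)] <- 0L
  matrix(as.integer(codes), nrow = nrow(mat))
}
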