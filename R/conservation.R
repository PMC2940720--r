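#' Per-position conservation profile
#'
#' Computes both column conservation measures for every reference position
#' of a cluster:
#'
#' * `s_blosum` — the BLOSUM62 conservation score: the sum of BLOSUM62
#'   scores between the reference residue and every non-gap ortholog residue
#'   in the column, normalized by the maximum attainable sum
#'   \eqn{(N - 1 - g_j)\, B(a_{ref}, a_{ref})} (where \eqn{g_j} counts gaps
#'   among the orthologs in column \eqn{j}), clamped below at 0 since BLOSUM
#'   scores can be negative.
#' * `s_identity` — the fraction of non-gap ortholog residues identical to
#'   the reference residue.
#'
#' Both lie in \[0, 1\] and equal 1 on perfectly conserved columns.
#' Positions where every ortholog is gapped get `NA` scores and are excluded
#' from conservation-stratified analyses.
#'
#' @param cluster An [ortholog_cluster()].
#' @return A tibble `protein_id`, `position`, `s_blosum`, `s_identity`,
#'   `n_nongap` (non-gap ortholog rows in the column).
#' @export
#' @examples
#' cl <- ortholog_cluster(c(ref = "AW", o1 = "AG", o2 = "SG"))
#' conservation_profile(cl)
conservation_profile <- function(cluster) {
  stopifnot(inherits(cluster, "ortholog_cluster"))
  b62 <- blosum62()
  cm <- column_map(cluster)
  mat <- cluster$mat[, cm$column, drop = FALSE]
  ref <- mat[cluster$reference_index, ]
  orth <- mat[-cluster$reference_index, , drop = FALSE]
  aa <- rownames(b62)

  score_col <- function(j) {
    col <- orth[, j]
    nongap <- col != "-" & col %in% aa
    n <- sum(nongap)
    if (n == 0L) {
      return(c(s_blosum = NA_real_, s_identity = NA_real_, n_nongap = 0))
    }
    r <- ref[[j]]
    sb <- max(0, sum(b62[r, col[nongap]]) / (n * b62[r, r]))
    si <- sum(col[nongap] == r) / n
    c(s_blosum = sb, s_identity = si, n_nongap = n)
  }
  sc <- vapply(seq_len(ncol(mat)), score_col, numeric(3))
  tibble::tibble(protein_id = cluster$protein_id, position = cm$position,
                 s_blosum = sc["s_blosum", ], s_identity = sc["s_identity", ],
                 n_nongap = as.integer(sc["n_nongap", ]))
}

#' @rdname conservation_profile
#' @param position A single reference position.
#' @return `blosum_conservation()` / `identity_conservation()`: the scalar
#'   score at one position.
#' @export
blosum_conservation <- function(cluster, position) {
  p <- conservation_profile(cluster)
  unname(p$s_blosum[match(position, p$position)])
}

#' @rdname conservation_profile
#' @export
identity_conservation <- function(cluster, position) {
  p <- conservation_profile(cluster)
  unname(p$s_identity[match(position, p$position)])
}

#' Threshold filter on a conservation profile
#'
#' `at_most` keeps positions with score <= t (used to remove the top
#' conserved columns when testing whether the correlation signal survives
#' without them); `at_least` keeps score >= t (used when conservation itself
#' is the predictor). Positions with undefined scores are always dropped.
#'
#' @param profile Output of [conservation_profile()] (one or more proteins,
#'   row-bound).
#' @param measure `"s_blosum"` or `"s_identity"`.
#' @param mode `"at_most"` or `"at_least"`.
#' @param t Threshold in \[0, 1\].
#' @return A tibble `protein_id`, `position` of retained positions.
#' @export
conservation_filter <- function(profile, measure = c("s_blosum", "s_identity"),
                                mode = c("at_most", "at_least"), t) {
  measure <- match.arg(measure)
  mode <- match.arg(mode)
  stopifnot(is.numeric(t), length(t) == 1L)
  v <- profile[[measure]]
  keep <- !is.na(v) & (if (mode == "at_most") v <= t else v >= t)
  dplyr::select(profile[keep, , drop = FALSE], "protein_id", "position")
}

#' LOD sweep over conservation thresholds
#'
#' Two stratified analyses over a grid of conservation cutoffs:
#'
#' * `type = "filter_universe"`: at each cutoff t the residue universe is
#'   restricted to positions with conservation <= t (progressively removing
#'   the top conserved columns) and the LOD of the *correlated* predictor is
#'   recomputed — a stable curve means the co-evolution signal is not an
#'   artifact of conservation.
#' * `type = "as_predictor"`: positions with conservation >= t form the
#'   predictor set and their disease LOD is computed — conservation's own
#'   performance curve.
#'
#' @param universe Residue universe tibble (`protein_id`, `position`).
#' @param labels Disease labels tibble.
#' @param correlated Correlated positions tibble (needed for
#'   `"filter_universe"`).
#' @param profile Conservation profile ([conservation_profile()] output).
#' @param measure `"s_blosum"` or `"s_identity"`.
#' @param thresholds Cutoff grid (default 1.00 down to 0.05 in steps of
#'   0.05).
#' @param type See above.
#' @return A tibble `t`, `n`, `d`, `c`, `dc`, `lod`, `fold`, `defined`.
#' @export
conservation_sweep <- function(universe, labels, correlated = NULL, profile,
                               measure = c("s_blosum", "s_identity"),
                               thresholds = seq(1, 0.05, by = -0.05),
                               type = c("filter_universe", "as_predictor")) {
  measure <- match.arg(measure)
  type <- match.arg(type)
  if (type == "filter_universe" && is.null(correlated)) {
    stop("'correlated' positions are required for type = 'filter_universe'",
         call. = FALSE)
  }
  purrr::map_dfr(thresholds, function(t) {
    if (type == "filter_universe") {
      uni <- dplyr::semi_join(
        universe, conservation_filter(profile, measure, "at_most", t),
        by = c("protein_id", "position"))
      pred <- correlated
    } else {
      uni <- universe
      pred <- conservation_filter(profile, measure, "at_least", t)
    }
    ct <- count_contingency(uni, labels, pred)
    if (ct$c == 0L || ct$d == 0L) {
      return(tibble::tibble(t = t, n = ct$n, d = ct$d, c = ct$c, dc = ct$dc,
                            lod = NA_real_, fold = NA_real_, defined = FALSE))
    }
    er <- compute_lod(ct)
    tibble::tibble(t = t, n = ct$n, d = ct$d, c = ct$c, dc = ct$dc,
                   lod = er$lod, fold = er$fold, defined = TRUE)
  })
}

# BLOSUM62 from Biostrings, cached
blosum62 <- function() {
  if (is.null(the$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    the$blosum62 <- e$BLOSUM62[AA20, AA20]
  }
  the$blosum62
}
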