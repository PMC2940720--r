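#' Extract evolutionarily tolerated (benign) substitutions
#'
#' Amino-acid differences observed in orthologs at least 95% identical to
#' the human reference (and covering at least 80% of it) are substitutions
#' evolution has tolerated in a near-identical sequence context, hence very
#' unlikely to cause disease. Each aligned non-gap mismatch of a qualifying
#' ortholog yields one record; records are deduplicated by (position,
#' observed residue).
#'
#' @param cluster An [ortholog_cluster()].
#' @param min_identity Minimum pairwise identity to the reference
#'   (default 0.95), computed on the alignment projection as in
#'   [redundancy_filter()].
#' @param min_coverage Minimum coverage of reference positions
#'   (default 0.80).
#' @return A tibble `protein_id`, `position`, `ref_residue`, `obs_residue`,
#'   `ortholog_id`, `identity`; zero rows when no ortholog qualifies (such
#'   proteins are skipped from the benign-control analysis).
#' @export
extract_benign <- function(cluster, min_identity = 0.95, min_coverage = 0.80) {
  stopifnot(inherits(cluster, "ortholog_cluster"))
  mat <- cluster$mat
  ref_i <- cluster$reference_index
  ref_row <- mat[ref_i, ]
  ref_cols <- which(!is.na(cluster$column_map))
  l_ref <- length(ref_cols)
  out <- list()
  for (s in setdiff(seq_len(nrow(mat)), ref_i)) {
    row <- mat[s, ]
    coverage <- sum(row[ref_cols] != "-") / l_ref
    if (coverage < min_coverage) next
    ident <- pair_identity(ref_row, row)
    if (ident < min_identity) next
    mism <- ref_cols[row[ref_cols] != "-" & row[ref_cols] != ref_row[ref_cols] &
                       row[ref_cols] %in% AA20]
    if (length(mism) == 0L) next
    out[[length(out) + 1L]] <- tibble::tibble(
      protein_id = cluster$protein_id,
      position = cluster$column_map[mism],
      ref_residue = ref_row[mism],
      obs_residue = row[mism],
      ortholog_id = rownames(mat)[s],
      identity = ident)
  }
  if (length(out) == 0L) {
    return(tibble::tibble(protein_id = character(0), position = integer(0),
                          ref_residue = character(0), obs_residue = character(0),
                          ortholog_id = character(0), identity = numeric(0)))
  }
  dplyr::distinct(dplyr::bind_rows(out), .data$protein_id, .data$position,
                  .data$obs_residue, .keep_all = TRUE)
}

#' Negative-control LOD of benign substitutions in correlated positions
#'
#' Recomputes the enrichment statistic with benign-substitution positions
#' playing the role of the label: positions tolerant to substitution should
#' be depleted, not enriched, among co-evolving positions, giving a clearly
#' negative LOD on data where the co-evolution signal marks functional
#' constraint.
#'
#' @param universe Residue universe tibble.
#' @param benign Tibble of benign-substitution positions (`protein_id`,
#'   `position`), e.g. [extract_benign()] output.
#' @param correlated Correlated position tibble.
#' @return An `enrichment_result`.
#' @export
benign_control_lod <- function(universe, benign, correlated) {
  if (nrow(benign) == 0L) {
    stop("no benign substitutions supplied", call. = FALSE)
  }
  enrich(universe, benign, correlated)
}
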