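#' Ortholog alignment cluster
#'
#' An `ortholog_cluster` holds one pre-aligned set of orthologous protein
#' sequences together with a designated human reference row. Internally the
#' alignment is a character matrix (one row per sequence, one column per
#' alignment column, `"-"` for gaps); all downstream column statistics index
#' into it directly. Reference positions are 1-based positions in the
#' ungapped reference sequence; alignment columns where the reference has a
#' gap map to no reference position and are excluded from scoring.
#'
#' @param sequences Character vector of aligned sequences (equal length,
#'   `"-"` as the gap character) or a character matrix of single residues.
#' @param ids Sequence identifiers (unique). Defaults to `seq1..seqN`.
#' @param reference_id Identifier of the reference (human) row.
#' @param protein_id Label used in tabular outputs; defaults to
#'   `reference_id`.
#'
#' @return An object of class `ortholog_cluster`: a list with elements
#'   `mat` (character matrix with rownames `ids`), `reference_index`,
#'   `protein_id`, and `column_map` (integer vector over alignment columns,
#'   `NA` where the reference is gapped, otherwise the reference position).
#' @export
#' @examples
#' cl <- ortholog_cluster(c(ref = "AC-DE", orth1 = "ACWDE", orth2 = "AC-D-"),
#'                        reference_id = "ref")
#' n_sequences(cl)
#' reference_length(cl)
ortholog_cluster <- function(sequences, ids = NULL, reference_id = NULL,
                             protein_id = NULL) {
  if (is.matrix(sequences)) {
    mat <- sequences
    if (is.null(ids)) ids <- rownames(mat)
  } else {
    if (is.null(ids)) ids <- names(sequences)
    sequences <- toupper(as.character(sequences))
    nch <- nchar(sequences)
    if (length(unique(nch)) != 1L) {
      stop("all aligned sequences must have equal length", call. = FALSE)
    }
    mat <- do.call(rbind, strsplit(sequences, "", fixed = TRUE))
  }
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(mat)))
  if (anyDuplicated(ids)) stop("sequence ids must be unique", call. = FALSE)
  rownames(mat) <- ids
  if (is.null(reference_id)) reference_id <- ids[[1L]]
  ref_idx <- match(reference_id, ids)
  if (is.na(ref_idx)) stop("reference_id not found among ids", call. = FALSE)
  if (nrow(mat) < 1L || ncol(mat) < 1L) stop("empty alignment", call. = FALSE)
  ref_nongap <- mat[ref_idx, ] != "-"
  cmap <- rep(NA_integer_, ncol(mat))
  cmap[ref_nongap] <- seq_len(sum(ref_nongap))
  structure(
    list(mat = mat, reference_index = ref_idx,
         protein_id = protein_id %||% reference_id,
         column_map = cmap),
    class = "ortholog_cluster"
  )
}

#' @export
print.ortholog_cluster <- function(x, ...) {
  cat(sprintf(
    "<ortholog_cluster> %s: %d sequences x %d columns (reference '%s', %d positions)\n",
    x$protein_id, nrow(x$mat), ncol(x$mat),
    rownames(x$mat)[x$reference_index], reference_length(x)))
  invisible(x)
}

#' @rdname ortholog_cluster
#' @param cluster An `ortholog_cluster`.
#' @export
n_sequences <- function(cluster) nrow(cluster$mat)

#' @rdname ortholog_cluster
#' @export
reference_length <- function(cluster) sum(!is.na(cluster$column_map))

#' @rdname ortholog_cluster
#' @export
reference_sequence <- function(cluster) {
  ref <- cluster$mat[cluster$reference_index, ]
  paste(ref[ref != "-"], collapse = "")
}

#' Map between alignment columns and reference positions
#'
#' @param cluster An `ortholog_cluster`.
#' @return A tibble with one row per alignment column where the reference is
#'   ungapped: `column` (alignment column, 1-based) and `position`
#'   (reference position, 1-based).
#' @export
column_map <- function(cluster) {
  keep <- !is.na(cluster$column_map)
  tibble::tibble(column = which(keep), position = cluster$column_map[keep])
}

#' Per-residue universe of a cluster set
#'
#' Builds the residue universe (one row per reference position per protein)
#' that enrichment statistics count over.
#'
#' @param clusters A list of `ortholog_cluster` objects (or a single one).
#' @return A tibble with columns `protein_id` and `position`.
#' @export
residue_universe <- function(clusters) {
  if (inherits(clusters, "ortholog_cluster")) clusters <- list(clusters)
  purrr::map_dfr(clusters, function(cl) {
    tibble::tibble(protein_id = cl$protein_id,
                   position = seq_len(reference_length(cl)))
  })
}

#' Read and write aligned ortholog clusters as FASTA
#'
#' Thin wrappers over Biostrings FASTA I/O. The reference sequence is
#' identified by id; every other record is treated as an aligned ortholog.
#'
#' @param path FASTA file of aligned sequences (gaps as `-`).
#' @param reference_id Id of the reference row.
#' @param protein_id Optional label (defaults to `reference_id`).
#' @return `read_cluster_fasta()`: an [ortholog_cluster()].
#' @export
read_cluster_fasta <- function(path, reference_id, protein_id = NULL) {
  aln <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aln))
  ortholog_cluster(as.character(aln), ids = ids,
                   reference_id = reference_id, protein_id = protein_id)
}

#' @rdname read_cluster_fasta
#' @param cluster An `ortholog_cluster` to write.
#' @export
write_cluster_fasta <- function(cluster, path) {
  seqs <- apply(cluster$mat, 1L, paste, collapse = "")
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(setNames(seqs, rownames(cluster$mat))), path)
  invisible(path)
}

# Pairwise identity of two aligned rows over columns where at least one of
# the two is non-gap; matches counted on columns where both are non-gap.
pair_identity <- function(a, b) {
  both_gap <- a == "-" & b == "-"
  denom <- sum(!both_gap)
  if (denom == 0L) return(0)
  sum(a == b & a != "-") / denom
}

`%||%` <- function(x, y) if (is.null(x)) y else x
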