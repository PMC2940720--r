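#' Read a PDB file into an atom table
#'
#' Reads ATOM records via bio3d, drops hydrogens, and maps residue numbers
#' to reference positions (by residue numbering; supply `offset` when the
#' structure numbering is shifted relative to the reference sequence).
#'
#' @param path PDB file.
#' @param chain Optional chain id to keep.
#' @param offset Added to residue numbers to obtain reference positions.
#' @return A tibble `position`, `resid` (3-letter), `elety` (atom name),
#'   `x`, `y`, `z`.
#' @export
read_structure_pdb <- function(path, chain = NULL, offset = 0) {
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  a <- a[a$type == "ATOM", , drop = FALSE]
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  hyd <- grepl("^[0-9]*H", trimws(a$elety))
  a <- a[!hyd, , drop = FALSE]
  tibble::tibble(position = as.integer(a$resno) + as.integer(offset),
                 resid = a$resid, elety = trimws(a$elety),
                 x = a$x, y = a$y, z = a$z)
}

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Residue contact map from atom coordinates
#'
#' Two residues are in contact when the smallest distance between their
#' usable atoms is at or below `threshold` *and* their sequence separation
#' exceeds `window` (contacts within the window are dominated by local
#' secondary structure and are excluded). Two atom selections are offered:
#' `sidechain_min` uses all non-hydrogen side-chain atoms (glycine, which
#' has none, falls back to its CA) with a 5.5 A default threshold; `cbeta`
#' uses only the C-beta atom (glycine falls back to CA) with an 8.0 A
#' default.
#'
#' @param atoms Atom tibble (`position`, `resid`, `elety`, `x`, `y`, `z`),
#'   e.g. from [read_structure_pdb()] or [generate_toy_structure()].
#' @param threshold Distance cutoff in Angstrom; default 5.5 for
#'   `sidechain_min`, 8.0 for `cbeta`.
#' @param window Minimum sequence separation (contact requires
#'   `|i - j| > window`); default 10.
#' @param mode `"sidechain_min"` or `"cbeta"`.
#' @return A tibble `pos_i`, `pos_j` (`pos_i < pos_j`), `min_dist`.
#' @export
contact_map <- function(atoms, threshold = NULL, window = 10,
                        mode = c("sidechain_min", "cbeta")) {
  mode <- match.arg(mode)
  if (is.null(threshold)) threshold <- if (mode == "cbeta") 8.0 else 5.5
  a <- atoms
  if (mode == "sidechain_min") {
    keep <- !(a$elety %in% BACKBONE_ATOMS)
    # glycine: no side chain, use CA
    gly <- a$position %in% unique(a$position[a$resid == "GLY"])
    keep <- keep | (gly & a$elety == "CA")
  } else {
    keep <- a$elety == "CB"
    has_cb <- unique(a$position[keep])
    keep <- keep | (!(a$position %in% has_cb) & a$elety == "CA")
  }
  a <- a[keep, , drop = FALSE]
  if (nrow(a) == 0L) {
    return(tibble::tibble(pos_i = integer(0), pos_j = integer(0),
                          min_dist = numeric(0)))
  }
  xyz <- as.matrix(a[, c("x", "y", "z")])
  dmat <- as.matrix(stats::dist(xyz))
  pos <- a$position
  # atom pairs at or below threshold, mapped to residue pairs; the minimum
  # over qualifying atom pairs is the true inter-residue minimum whenever it
  # is <= threshold, which is all we report
  hit <- which(upper.tri(dmat) & dmat <= threshold, arr.ind = TRUE)
  if (nrow(hit) == 0L) {
    return(tibble::tibble(pos_i = integer(0), pos_j = integer(0),
                          min_dist = numeric(0)))
  }
  pi <- pmin(pos[hit[, 1]], pos[hit[, 2]])
  pj <- pmax(pos[hit[, 1]], pos[hit[, 2]])
  keep <- (pj - pi) > window
  if (!any(keep)) {
    return(tibble::tibble(pos_i = integer(0), pos_j = integer(0),
                          min_dist = numeric(0)))
  }
  df <- tibble::tibble(pos_i = as.integer(pi[keep]),
                       pos_j = as.integer(pj[keep]),
                       dist = dmat[hit][keep])
  out <- dplyr::summarise(dplyr::group_by(df, .data$pos_i, .data$pos_j),
                          min_dist = min(.data$dist), .groups = "drop")
  dplyr::arrange(out, .data$pos_i, .data$pos_j)
}

# Maximum accessible surface area per residue (A^2), theoretical values of
# Tien et al. (2013), used to convert ASA to relative solvent accessibility.
MAX_ASA <- c(
  ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167, GLU = 223,
  GLN = 225, GLY = 104, HIS = 224, ILE = 197, LEU = 201, LYS = 236,
  MET = 224, PHE = 240, PRO = 159, SER = 155, THR = 172, TRP = 285,
  TYR = 263, VAL = 174)

AA1TO3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
            E = "GLU", Q = "GLN", G = "GLY", H = "HIS", I = "ILE",
            L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
            S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

#' Discretize solvent accessibility
#'
#' Converts accessible surface area (ASA, from a DSSP-style table) to
#' relative solvent accessibility RSA = ASA / maxASA(residue type) and
#' discretizes into three states: *buried* (RSA <= `buried_max`),
#' *exposed* (RSA >= `exposed_min`), *intermediate* otherwise. Rows with
#' unknown residue types are dropped with a warning. If an `rsa` column is
#' already present it is used directly.
#'
#' @param records Tibble with `position`, `aa` (1- or 3-letter residue
#'   type) and `asa` (or `rsa`); optional `ss` secondary-structure class.
#' @param buried_max,exposed_min RSA class boundaries (defaults 0.09 and
#'   0.36, common working values).
#' @return The input with `rsa` and `class` columns added
#'   (`class` in `"buried"`, `"intermediate"`, `"exposed"`).
#' @export
classify_accessibility <- function(records, buried_max = 0.09,
                                   exposed_min = 0.36) {
  stopifnot(buried_max <= exposed_min)
  if (!"rsa" %in% names(records)) {
    aa <- toupper(records$aa)
    aa3 <- ifelse(nchar(aa) == 1L, AA1TO3[aa], aa)
    maxasa <- MAX_ASA[aa3]
    if (anyNA(maxasa)) {
      warning(sprintf("%d records with unknown residue type skipped",
                      sum(is.na(maxasa))), call. = FALSE)
      records <- records[!is.na(maxasa), , drop = FALSE]
      maxasa <- maxasa[!is.na(maxasa)]
    }
    records$rsa <- records$asa / unname(maxasa)
  }
  records$class <- dplyr::case_when(
    records$rsa <= buried_max ~ "buried",
    records$rsa >= exposed_min ~ "exposed",
    TRUE ~ "intermediate")
  records
}

#' Read a DSSP-style accessibility table
#'
#' @param path TSV with columns `position`, `aa`, `asa` and optionally
#'   `ss` (secondary structure: helix/sheet/turn/other) and `protein_id`.
#' @return A tibble.
#' @export
read_accessibility_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Overlap between selected co-evolving pairs and structural contacts
#'
#' @param selected Selected pair tibble (`pos_i`, `pos_j`), one protein.
#' @param contacts Contact tibble from [contact_map()].
#' @return A list: `n_pairs`, `n_contact`, `fraction_contact` (of selected
#'   pairs whose residues are in contact), `positions` (tibble `position`,
#'   `has_contact_correlation`), `non_contact_positions` (correlated
#'   positions with no contact correlation, for the non-contact LOD).
#' @export
contact_overlap <- function(selected, contacts) {
  key <- function(d) paste(d$pos_i, d$pos_j)
  in_contact <- key(selected) %in% key(contacts)
  pos_all <- sort(unique(c(selected$pos_i, selected$pos_j)))
  pos_contact <- sort(unique(c(selected$pos_i[in_contact],
                               selected$pos_j[in_contact])))
  positions <- tibble::tibble(
    position = pos_all,
    has_contact_correlation = pos_all %in% pos_contact)
  list(n_pairs = nrow(selected),
       n_contact = sum(in_contact),
       fraction_contact = if (nrow(selected) > 0) mean(in_contact) else NA_real_,
       positions = positions,
       non_contact_positions = pos_all[!(pos_all %in% pos_contact)])
}
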