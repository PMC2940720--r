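#' Simulation configuration for synthetic ortholog clusters
#'
#' Defines the generative model used in place of licensed mutation/ortholog
#' data. A cluster has three kinds of alignment columns, all disjoint:
#' background columns (each non-reference row keeps the reference residue
#' with probability `base_identity`, otherwise draws uniformly from the
#' other 19 amino acids), conserved columns (same model at
#' `conserved_identity`), and planted co-evolving column pairs. A planted
#' pair draws, per row, one of the `coupling_states` (a pair of residues,
#' one per column); with probability `coupling_fidelity` both columns show
#' the matched state, otherwise the second column switches to a different
#' state. Disease labels are then placed with probability
#' `background_disease_rate` everywhere except planted-pair positions,
#' which use `disease_fold` times that rate.
#'
#' @param n_sequences Number of rows including the reference (30-300 in the
#'   emulated data; smaller values are allowed for unit tests).
#' @param length Alignment length in columns (reference is generated
#'   gap-free, so this equals the reference length).
#' @param base_identity Expected per-column identity to the reference for
#'   background columns, in (0,1).
#' @param n_coevolving_pairs Number of planted co-evolving column pairs.
#' @param coupling_states List of length >= 2 of two-residue character
#'   vectors, e.g. `list(c("A","V"), c("S","T"))`, giving the joint states
#'   of a planted pair.
#' @param coupling_fidelity Probability a row draws a matched state pair,
#'   in (0.5, 1].
#' @param n_conserved_columns Number of planted highly conserved columns.
#' @param conserved_identity Per-column identity for conserved columns.
#' @param disease_fold Multiplier (>= 1) on the background disease-label
#'   rate at planted-pair positions.
#' @param background_disease_rate Background disease-label probability per
#'   position. Default 0.019 matches the background rate observed in the
#'   large-scale human disease-mutation survey this generator emulates.
#' @param gap_rate Per-cell gap probability in non-reference rows.
#' @param min_pair_separation Minimum sequence separation between the two
#'   columns of a planted pair (default 11, i.e. beyond the 10-position
#'   window used by the contact analysis).
#' @param seed Integer seed; every stochastic step derives from it.
#' @param protein_id Label for the generated protein.
#'
#' @return A `sim_config` list (validated).
#' @export
sim_config <- function(n_sequences = 100, length = 200, base_identity = 0.5,
                       n_coevolving_pairs = 5,
                       coupling_states = list(c("A", "V"), c("S", "T")),
                       coupling_fidelity = 0.9, n_conserved_columns = 10,
                       conserved_identity = 0.98, disease_fold = 1.66,
                       background_disease_rate = 0.019, gap_rate = 0.02,
                       min_pair_separation = 11, seed = 1,
                       protein_id = "SYN1") {
  stopifnot(n_sequences >= 2, length >= 2,
            base_identity > 0, base_identity < 1,
            n_coevolving_pairs >= 0,
            coupling_fidelity > 0.5 - 1e-9, coupling_fidelity <= 1,
            n_conserved_columns >= 0,
            conserved_identity >= 0, conserved_identity <= 1,
            disease_fold >= 0,
            background_disease_rate >= 0, background_disease_rate <= 1,
            gap_rate >= 0, gap_rate < 1)
  if (length < 2 * n_coevolving_pairs + n_conserved_columns) {
    stop("alignment length too small for the requested planted columns",
         call. = FALSE)
  }
  if (length(coupling_states) < 2 && n_coevolving_pairs > 0) {
    stop("need at least 2 coupling states", call. = FALSE)
  }
  structure(as.list(environment()), class = "sim_config")
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# categorical column: reference residue with prob p, else uniform other 19
draw_column <- function(ref_res, n, p) {
  res <- rep(ref_res, n)
  flip <- runif(n) >= p
  k <- sum(flip)
  if (k > 0) res[flip] <- sample(setdiff(AA20, ref_res), k, replace = TRUE)
  res
}

#' Generate a synthetic ortholog cluster with known ground truth
#'
#' @param config A [sim_config()].
#' @return A list with elements `cluster` (an [ortholog_cluster()], reference
#'   row gap-free) and `truth` (a `synthetic_truth` list: `planted_pairs`
#'   tibble of `pos_i`/`pos_j`, `conserved_columns`, `planted_positions`).
#'   Because the reference row has no gaps, alignment columns and reference
#'   positions coincide.
#' @export
#' @examples
#' out <- generate_cluster(sim_config(n_sequences = 20, length = 60, seed = 7))
#' out$truth$planted_pairs
generate_cluster <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$length
  N <- config$n_sequences
  npair <- config$n_coevolving_pairs

  # planted pair columns: separation constraint, bounded retries
  planted <- matrix(integer(0), ncol = 2)
  if (npair > 0) {
    ok <- FALSE
    for (try in seq_len(200)) {
      cand <- sample.int(L, 2L * npair)
      m <- matrix(cand, ncol = 2, byrow = TRUE)
      m <- t(apply(m, 1L, sort))
      if (all(m[, 2] - m[, 1] >= config$min_pair_separation)) {
        planted <- m
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("could not place planted pairs with the required separation; ",
           "increase alignment length", call. = FALSE)
    }
  }
  planted_cols <- as.integer(planted)
  conserved <- sample(setdiff(seq_len(L), planted_cols),
                      config$n_conserved_columns)

  # reference residues; planted columns take state-1 residues so the
  # reference is itself a member of the coupled state system
  ref <- sample(AA20, L, replace = TRUE)
  if (npair > 0) {
    s1 <- config$coupling_states[[1L]]
    ref[planted[, 1]] <- s1[[1L]]
    ref[planted[, 2]] <- s1[[2L]]
  }

  mat <- matrix("", nrow = N, ncol = L)
  mat[1L, ] <- ref
  n_orth <- N - 1L
  if (n_orth > 0) {
    col_kind <- rep("background", L)
    col_kind[conserved] <- "conserved"
    col_kind[planted_cols] <- "planted"
    for (j in seq_len(L)) {
      if (col_kind[j] == "background") {
        mat[-1L, j] <- draw_column(ref[j], n_orth, config$base_identity)
      } else if (col_kind[j] == "conserved") {
        mat[-1L, j] <- draw_column(ref[j], n_orth, config$conserved_identity)
      }
    }
    if (npair > 0) {
      n_states <- length(config$coupling_states)
      a <- vapply(config$coupling_states, `[`, character(1), 1L)
      b <- vapply(config$coupling_states, `[`, character(1), 2L)
      for (p in seq_len(npair)) {
        s <- sample.int(n_states, n_orth, replace = TRUE)
        mismatch <- runif(n_orth) >= config$coupling_fidelity
        s2 <- s
        if (any(mismatch)) {
          # a mismatched row shows a *different* state in the second column
          # (others[sample.int(...)] avoids sample()'s scalar expansion)
          s2[mismatch] <- vapply(s[mismatch], function(si) {
            others <- setdiff(seq_len(n_states), si)
            others[[sample.int(length(others), 1L)]]
          }, integer(1))
        }
        mat[-1L, planted[p, 1]] <- a[s]
        mat[-1L, planted[p, 2]] <- b[s2]
      }
    }
    if (config$gap_rate > 0) {
      gap <- matrix(runif(n_orth * L) < config$gap_rate, nrow = n_orth)
      mat[-1L, ][gap] <- "-"
    }
  }

  ids <- c(paste0(config$protein_id, "_ref"),
           if (n_orth > 0) paste0(config$protein_id, "_orth", seq_len(n_orth)))
  rownames(mat) <- ids
  cluster <- ortholog_cluster(mat, reference_id = ids[[1L]],
                              protein_id = config$protein_id)
  truth <- structure(
    list(
      protein_id = config$protein_id,
      planted_pairs = tibble::tibble(
        pos_i = as.integer(planted[, 1][order(planted[, 1])]),
        pos_j = as.integer(planted[, 2][order(planted[, 1])])),
      conserved_columns = sort(as.integer(conserved)),
      planted_positions = sort(planted_cols),
      length = L),
    class = "synthetic_truth")
  list(cluster = cluster, truth = truth)
}

#' Assign disease labels with planted enrichment
#'
#' Labels each reference position "disease" independently: background
#' positions at `background_disease_rate`, planted-pair positions at
#' `min(1, disease_fold * background_disease_rate)` (clamped with a warning
#' when the product exceeds 1).
#'
#' @param truth A `synthetic_truth` from [generate_cluster()].
#' @param config The [sim_config()] used to generate it.
#' @param seed Optional seed for the label draw (defaults to
#'   `config$seed + 1` so labels are reproducible but independent of the
#'   alignment draw).
#' @return A tibble with columns `protein_id`, `position`, `label`
#'   (`"disease"`), one row per labelled position.
#' @export
assign_disease_labels <- function(truth, config, seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(seed %||% (config$seed + 1L))
  rate_bg <- config$background_disease_rate
  rate_pl <- config$disease_fold * rate_bg
  if (rate_pl > 1) {
    warning("disease_fold x background_disease_rate > 1; clamped to 1",
            call. = FALSE)
    rate_pl <- 1
  }
  rate <- rep(rate_bg, truth$length)
  rate[truth$planted_positions] <- rate_pl
  hit <- runif(truth$length) < rate
  tibble::tibble(protein_id = truth$protein_id,
                 position = which(hit), label = "disease")
}

#' Generate a toy 3D structure realizing a chosen contact fraction
#'
#' Emits pseudo-atom coordinates (one backbone CA and one side-chain CB
#' pseudo-atom per residue) such that a chosen fraction of the planted
#' co-evolving pairs are in spatial contact (minimum inter-residue atom
#' distance < 5.5 A) while every other planted pair is farther than 8.0 A.
#' Residues sit on a line at 3.8 A backbone spacing, so sequence-adjacent
#' residues have native-like spacing and sequence-distant residues are far
#' apart unless a contact is planted.
#'
#' @param truth A `synthetic_truth`.
#' @param contact_fraction Fraction of planted pairs to place in contact,
#'   in \[0, 1\]; `round(contact_fraction * n_pairs)` pairs are chosen.
#' @param seed Integer seed for the choice of contact pairs.
#' @return A list with `atoms` (tibble: `position`, `resid`, `elety`,
#'   `x`, `y`, `z`) and `contact_pairs` (tibble `pos_i`, `pos_j` of the
#'   pairs placed in contact).
#' @export
generate_toy_structure <- function(truth, contact_fraction, seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"),
            contact_fraction >= 0, contact_fraction <= 1)
  set.seed(seed)
  L <- truth$length
  pairs <- truth$planted_pairs
  n_contact <- round(contact_fraction * nrow(pairs))
  idx <- if (n_contact > 0) sort(sample.int(nrow(pairs), n_contact)) else integer(0)

  ca <- cbind(x = 3.8 * seq_len(L), y = 0, z = 0)
  cb <- cbind(x = 3.8 * seq_len(L), y = 1.5, z = 0)
  for (ii in idx) {
    i <- pairs$pos_i[[ii]]; j <- pairs$pos_j[[ii]]
    # move j's side-chain pseudo-atom next to i's: min distance 4.0 A
    cb[j, ] <- cb[i, ] + c(0, 0, 4.0)
  }
  atoms <- tibble::tibble(
    position = rep(seq_len(L), each = 2L),
    resid = rep("ALA", 2L * L),
    elety = rep(c("CA", "CB"), L),
    x = as.vector(rbind(ca[, 1], cb[, 1])),
    y = as.vector(rbind(ca[, 2], cb[, 2])),
    z = as.vector(rbind(ca[, 3], cb[, 3])))
  contact_pairs <- pairs[idx, , drop = FALSE]
  # verify the geometric guarantees by direct distance computation; bail out
  # rather than emit a bad structure
  min_dist <- vapply(seq_len(nrow(pairs)), function(p) {
    ai <- rbind(ca[pairs$pos_i[[p]], ], cb[pairs$pos_i[[p]], ])
    aj <- rbind(ca[pairs$pos_j[[p]], ], cb[pairs$pos_j[[p]], ])
    min(sqrt(outer(rowSums(ai^2), rowSums(aj^2), "+") - 2 * ai %*% t(aj)))
  }, numeric(1))
  want <- seq_len(nrow(pairs)) %in% idx
  if (any(min_dist[want] >= 5.5) || any(min_dist[!want] <= 8.0)) {
    stop("toy structure placement failed to realize the contact fraction",
         call. = FALSE)
  }
  list(atoms = atoms, contact_pairs = contact_pairs)
}

#' Generate a cohort of synthetic clusters with labels
#'
#' Convenience wrapper generating `n_proteins` independent clusters from a
#' template configuration (per-protein seeds are derived from `seed`), with
#' disease labels, pooled truth, and the residue universe.
#'
#' @param n_proteins Number of clusters.
#' @param config Template [sim_config()]; its `seed`/`protein_id` are
#'   overridden per protein.
#' @param seed Cohort seed.
#' @return List with `clusters` (named list), `truths` (named list),
#'   `labels` (tibble), `universe` (tibble), `planted_positions` (tibble
#'   `protein_id`, `position`).
#' @export
generate_cohort <- function(n_proteins, config, seed = 1) {
  stopifnot(inherits(config, "sim_config"), n_proteins >= 1)
  base <- (seed * 10007L) %% 1000003L
  out <- purrr::map(seq_len(n_proteins), function(i) {
    cfg <- config
    cfg$seed <- base + i
    cfg$protein_id <- sprintf("SYN%03d", i)
    g <- generate_cluster(cfg)
    g$labels <- assign_disease_labels(g$truth, cfg)
    g
  })
  clusters <- purrr::map(out, "cluster")
  truths <- purrr::map(out, "truth")
  names(clusters) <- names(truths) <- purrr::map_chr(truths, "protein_id")
  list(
    clusters = clusters,
    truths = truths,
    labels = purrr::map_dfr(out, "labels"),
    universe = residue_universe(clusters),
    planted_positions = purrr::map_dfr(truths, function(tr) {
      tibble::tibble(protein_id = tr$protein_id,
                     position = tr$planted_positions)
    })
  )
}

#' Write synthetic outputs to disk
#'
#' Writers for the synthetic module's external formats: aligned FASTA for
#' the cluster, TSV for labels, PDB for toy coordinates, JSON for the truth.
#'
#' @param labels Label tibble from [assign_disease_labels()].
#' @param path Output path.
#' @export
write_label_tsv <- function(labels, path) {
  readr::write_tsv(labels, path)
  invisible(path)
}

#' @rdname write_label_tsv
#' @param truth A `synthetic_truth`.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(protein_id = truth$protein_id,
         planted_pairs = truth$planted_pairs,
         conserved_columns = truth$conserved_columns,
         length = truth$length),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_label_tsv
#' @param structure A list from [generate_toy_structure()].
#' @export
write_structure_pdb <- function(structure, path) {
  a <- structure$atoms
  bio3d::write.pdb(
    pdb = NULL, file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    resno = a$position, resid = a$resid, elety = a$elety,
    chain = rep("A", nrow(a)))
  invisible(path)
}
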