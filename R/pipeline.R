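#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis. Clusters can be given
#' as a list of [ortholog_cluster()] objects or as a manifest tibble
#' (`cluster_id`, `reference_id`, `fasta_path`) pointing at aligned FASTA
#' files.
#'
#' @param clusters List of clusters or a manifest tibble.
#' @param labels Disease-label tibble (`protein_id`, `position`, `label`)
#'   or a TSV path.
#' @param k Selection constant (default 5).
#' @param min_size Minimum cluster size after filtering (default 30).
#' @param min_coverage Coverage filter threshold (default 0.80).
#' @param max_identity Redundancy threshold (default 0.90).
#' @param cap Sequence cap per cluster (default 300).
#' @param min_valid Minimum gap-free rows per scored pair (default 10).
#' @param conservation_grid Threshold grid for the conservation sweeps.
#' @param k_grid Grid for the k sweep.
#' @param reps Permutation / bootstrap replicates (default 1000).
#' @param seed Master seed (mandatory; every stochastic stage derives its
#'   seed from it).
#' @param preprocess Whether to run the filtering chain (default TRUE;
#'   synthetic clusters are already clean and may skip it).
#' @return A `run_config` list.
#' @export
run_config <- function(clusters, labels, k = 5, min_size = 30,
                       min_coverage = 0.80, max_identity = 0.90, cap = 300,
                       min_valid = 10,
                       conservation_grid = seq(1, 0.05, by = -0.05),
                       k_grid = c(1, 2, 5, 10, 20), reps = 1000, seed = 1,
                       preprocess = TRUE) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (is.character(labels)) labels <- readr::read_tsv(labels,
                                                      show_col_types = FALSE)
  if (is.data.frame(clusters)) {
    clusters <- purrr::pmap(clusters, function(cluster_id, reference_id,
                                               fasta_path, ...) {
      read_cluster_fasta(fasta_path, reference_id, protein_id = cluster_id)
    })
  }
  structure(as.list(environment()), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes preprocessing, OMES pair scoring and selection, correlated
#' position calling, conservation profiling and sweeps, the k sweep, the
#' correlation-network degree analysis, global and per-protein enrichment
#' statistics with permutation null and column bootstrap, and (when
#' structures are provided per cluster) the contact stratification. Writes
#' per-stage TSVs plus a machine-readable JSON report to `out_dir`. Outputs
#' are a deterministic function of the configuration and seed.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   writing.
#' @return Invisibly, a list with all stage results (`residues`, `pairs`,
#'   `selected`, `correlated`, `conservation`, `global`, `per_protein`,
#'   `permutation`, `bootstrap`, `conservation_sweeps`, `k_sweep`,
#'   `degree_lod`, `report`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  seed <- as.integer(config$seed)

  clusters <- config$clusters
  if (config$preprocess) {
    clusters <- purrr::compact(purrr::imap(clusters, function(cl, i) {
      preprocess_cluster(cl, config$min_coverage, config$max_identity,
                         config$min_size, config$cap, seed = seed + 17L)
    }))
  }
  if (length(clusters) == 0L) stop("no clusters passed filtering", call. = FALSE)
  names(clusters) <- purrr::map_chr(clusters, "protein_id")

  universe <- residue_universe(clusters)
  labels <- dplyr::distinct(
    dplyr::select(config$labels, "protein_id", "position"))
  labels <- dplyr::semi_join(labels, universe,
                             by = c("protein_id", "position"))

  lengths <- tibble::tibble(
    protein_id = names(clusters),
    L = purrr::map_int(clusters, reference_length))

  pairs <- purrr::map_dfr(clusters, omes_pairs, min_valid = config$min_valid)
  selected <- purrr::map_dfr(clusters, function(cl) {
    select_top_pairs(pairs[pairs$protein_id == cl$protein_id, , drop = FALSE],
                     L = reference_length(cl), k = config$k)
  })
  correlated <- call_correlated_positions(selected)

  conservation <- purrr::map_dfr(clusters, conservation_profile)

  global <- enrich(universe, labels, correlated)
  residues <- build_residue_table(universe, labels, correlated)
  perm <- permutation_null(universe, labels, correlated,
                           reps = config$reps, seed = seed + 1L)
  boot <- column_bootstrap(residues, reps = config$reps, seed = seed + 2L)
  per_protein <- per_protein_lods(universe, labels, correlated)

  sweeps <- purrr::map(
    setNames(c("s_blosum", "s_identity"), c("s_blosum", "s_identity")),
    function(m) {
      list(
        correlation_filtered = conservation_sweep(
          universe, labels, correlated, conservation, measure = m,
          thresholds = config$conservation_grid, type = "filter_universe"),
        conservation_predictor = conservation_sweep(
          universe, labels, profile = conservation, measure = m,
          thresholds = config$conservation_grid, type = "as_predictor"))
    })

  ksw <- k_sweep(pairs, lengths, universe, labels, k_values = config$k_grid)

  degrees <- purrr::map_dfr(names(clusters), function(pid) {
    g <- build_graph(selected[selected$protein_id == pid, , drop = FALSE])
    dplyr::mutate(graph_degrees(g), protein_id = pid)
  })
  deg_lod <- degree_lod(degrees, universe, labels)

  report <- list(
    config = list(k = config$k, min_size = config$min_size,
                  min_coverage = config$min_coverage,
                  max_identity = config$max_identity, cap = config$cap,
                  min_valid = config$min_valid, reps = config$reps,
                  seed = seed),
    n_proteins = length(clusters),
    global = as.list(tidy(global)),
    permutation = as.list(glance(perm)),
    bootstrap = as.list(glance(boot)),
    per_protein_summary = list(
      scored = sum(!per_protein$excluded),
      excluded = sum(per_protein$excluded),
      median_lod = median(per_protein$lod[!per_protein$excluded])))

  res <- list(residues = residues, pairs = pairs, selected = selected,
              correlated = correlated, conservation = conservation,
              global = global, per_protein = per_protein,
              permutation = perm, bootstrap = boot,
              conservation_sweeps = sweeps, k_sweep = ksw,
              degree_lod = deg_lod, report = report)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(df, f) readr::write_tsv(df, file.path(out_dir, f))
    w(pairs, "pairs.tsv")
    w(selected, "selected_pairs.tsv")
    w(correlated, "correlated_positions.tsv")
    w(conservation, "conservation_profile.tsv")
    w(residues, "residues.tsv")
    w(per_protein, "per_protein_lod.tsv")
    w(ksw, "k_sweep.tsv")
    w(dplyr::bind_rows(purrr::map(sweeps, "correlation_filtered"),
                       .id = "measure"), "conservation_sweep_correlation.tsv")
    w(dplyr::bind_rows(purrr::map(sweeps, "conservation_predictor"),
                       .id = "measure"), "conservation_sweep_predictor.tsv")
    w(deg_lod, "degree_lod.tsv")
    w(tidy(perm), "permutation_null.tsv")
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(res)
}

#' Recompute LODs and Fisher p-values from published contingency counts
#'
#' Reads a TSV of contingency counts (`subset`, `n`, `d`, `c`, `dc`) — for
#' example the summary tables of a published genome-scale disease-mutation
#' survey — and recomputes `fold`, `lod` and the one-sided Fisher p for
#' every row. The bundled fixture
#' `system.file("extdata", "published_counts.tsv", package = "coevomut")`
#' carries the printed counts of such a survey.
#'
#' @param counts_file TSV path (or a data frame with the same columns).
#' @return A tibble `subset`, `n`, `d`, `c`, `dc`, `fold`, `lod`,
#'   `lod_2dp`, `p_fisher`.
#' @export
#' @examples
#' f <- system.file("extdata", "published_counts.tsv", package = "coevomut")
#' reproduce_published_tables(f)
reproduce_published_tables <- function(counts_file) {
  tab <- if (is.data.frame(counts_file)) {
    tibble::as_tibble(counts_file)
  } else {
    readr::read_tsv(counts_file, show_col_types = FALSE)
  }
  need <- c("subset", "n", "d", "c", "dc")
  if (!all(need %in% names(tab))) {
    stop("counts file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  purrr::imap_dfr(split(tab, seq_len(nrow(tab))), function(row, i) {
    ct <- tryCatch(contingency_table(row$n, row$d, row$c, row$dc),
                   error = function(e) {
                     stop(sprintf("malformed counts in row %s: %s", i,
                                  conditionMessage(e)), call. = FALSE)
                   })
    er <- compute_lod(ct)
    tibble::tibble(subset = row$subset, n = row$n, d = row$d, c = row$c,
                   dc = row$dc, fold = er$fold, lod = er$lod,
                   lod_2dp = round(er$lod, 2),
                   p_fisher = fisher_test(ct))
  })
}

#' Bundled synthetic demonstration analysis
#'
#' Generates a small synthetic cohort (planted co-evolving pairs, conserved
#' columns, disease labels enriched at the planted positions) and a matching
#' [run_config()], sized to run in seconds. Used by the worked example and
#' the determinism checks.
#'
#' @param seed Master seed.
#' @param n_proteins,n_sequences,length Cohort dimensions.
#' @param reps Permutation/bootstrap replicates for the demo (default 200).
#' @param disease_fold Planted label enrichment (default 1.66).
#' @param background_disease_rate Background label rate (default 0.15,
#'   elevated above the genome-scale rate so the small demo has enough
#'   labelled positions to stratify).
#' @return A `run_config` whose `clusters`/`labels` are synthetic; the
#'   planted truth is attached as attribute `"truth"`.
#' @export
demo_config <- function(seed = 1, n_proteins = 8, n_sequences = 60,
                        length = 120, reps = 200, disease_fold = 1.66,
                        background_disease_rate = 0.15) {
  cfg <- sim_config(n_sequences = n_sequences, length = length,
                    base_identity = 0.5, n_coevolving_pairs = 6,
                    coupling_fidelity = 0.95, n_conserved_columns = 8,
                    conserved_identity = 0.98, disease_fold = disease_fold,
                    background_disease_rate = background_disease_rate,
                    gap_rate = 0.02, seed = seed)
  cohort <- generate_cohort(n_proteins, cfg, seed = seed)
  # select as many pairs as were planted (k = 6/120): the demo measures the
  # planted enrichment, not the dilution behaviour, which k_sweep shows
  rc <- run_config(clusters = cohort$clusters, labels = cohort$labels,
                   k = 6 / length, min_size = 10, reps = reps, seed = seed,
                   k_grid = c(0.025, 0.05, 0.1, 0.5, 1, 2, 5),
                   preprocess = FALSE)
  attr(rc, "truth") <- cohort
  rc
}
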