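#' Contingency table for enrichment of a predictor in disease positions
#'
#' The 2x2 counts feeding every LOD and Fisher test: `n` residues in the
#' universe, `d` disease-labelled residues, `c` predictor-positive residues
#' (correlated / conserved / in-contact / ...), and `dc` residues that are
#' both.
#'
#' @param n,d,c,dc Non-negative counts with `dc <= min(d, c)`,
#'   `d <= n`, `c <= n`.
#' @return A `contingency_table` object.
#' @export
#' @examples
#' contingency_table(741436, 14211, 62365, 1988)
contingency_table <- function(n, d, c, dc) {
  n <- as.numeric(n); d <- as.numeric(d)
  c <- as.numeric(c); dc <- as.numeric(dc)
  stopifnot(length(n) == 1, length(d) == 1, length(c) == 1, length(dc) == 1,
            !is.na(n), !is.na(d), !is.na(c), !is.na(dc),
            n >= 0, d >= 0, c >= 0, dc >= 0)
  if (dc > min(d, c) || d > n || c > n || (d - dc) > (n - c)) {
    stop("inconsistent contingency counts", call. = FALSE)
  }
  structure(list(n = n, d = d, c = c, dc = dc), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> n=%g d=%g c=%g dc=%g\n",
              x$n, x$d, x$c, x$dc))
  invisible(x)
}

#' Count a contingency table from position sets
#'
#' @param universe Tibble (`protein_id`, `position`) of all residues.
#' @param disease Tibble of disease-labelled positions (same keys).
#' @param predictor Tibble of predictor-positive positions.
#' @return A [contingency_table()].
#' @export
count_contingency <- function(universe, disease, predictor) {
  key <- function(x) paste(x$protein_id, x$position)
  u <- unique(key(universe))
  dd <- intersect(unique(key(disease)), u)
  cc <- intersect(unique(key(predictor)), u)
  contingency_table(length(u), length(dd), length(cc),
                    length(intersect(dd, cc)))
}

#' Log-odds (LOD) enrichment statistic
#'
#' The LOD is the base-2 logarithm of the rate ratio between the
#' disease-label rate inside the predictor-positive subset and the global
#' rate: \eqn{LOD = \log_2((dc/c)/(d/n))}. `dc = 0` yields `-Inf` (flagged
#' via `defined = FALSE`), the convention used for per-protein scores where
#' no disease position happens to be predictor-positive.
#'
#' @param t A [contingency_table()].
#' @return An `enrichment_result`: list with `table`, `fold`, `lod`,
#'   `defined`.
#' @export
#' @examples
#' compute_lod(contingency_table(741436, 14211, 62365, 1988))  # LOD 0.73
compute_lod <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  if (t$c == 0 || t$d == 0) {
    stop("LOD undefined: no predictor-positive (c = 0) or no disease (d = 0) residues",
         call. = FALSE)
  }
  fold <- (t$dc / t$c) / (t$d / t$n)
  structure(list(table = t, fold = fold, lod = log2(fold),
                 defined = t$dc > 0),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> LOD = %.4f (fold = %.4f)%s\n",
              x$lod, x$fold,
              if (!is.null(x$p_fisher)) sprintf(", Fisher p = %.3g", x$p_fisher)
              else ""))
  invisible(x)
}

#' Fisher's exact test on a contingency table
#'
#' Exact hypergeometric test comparing the disease proportion among
#' predictor-positive residues with the rest. One-sided (`greater`) by
#' default since the hypothesis under test is enrichment.
#'
#' @param t A [contingency_table()].
#' @param sided `"greater"` (default) or `"two_sided"`.
#' @return The p-value.
#' @export
fisher_test <- function(t, sided = c("greater", "two_sided")) {
  stopifnot(inherits(t, "contingency_table"))
  sided <- match.arg(sided)
  m <- matrix(c(t$dc, t$c - t$dc, t$d - t$dc, t$n - t$c - t$d + t$dc),
              nrow = 2, byrow = TRUE)
  fisher.test(m, alternative = if (sided == "greater") "greater" else "two.sided")$p.value
}

#' Full enrichment analysis of one predictor
#'
#' Convenience wrapper: counts the table, computes LOD, fold and Fisher p.
#'
#' @inheritParams count_contingency
#' @inheritParams fisher_test
#' @return An `enrichment_result` with `p_fisher` attached.
#' @export
enrich <- function(universe, disease, predictor,
                   sided = c("greater", "two_sided")) {
  ct <- count_contingency(universe, disease, predictor)
  er <- compute_lod(ct)
  er$p_fisher <- fisher_test(ct, sided = match.arg(sided))
  er
}

#' Permutation null distribution of the LOD
#'
#' Shuffles the disease / non-disease tags over the entire residue universe
#' (margins `n`, `d`, `c` fixed) and recomputes the LOD `reps` times,
#' yielding the empirical background distribution the observed LOD is
#' judged against. The empirical p-value uses the add-one correction
#' \eqn{p = (1 + \#\{null \ge obs\}) / (reps + 1)}.
#'
#' @inheritParams count_contingency
#' @param reps Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return A `permutation_null` object: list with `observed` (LOD),
#'   `null_lods`, `p_empirical`, `reps`, `table`.
#' @export
permutation_null <- function(universe, disease, predictor, reps = 1000,
                             seed = 1) {
  ct <- count_contingency(universe, disease, predictor)
  if (ct$c == 0 || ct$d == 0) stop("permutation null undefined for c = 0 or d = 0",
                                   call. = FALSE)
  observed <- compute_lod(ct)$lod
  set.seed(seed)
  n <- ct$n; d <- ct$d; c <- ct$c
  base_rate <- d / n
  # shuffling the d disease tags over n residues and intersecting with the
  # c predictor slots: draw the shuffled tag locations each rep
  pred_mask <- c(rep(TRUE, c), rep(FALSE, n - c))
  null_lods <- vapply(seq_len(reps), function(r) {
    dc_perm <- sum(pred_mask[sample.int(n, d)])
    log2((dc_perm / c) / base_rate)
  }, numeric(1))
  structure(list(observed = observed,
                 null_lods = null_lods,
                 p_empirical = (1 + sum(null_lods >= observed)) / (reps + 1),
                 reps = reps, table = ct),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  fin <- x$null_lods[is.finite(x$null_lods)]
  cat(sprintf(
    "<permutation_null> observed LOD = %.4f; null mean = %.4f (sd %.4f, %d reps); empirical p = %.4g\n",
    x$observed, mean(fin), stats::sd(fin), x$reps, x$p_empirical))
  invisible(x)
}

#' Column bootstrap of the LOD
#'
#' Resamples, with replacement, the reference positions (alignment columns)
#' of each protein and recomputes the LOD on the pooled resampled data set,
#' giving a percentile confidence interval for the observed value.
#'
#' @param residues A residue table: one row per (`protein_id`, `position`)
#'   with logical columns `disease` and `predictor` (see
#'   [build_residue_table()]).
#' @param reps Bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param conf Central interval mass (default 0.95).
#' @return A `column_bootstrap` object: `observed`, `boot_lods`, `ci`
#'   (named lower/upper), `reps`.
#' @export
column_bootstrap <- function(residues, reps = 1000, seed = 1, conf = 0.95) {
  stopifnot(all(c("protein_id", "disease", "predictor") %in% names(residues)))
  set.seed(seed)
  idx_by_protein <- split(seq_len(nrow(residues)), residues$protein_id)
  dis <- residues$disease
  pred <- residues$predictor
  n <- nrow(residues)
  observed <- log2((sum(dis & pred) / sum(pred)) / (sum(dis) / n))
  boot_lods <- vapply(seq_len(reps), function(r) {
    take <- unlist(lapply(idx_by_protein, function(ix) {
      ix[sample.int(length(ix), length(ix), replace = TRUE)]
    }), use.names = FALSE)
    d <- sum(dis[take]); c <- sum(pred[take]); dc <- sum(dis[take] & pred[take])
    if (c == 0 || d == 0) return(NA_real_)
    log2((dc / c) / (d / n))
  }, numeric(1))
  alpha <- (1 - conf) / 2
  ci <- quantile(boot_lods[is.finite(boot_lods)], c(alpha, 1 - alpha),
                 na.rm = TRUE)
  structure(list(observed = observed, boot_lods = boot_lods,
                 ci = setNames(as.numeric(ci), c("lower", "upper")),
                 reps = reps, conf = conf),
            class = "column_bootstrap")
}

#' @export
print.column_bootstrap <- function(x, ...) {
  cat(sprintf("<column_bootstrap> observed LOD = %.4f; %d%% CI [%.4f, %.4f] (%d reps)\n",
              x$observed, round(100 * x$conf), x$ci[["lower"]],
              x$ci[["upper"]], x$reps))
  invisible(x)
}

#' Per-protein LOD scores
#'
#' Recomputes the contingency table and LOD within each protein. Proteins
#' where no disease position is predictor-positive (`dc = 0`) get
#' `lod = -Inf` and are flagged `excluded = TRUE`: with very few known
#' disease mutations the chance that none falls in a correlated position is
#' large, and no valid statistic can be computed. Proteins with `c = 0` or
#' `d = 0` get `NA` and the same flag.
#'
#' @inheritParams count_contingency
#' @return A tibble `protein_id`, `n`, `d`, `c`, `dc`, `lod`, `fold`,
#'   `excluded`.
#' @export
per_protein_lods <- function(universe, disease, predictor) {
  res <- build_residue_table(universe, disease, predictor)
  out <- dplyr::summarise(
    dplyr::group_by(res, .data$protein_id),
    n = dplyr::n(), d = sum(.data$disease), c = sum(.data$predictor),
    dc = sum(.data$disease & .data$predictor), .groups = "drop")
  dplyr::mutate(out,
    fold = ifelse(.data$c > 0 & .data$d > 0,
                  (.data$dc / .data$c) / (.data$d / .data$n), NA_real_),
    lod = log2(.data$fold),
    excluded = .data$dc == 0 | .data$c == 0 | .data$d == 0)
}

#' Stratified LODs
#'
#' Recomputes `n`, `d`, `c`, `dc` and the LOD inside each stratum of the
#' residue universe (a conservation bin, an accessibility class, a
#' secondary-structure class, ...). A stratum equal to the full universe
#' reproduces the global LOD. Empty strata, or strata with `c = 0` or
#' `d = 0`, are flagged undefined.
#'
#' @inheritParams count_contingency
#' @param strata Named list of position tibbles (`protein_id`, `position`),
#'   or a tibble with a `stratum` column plus the position keys.
#' @return A tibble `stratum`, `n`, `d`, `c`, `dc`, `lod`, `fold`,
#'   `defined`.
#' @export
stratified_lod <- function(universe, disease, predictor, strata) {
  if (is.data.frame(strata)) {
    strata <- split(strata[c("protein_id", "position")], strata$stratum)
  }
  purrr::imap_dfr(strata, function(pos, name) {
    uni <- dplyr::semi_join(universe, pos, by = c("protein_id", "position"))
    if (nrow(uni) == 0L) {
      return(tibble::tibble(stratum = name, n = 0, d = 0, c = 0, dc = 0,
                            lod = NA_real_, fold = NA_real_, defined = FALSE))
    }
    ct <- count_contingency(uni, disease, predictor)
    if (ct$c == 0 || ct$d == 0) {
      return(tibble::tibble(stratum = name, n = ct$n, d = ct$d, c = ct$c,
                            dc = ct$dc, lod = NA_real_, fold = NA_real_,
                            defined = FALSE))
    }
    er <- compute_lod(ct)
    tibble::tibble(stratum = name, n = ct$n, d = ct$d, c = ct$c, dc = ct$dc,
                   lod = er$lod, fold = er$fold, defined = er$defined)
  })
}

#' Build the per-residue analysis table
#'
#' The central tidy container of the pipeline: one row per residue of the
#' universe with logical columns for the disease label and the predictor.
#'
#' @inheritParams count_contingency
#' @return Tibble `protein_id`, `position`, `disease`, `predictor`.
#' @export
build_residue_table <- function(universe, disease, predictor) {
  key <- function(x) paste(x$protein_id, x$position)
  u <- dplyr::distinct(universe, .data$protein_id, .data$position)
  dplyr::mutate(u,
                disease = key(u) %in% key(disease),
                predictor = key(u) %in% key(predictor))
}
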