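#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an enrichment result
#'
#' @param x An `enrichment_result` from [compute_lod()] or [enrich()].
#' @param ... Unused.
#' @return A one-row tibble: `n`, `d`, `c`, `dc`, `fold`, `lod`,
#'   `p_fisher` (NA when no test was run), `defined`.
#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble::tibble(n = x$table$n, d = x$table$d, c = x$table$c, dc = x$table$dc,
                 fold = x$fold, lod = x$lod,
                 p_fisher = x$p_fisher %||% NA_real_,
                 defined = x$defined)
}

#' @rdname tidy.enrichment_result
#' @export
glance.enrichment_result <- function(x, ...) tidy.enrichment_result(x, ...)

#' Tidy a permutation null
#'
#' @param x A `permutation_null`.
#' @param ... Unused.
#' @return `tidy()`: a tibble of the null LODs (`rep`, `lod`). `glance()`:
#'   one row with `observed`, `p_empirical`, `null_mean`, `null_sd`,
#'   `null_q025`, `null_q975`, `reps` (null summaries over finite values).
#' @export
tidy.permutation_null <- function(x, ...) {
  tibble::tibble(rep = seq_along(x$null_lods), lod = x$null_lods)
}

#' @rdname tidy.permutation_null
#' @export
glance.permutation_null <- function(x, ...) {
  fin <- x$null_lods[is.finite(x$null_lods)]
  q <- quantile(fin, c(0.025, 0.975))
  tibble::tibble(observed = x$observed, p_empirical = x$p_empirical,
                 null_mean = mean(fin), null_sd = stats::sd(fin),
                 null_q025 = q[[1]], null_q975 = q[[2]], reps = x$reps)
}

#' Tidy a column bootstrap
#'
#' @param x A `column_bootstrap`.
#' @param ... Unused.
#' @return `tidy()`: tibble (`rep`, `lod`). `glance()`: one row with
#'   `observed`, `ci_lower`, `ci_upper`, `conf`, `reps`.
#' @export
tidy.column_bootstrap <- function(x, ...) {
  tibble::tibble(rep = seq_along(x$boot_lods), lod = x$boot_lods)
}

#' @rdname tidy.column_bootstrap
#' @export
glance.column_bootstrap <- function(x, ...) {
  tibble::tibble(observed = x$observed, ci_lower = x$ci[["lower"]],
                 ci_upper = x$ci[["upper"]], conf = x$conf, reps = x$reps)
}
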