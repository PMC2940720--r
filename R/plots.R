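#' Plot a permutation null distribution against the observed LOD
#'
#' Histogram of the permutation-null LODs with the observed value as a
#' dashed vertical line; optionally overlays a bootstrap distribution of
#' the observed LOD.
#'
#' @param object A `permutation_null`.
#' @param bootstrap Optional `column_bootstrap` to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.permutation_null <- function(object, bootstrap = NULL, ...) {
  null_df <- dplyr::mutate(tidy(object), what = "permutation null")
  df <- null_df
  if (!is.null(bootstrap)) {
    df <- dplyr::bind_rows(df,
      dplyr::mutate(tidy(bootstrap), what = "bootstrap of observed"))
  }
  df <- df[is.finite(df$lod), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lod, fill = .data$what)) +
    ggplot2::geom_histogram(bins = 40, alpha = 0.7, position = "identity") +
    ggplot2::geom_vline(xintercept = object$observed, linetype = "dashed") +
    ggplot2::labs(x = "LOD", y = "count", fill = NULL,
                  title = "Observed LOD vs permutation background") +
    ggplot2::theme_minimal()
}

#' Histogram of per-protein LOD scores
#'
#' Finite per-protein LODs as a histogram; proteins with `dc = 0`
#' (LOD of -Inf) are shown as a separate annotated bar count.
#'
#' @param per_protein Output of [per_protein_lods()].
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_per_protein_lods <- function(per_protein, bins = 30) {
  fin <- per_protein[is.finite(per_protein$lod), , drop = FALSE]
  n_inf <- sum(is.infinite(per_protein$lod) & per_protein$lod < 0, na.rm = TRUE)
  ggplot2::ggplot(fin, ggplot2::aes(x = .data$lod)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey30") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "per-protein LOD", y = "proteins",
                  subtitle = sprintf("%d proteins with LOD = -Inf excluded",
                                     n_inf)) +
    ggplot2::theme_minimal()
}

#' Plot a conservation-threshold LOD sweep
#'
#' @param sweep Output of [conservation_sweep()].
#' @return A ggplot object.
#' @export
plot_conservation_sweep <- function(sweep) {
  df <- sweep[sweep$defined, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$lod)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "conservation cutoff t", y = "LOD") +
    ggplot2::theme_minimal()
}

#' Plot a k-sweep of the selection constant
#'
#' @param sweep Output of [k_sweep()].
#' @return A ggplot object.
#' @export
plot_k_sweep <- function(sweep) {
  df <- sweep[sweep$defined, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$lod)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "selection constant k (top L x k pairs)", y = "LOD") +
    ggplot2::theme_minimal()
}

#' Plot LOD by correlation-network degree
#'
#' @param degree_table Output of [degree_lod()].
#' @return A ggplot object.
#' @export
plot_degree_lod <- function(degree_table) {
  df <- degree_table[degree_table$defined & degree_table$degree > 0, ,
                     drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$degree, y = .data$lod)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "degree (correlation partners)", y = "LOD") +
    ggplot2::theme_minimal()
}
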