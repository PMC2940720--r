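#' Correlation network from selected pairs
#'
#' Builds the per-protein graph whose nodes are correlated reference
#' positions and whose edges are the selected co-evolving pairs. A node
#' exists iff it appears in at least one selected edge.
#'
#' @param selected Selected pair tibble for one protein (`pos_i`, `pos_j`).
#' @return An igraph graph with vertex attribute `position`.
#' @export
build_graph <- function(selected) {
  if (nrow(selected) == 0L) {
    g <- igraph::make_empty_graph(directed = FALSE)
    return(g)
  }
  el <- cbind(as.character(selected$pos_i), as.character(selected$pos_j))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::V(g)$position <- as.integer(igraph::V(g)$name)
  g
}

#' Node degrees of a correlation network
#'
#' @param graph An igraph graph from [build_graph()].
#' @return Tibble `position`, `degree`.
#' @export
graph_degrees <- function(graph) {
  if (igraph::vcount(graph) == 0L) {
    return(tibble::tibble(position = integer(0), degree = integer(0)))
  }
  tibble::tibble(position = igraph::V(graph)$position,
                 degree = as.integer(igraph::degree(graph)))
}

#' Disease-enrichment LOD by correlation-network degree
#'
#' Positions correlated with many partners should be more functionally
#' constrained; this stratifies the disease LOD by the degree (number of
#' correlation partners) of each position. Positions absent from the
#' network have degree 0. Degrees at or above `max_degree` are pooled into
#' one bin since very large degrees are rare and noisy.
#'
#' @param degrees Tibble (`protein_id`, `position`, `degree`) pooled over
#'   proteins (add `protein_id` to [graph_degrees()] output).
#' @param universe Residue universe tibble.
#' @param labels Disease label tibble.
#' @param max_degree Pooling cap for the top bin (default 10).
#' @return A tibble `degree` (bin label), `n`, `d`, `c`, `dc`, `lod`,
#'   `fold`, `defined`; `lod = -Inf` for bins where no disease position has
#'   that degree, flagged `defined = FALSE`.
#' @export
degree_lod <- function(degrees, universe, labels, max_degree = 10) {
  key <- function(x) paste(x$protein_id, x$position)
  deg <- setNames(degrees$degree, key(degrees))
  uni_deg <- deg[key(universe)]
  uni_deg[is.na(uni_deg)] <- 0L
  bin <- pmin(uni_deg, max_degree)
  strata <- split(universe[c("protein_id", "position")],
                  factor(bin, levels = sort(unique(bin))))
  out <- purrr::imap_dfr(strata, function(pos, b) {
    ct <- count_contingency(universe, labels, pos)
    # here the "predictor" is membership in the degree bin
    if (ct$c == 0 || ct$d == 0) {
      return(tibble::tibble(degree = as.integer(b), n = ct$n, d = ct$d,
                            c = ct$c, dc = ct$dc, lod = NA_real_,
                            fold = NA_real_, defined = FALSE))
    }
    er <- compute_lod(ct)
    tibble::tibble(degree = as.integer(b), n = ct$n, d = ct$d, c = ct$c,
                   dc = ct$dc, lod = er$lod, fold = er$fold,
                   defined = er$defined)
  })
  out
}
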