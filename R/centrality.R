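#' Node strength
#'
#' Absolute sum of a node's edge weights, `s_i = sum_j |w_ij|`.
#'
#' @param model A [network_model()].
#' @return Named numeric vector.
#' @export
node_strength <- function(model) {
  rowSums(abs(model$weights))
}

#' Expected influence (one-step)
#'
#' Signed sum of a node's edge weights, `EI_i = sum_j w_ij`; equals strength
#' when the network has no negative edges.
#'
#' @param model A [network_model()].
#' @return Named numeric vector.
#' @export
expected_influence <- function(model) {
  rowSums(model$weights)
}

#' Betweenness centrality on the weighted network
#'
#' Edges get length `1 / |w_ij|` (stronger edges are shorter); for every
#' unordered node pair the geodesics are found and interior nodes credited,
#' with tied geodesics splitting the credit fractionally (Brandes
#' convention). Absent edges (weight 0) are non-adjacent.
#'
#' @param model A [network_model()].
#' @return Named numeric vector of (possibly fractional) path counts.
#' @export
betweenness_centrality <- function(model) {
  w <- abs(model$weights)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  b <- igraph::betweenness(g, directed = FALSE,
                           weights = 1 / igraph::E(g)$weight)
  stats::setNames(as.numeric(b), model$node_names)
}

#' Centrality table for a fitted network
#'
#' Raw and z-standardized strength, betweenness and expected influence for
#' every node, in the model's node order. A metric with zero spread gets
#' z-scores of 0 and is flagged in the `degenerate` attribute.
#'
#' @param model A [network_model()].
#' @return A data frame of class `centrality_table` with columns `node`,
#'   `strength`, `betweenness`, `expected_influence` and their `z_` versions.
#' @export
centrality_table <- function(model) {
  s <- node_strength(model)
  b <- betweenness_centrality(model)
  ei <- expected_influence(model)
  zf <- function(x) {
    sdx <- stats::sd(x)
    if (is.na(sdx) || sdx == 0) rep(0, length(x)) else (x - mean(x)) / sdx
  }
  degenerate <- c(strength = stats::sd(s) == 0,
                  betweenness = stats::sd(b) == 0,
                  expected_influence = stats::sd(ei) == 0)
  out <- data.frame(node = model$node_names, strength = unname(s),
                    betweenness = unname(b),
                    expected_influence = unname(ei),
                    z_strength = zf(unname(s)),
                    z_betweenness = zf(unname(b)),
                    z_expected_influence = zf(unname(ei)),
                    stringsAsFactors = FALSE)
  attr(out, "degenerate") <- degenerate
  class(out) <- c("centrality_table", class(out))
  out
}

#' Line plot of centrality profiles across fitted models
#'
#' Mirrors the usual centrality panel: one line per model, z-scores by
#' default, nodes on the vertical axis.
#'
#' @param tables Named list of [centrality_table()]s (one per model).
#' @param metric One of `"strength"`, `"betweenness"`,
#'   `"expected_influence"`.
#' @param z Plot z-scores (default) or raw values.
#' @return Invisibly, the plotted matrix (nodes x models).
#' @export
plot_centrality <- function(tables, metric = c("strength", "betweenness",
                                               "expected_influence"),
                            z = TRUE) {
  metric <- match.arg(metric)
  col <- if (z) paste0("z_", metric) else metric
  nodes <- tables[[1]]$node
  m <- sapply(tables, function(t) t[[col]][match(nodes, t$node)])
  graphics::matplot(m, seq_along(nodes), type = "b", pch = seq_along(tables),
                    lty = 1, xlab = if (z) paste("z", metric) else metric,
                    ylab = "", yaxt = "n")
  graphics::axis(2, at = seq_along(nodes), labels = nodes, las = 2,
                 cex.axis = 0.6)
  graphics::legend("topright", legend = names(tables),
                   pch = seq_along(tables), lty = 1, cex = 0.7,
                   col = seq_along(tables))
  invisible(m)
}
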