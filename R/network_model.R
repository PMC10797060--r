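#' Construct a fitted network model
#'
#' Container for an estimated pairwise Markov random field: a symmetric
#' edge-weight matrix with zero diagonal plus estimator provenance.
#'
#' @param family `"ggm"`, `"ising"` or `"mgm"`.
#' @param weights Symmetric numeric matrix with zero diagonal; for a GGM
#'   every weight is a partial correlation in `[-1, 1]`.
#' @param gamma EBIC hyperparameter used.
#' @param selected_penalties Chosen penalty (global for GGM, per node
#'   otherwise).
#' @param symmetrization Rule tag (`"glasso"`, `"AND"`, `"OR"`).
#' @param node_names Optional labels (defaults to `colnames(weights)`).
#' @return An object of class `network_model`.
#' @export
network_model <- function(family = c("ggm", "ising", "mgm"), weights,
                          gamma, selected_penalties = NULL,
                          symmetrization = "glasso", node_names = NULL) {
  family <- match.arg(family)
  stopifnot(is.matrix(weights), nrow(weights) == ncol(weights))
  if (is.null(node_names)) node_names <- colnames(weights)
  if (is.null(node_names))
    node_names <- paste0("V", seq_len(ncol(weights)))
  dimnames(weights) <- list(node_names, node_names)
  if (max(abs(weights - t(weights))) > 1e-8)
    stop("weight matrix is not symmetric", call. = FALSE)
  weights <- (weights + t(weights)) / 2
  if (any(diag(weights) != 0))
    stop("weight matrix must have a zero diagonal", call. = FALSE)
  if (family == "ggm" && any(abs(weights) > 1 + 1e-8))
    stop("GGM edge weights must be partial correlations in [-1, 1]",
         call. = FALSE)
  structure(list(family = family, node_names = node_names,
                 weights = weights, gamma = gamma,
                 selected_penalties = selected_penalties,
                 symmetrization = symmetrization),
            class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  ut <- x$weights[upper.tri(x$weights)]
  cat("<network_model>", toupper(x$family), "-", length(x$node_names),
      "nodes,", sum(ut != 0), "edges (gamma =", x$gamma, ",",
      x$symmetrization, "rule)\n")
  invisible(x)
}

#' Extract the edge list of a fitted network
#'
#' @param model A `network_model`.
#' @param keep_zero Include absent edges too?
#' @return Data frame with columns `i`, `j` (node names) and `weight`.
#' @export
as_edge_list <- function(model, keep_zero = FALSE) {
  w <- model$weights
  idx <- which(upper.tri(w), arr.ind = TRUE)
  out <- data.frame(i = model$node_names[idx[, 1]],
                    j = model$node_names[idx[, 2]],
                    weight = w[idx], stringsAsFactors = FALSE)
  if (!keep_zero) out <- out[out$weight != 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Serialize a fitted network to JSON (plus optional edge-list CSV)
#'
#' @param model A `network_model`.
#' @param path Output JSON path.
#' @param edges_csv Optional CSV path for the edge list.
#' @return Invisibly, `path`.
#' @export
write_network_json <- function(model, path, edges_csv = NULL) {
  obj <- list(family = model$family, gamma = model$gamma,
              symmetrization = model$symmetrization,
              node_names = model$node_names,
              selected_penalties = model$selected_penalties,
              weights = model$weights)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", null = "null")
  if (!is.null(edges_csv))
    utils::write.csv(as_edge_list(model), edges_csv, row.names = FALSE)
  invisible(path)
}
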