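#' Fit a Gaussian graphical model by EBIC-tuned graphical lasso
#'
#' Runs the graphical lasso over a decreasing log-spaced penalty path on the
#' sample Pearson correlation matrix, scores every path point by the EBIC
#' (with the number of selected edges as the parameter count and the number
#' of candidate edges `p(p-1)/2` as the candidate count), and converts the
#' selected precision matrix `K` to partial-correlation edge weights
#' `w_ij = -K_ij / sqrt(K_ii * K_jj)`.
#'
#' Binary 0/1 columns are admitted as-is (Pearson correlations on the coded
#' values); no polychoric correction is attempted.
#'
#' @param data Numeric matrix or data frame (rows = participants). Rows with
#'   any missing value among these columns are dropped.
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param n_lambda,lambda_min_ratio Penalty path: `n_lambda` log-spaced
#'   values from the smallest penalty giving an empty graph down to that
#'   value times `lambda_min_ratio`.
#' @return A [network_model()] with `family = "ggm"`.
#' @seealso [ggm_from_correlation()] to fit from a correlation matrix
#'   directly.
#' @export
fit_ggm <- function(data, gamma = 0.5, n_lambda = 100L,
                    lambda_min_ratio = 0.01) {
  data <- as.matrix(as.data.frame(data))
  data <- data[stats::complete.cases(data), , drop = FALSE]
  p <- ncol(data)
  n <- nrow(data)
  if (p < 2) stop("need at least 2 variables", call. = FALSE)
  sds <- apply(data, 2, stats::sd)
  if (any(sds == 0) || any(!is.finite(sds)))
    stop("zero-variance or non-finite column(s): ",
         paste(colnames(data)[sds == 0 | !is.finite(sds)], collapse = ", "),
         call. = FALSE)
  if (n <= p)
    warning("n <= p: graphical-lasso estimates may be unstable",
            call. = FALSE)
  S <- stats::cor(data)
  ggm_from_correlation(S, n, gamma = gamma, n_lambda = n_lambda,
                       lambda_min_ratio = lambda_min_ratio)
}

#' Fit a Gaussian graphical model from a correlation matrix
#'
#' @param S Sample correlation matrix.
#' @param n Sample size the correlations were computed from.
#' @inheritParams fit_ggm
#' @return A [network_model()] with `family = "ggm"`.
#' @export
ggm_from_correlation <- function(S, n, gamma = 0.5, n_lambda = 100L,
                                 lambda_min_ratio = 0.01) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S), n >= 1)
  if (any(!is.finite(S)))
    stop("non-finite correlations in input", call. = FALSE)
  p <- ncol(S)
  lmax <- max(abs(S[upper.tri(S)]))
  if (lmax == 0) lmax <- 1e-4
  rhos <- lambda_path(lmax, n_lambda, lambda_min_ratio)
  fit <- .glasso_path_cpp(S, rhos, maxit = 100L, tol = 1e-5)

  # The lasso path proposes the candidate edge patterns; each distinct
  # pattern is rescored by the EBIC of its pattern-constrained Gaussian
  # MLE (a "relaxed" refit), which removes the shrinkage bias of the
  # penalized likelihood from model selection. The selected pattern's
  # constrained MLE supplies the reported partial correlations.
  pats <- lapply(fit$theta, function(K) K != 0)
  keys <- vapply(pats, function(m) paste(which(m[upper.tri(m)]),
                                         collapse = ","), character(1))
  uni <- which(!duplicated(keys))
  # the empty graph is always a candidate (the path's largest penalty can
  # fall one ulp short of excluding every edge)
  adjs <- c(list(matrix(0L, p, p)),
            lapply(uni, function(i) (fit$theta[[i]] != 0) * 1L))
  ks <- c(0, fit$n_edges[uni])
  lams <- c(Inf, rhos[uni])
  refits <- lapply(adjs, function(a) .glasso_refit_cpp(S, a))
  ll <- n * vapply(refits, `[[`, numeric(1), "loglik_unit")
  # patterns whose constrained MLE does not exist (e.g. too dense for the
  # sample size) are invalid candidates
  valid <- is.finite(ll) &
    vapply(refits, function(r) {
      all(is.finite(r$theta)) && all(diag(r$theta) > 0) &&
        min(eigen(r$theta, symmetric = TRUE,
                  only.values = TRUE)$values) > 0
    }, logical(1))
  p_cand <- p * (p - 1) / 2
  sel_v <- select_on_path(ll[valid], ks[valid], lams[valid], n = n,
                          p = p_cand, gamma = gamma)
  sel <- which(valid)[sel_v]
  K <- refits[[sel]]$theta
  w <- precision_to_pcor(K)
  dimnames(w) <- dimnames(S)
  network_model("ggm", w, gamma = gamma,
                selected_penalties = lams[sel],
                symmetrization = "glasso",
                node_names = colnames(S))
}

#' Convert a precision matrix to partial correlations
#'
#' `w_ij = -K_ij / sqrt(K_ii * K_jj)`, zero diagonal; values are clamped to
#' `[-1, 1]` against rounding noise.
#'
#' @param K Symmetric positive-definite precision matrix.
#' @return Partial-correlation matrix.
#' @export
precision_to_pcor <- function(K) {
  d <- sqrt(diag(K))
  w <- -K / tcrossprod(d)
  diag(w) <- 0
  w[w > 1] <- 1
  w[w < -1] <- -1
  (w + t(w)) / 2
}
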