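#' Extended Bayesian information criterion
#'
#' `EBIC = -2 * log_likelihood + k * log(n) + 2 * gamma * k * log(p)`,
#' where `k` is the number of nonzero selected parameters and `p` the
#' number of candidate parameters (candidate predictors for a nodewise
#' regression; candidate edges for a whole-network fit). `gamma = 0`
#' reduces to the ordinary BIC; larger `gamma` favours sparser models.
#'
#' @param log_likelihood Fitted log-likelihood.
#' @param k Nonzero-parameter count (`>= 0`).
#' @param n Sample size (`>= 1`).
#' @param p Candidate-parameter count.
#' @param gamma EBIC hyperparameter (`>= 0`).
#' @return The EBIC value (smaller is better).
#' @export
ebic_score <- function(log_likelihood, k, n, p, gamma) {
  stopifnot(n >= 1, k >= 0, gamma >= 0)
  if (p == 0 && k > 0)
    stop("k > 0 with no candidate parameters (p = 0)", call. = FALSE)
  extended <- if (k == 0) 0 else 2 * gamma * k * log(p)
  -2 * log_likelihood + k * log(n) + extended
}

#' Select the EBIC-minimizing fit along a penalty path
#'
#' @param log_likelihoods,ks Per-candidate log-likelihood and nonzero count.
#' @param lambdas Per-candidate penalty (used for tie-breaking).
#' @param n,p,gamma Passed to [ebic_score()].
#' @return Index of the chosen candidate; ties are broken toward the larger
#'   penalty (the sparser model).
#' @export
select_on_path <- function(log_likelihoods, ks, lambdas, n, p, gamma) {
  stopifnot(length(log_likelihoods) >= 1,
            length(log_likelihoods) == length(ks),
            length(ks) == length(lambdas))
  eb <- mapply(ebic_score, log_likelihoods, ks,
               MoreArgs = list(n = n, p = p, gamma = gamma))
  best <- which(eb <= min(eb) + 1e-10)
  best[which.max(lambdas[best])]
}

#' Log-spaced penalty path
#'
#' @param lambda_max Largest penalty (the smallest giving an empty model).
#' @param n_points Number of grid points.
#' @param min_ratio Ratio of smallest to largest penalty.
#' @return Strictly decreasing positive vector.
#' @export
lambda_path <- function(lambda_max, n_points = 100L, min_ratio = 0.01) {
  stopifnot(lambda_max > 0, n_points >= 1, min_ratio > 0, min_ratio <= 1)
  exp(seq(log(lambda_max), log(lambda_max * min_ratio),
          length.out = n_points))
}
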