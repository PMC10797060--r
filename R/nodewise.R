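# Shared machinery for nodewise L1 fits (Ising / mixed graphical models).

# One L1-penalized nodewise regression over a penalty path with EBIC
# selection. Returns the selected slope vector (named by predictor),
# selected lambda, and selected nonzero count.
nodewise_l1 <- function(x, y, family = c("binomial", "gaussian"), gamma,
                        n_lambda = 100L, lambda_min_ratio = 0.01) {
  family <- match.arg(family)
  x <- as.matrix(x)
  n <- length(y)
  p_cand <- ncol(x)

  if (p_cand == 1L) {
    # Degenerate path: glmnet needs >= 2 predictors, so compare the null
    # model against the single-predictor fit by EBIC directly (the two
    # endpoints of the path).
    df <- data.frame(y = y, x1 = x[, 1])
    if (family == "binomial") {
      f1 <- stats::glm(y ~ x1, data = df, family = stats::binomial())
      f0 <- stats::glm(y ~ 1, data = df, family = stats::binomial())
    } else {
      f1 <- stats::lm(y ~ x1, data = df)
      f0 <- stats::lm(y ~ 1, data = df)
    }
    ll <- c(as.numeric(stats::logLik(f0)), as.numeric(stats::logLik(f1)))
    sel <- select_on_path(ll, c(0L, 1L), c(1, 0), n = n, p = 1L,
                          gamma = gamma)
    beta <- if (sel == 2L) stats::coef(f1)[["x1"]] else 0
    return(list(beta = stats::setNames(beta, colnames(x)),
                lambda = c(Inf, 0)[sel], k = sel - 1L))
  }

  fit <- glmnet::glmnet(x, y, family = family, nlambda = n_lambda,
                        lambda.min.ratio = lambda_min_ratio,
                        standardize = TRUE)

  if (family == "binomial") {
    # eLasso convention: EBIC on the penalized likelihood along the path
    dev <- (1 - fit$dev.ratio) * fit$nulldev
    ll <- -dev / 2
    sel <- select_on_path(ll, fit$df, fit$lambda, n = n, p = p_cand,
                          gamma = gamma)
    beta <- as.numeric(fit$beta[, sel])
    return(list(beta = stats::setNames(beta, colnames(x)),
                lambda = fit$lambda[sel], k = fit$df[sel]))
  }

  # Gaussian response: shrinkage of strong true coefficients keeps
  # improving the penalized RSS along the path, which overselects; rescore
  # each distinct support by its OLS refit and report refit coefficients.
  nz <- fit$beta != 0
  keys <- apply(nz, 2, function(z) paste(which(z), collapse = ","))
  uni <- which(!duplicated(keys))
  xc <- scale(x, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  xtx <- crossprod(xc)
  xty <- drop(crossprod(xc, yc))
  yty <- sum(yc^2)
  refit_beta <- function(s) {
    if (!length(s)) return(numeric(0))
    solve(xtx[s, s, drop = FALSE], xty[s])
  }
  rss <- vapply(uni, function(i) {
    s <- which(nz[, i])
    if (!length(s)) return(yty)
    yty - sum(refit_beta(s) * xty[s])
  }, numeric(1))
  ll <- -n / 2 * (log(2 * pi * pmax(rss, 1e-12) / n) + 1)
  sel_u <- select_on_path(ll, fit$df[uni], fit$lambda[uni], n = n,
                          p = p_cand, gamma = gamma)
  s <- which(nz[, uni[sel_u]])
  beta <- numeric(p_cand)
  beta[s] <- refit_beta(s)
  list(beta = stats::setNames(beta, colnames(x)),
       lambda = fit$lambda[uni][sel_u], k = length(s))
}

#' Symmetrize a matrix of directional nodewise coefficients
#'
#' `B[i, j]` holds the coefficient of predictor `i` in the regression of
#' node `j`. The edge weight is the mean of the two directional
#' coefficients; under the AND rule an edge exists only if both nodewise
#' selections kept the pair, under OR if either did (a missing direction
#' contributes 0 to the mean).
#'
#' @param B Square matrix of directional coefficients with zero diagonal.
#' @param rule `"AND"` or `"OR"`.
#' @return Symmetric weight matrix with zero diagonal.
#' @export
symmetrize_nodewise <- function(B, rule = c("AND", "OR")) {
  rule <- match.arg(rule)
  stopifnot(is.matrix(B), nrow(B) == ncol(B))
  w <- (B + t(B)) / 2
  keep <- if (rule == "AND") (B != 0) & (t(B) != 0) else (B != 0) | (t(B) != 0)
  w[!keep] <- 0
  diag(w) <- 0
  w
}

check_binary_cols <- function(data, cols = colnames(data)) {
  for (nm in cols) {
    v <- data[, nm]
    if (!all(v %in% c(0, 1)))
      stop("column '", nm, "' is not binary 0/1", call. = FALSE)
    if (stats::var(v) == 0)
      stop("column '", nm, "' is constant", call. = FALSE)
  }
  invisible(TRUE)
}

#' Fit an Ising network by nodewise L1 logistic regression (eLasso)
#'
#' Each binary node is regressed on all others with an L1-penalized
#' logistic regression over a log-spaced penalty path; the EBIC (with
#' `p - 1` candidate predictors) picks each node's neighbour set, and the
#' directional coefficients are symmetrized by the AND rule (edge kept only
#' if selected in both directions; weight = mean of the two coefficients).
#' Continuous variables must be excluded before calling.
#'
#' @param data Matrix/data frame of 0/1 columns; rows with missing values
#'   are dropped.
#' @param gamma EBIC hyperparameter (default 0.25).
#' @param n_lambda,lambda_min_ratio Penalty path settings.
#' @param rule Symmetrization rule, `"AND"` (default) or `"OR"`.
#' @return A [network_model()] with `family = "ising"`.
#' @export
fit_ising <- function(data, gamma = 0.25, n_lambda = 100L,
                      lambda_min_ratio = 0.01, rule = c("AND", "OR")) {
  rule <- match.arg(rule)
  data <- as.matrix(as.data.frame(data))
  data <- data[stats::complete.cases(data), , drop = FALSE]
  p <- ncol(data)
  if (p < 2) stop("need at least 2 nodes", call. = FALSE)
  check_binary_cols(data)
  nodes <- colnames(data)

  B <- matrix(0, p, p, dimnames = list(nodes, nodes))
  lam <- stats::setNames(numeric(p), nodes)
  for (j in seq_len(p)) {
    fitj <- nodewise_l1(data[, -j, drop = FALSE], data[, j], "binomial",
                        gamma, n_lambda, lambda_min_ratio)
    B[nodes[-j], j] <- fitj$beta
    lam[j] <- fitj$lambda
  }
  w <- symmetrize_nodewise(B, rule)
  network_model("ising", w, gamma = gamma, selected_penalties = lam,
                symmetrization = rule, node_names = nodes)
}

#' Fit a mixed graphical model by nodewise L1 regressions
#'
#' Continuous nodes are standardized and regressed by L1 least squares,
#' binary nodes by L1 logistic regression, each over its own penalty path
#' with EBIC selection; directional coefficients are symmetrized by the
#' AND rule with coefficient averaging.
#'
#' @param data Matrix/data frame; rows with missing values are dropped.
#' @param kinds Character vector per column: `"binary"` or `"continuous"`.
#' @param gamma EBIC hyperparameter (default 0.25).
#' @param n_lambda,lambda_min_ratio Penalty path settings.
#' @param rule Symmetrization rule.
#' @return A [network_model()] with `family = "mgm"`.
#' @export
fit_mgm <- function(data, kinds, gamma = 0.25, n_lambda = 100L,
                    lambda_min_ratio = 0.01, rule = c("AND", "OR")) {
  rule <- match.arg(rule)
  data <- as.matrix(as.data.frame(data))
  data <- data[stats::complete.cases(data), , drop = FALSE]
  p <- ncol(data)
  stopifnot(length(kinds) == p)
  if (!all(kinds %in% c("binary", "continuous")))
    stop("unsupported variable kind(s): ",
         paste(unique(kinds[!kinds %in% c("binary", "continuous")]),
               collapse = ", "),
         " (only binary and continuous nodes are supported)", call. = FALSE)
  nodes <- colnames(data)
  check_binary_cols(data, nodes[kinds == "binary"])
  for (nm in nodes[kinds == "continuous"])
    if (stats::sd(data[, nm]) == 0)
      stop("column '", nm, "' is constant", call. = FALSE)
  data[, kinds == "continuous"] <-
    scale(data[, kinds == "continuous", drop = FALSE])

  B <- matrix(0, p, p, dimnames = list(nodes, nodes))
  lam <- stats::setNames(numeric(p), nodes)
  for (j in seq_len(p)) {
    fam <- if (kinds[j] == "binary") "binomial" else "gaussian"
    fitj <- nodewise_l1(data[, -j, drop = FALSE], data[, j], fam,
                        gamma, n_lambda, lambda_min_ratio)
    B[nodes[-j], j] <- fitj$beta
    lam[j] <- fitj$lambda
  }
  w <- symmetrize_nodewise(B, rule)
  network_model("mgm", w, gamma = gamma, selected_penalties = lam,
                symmetrization = rule, node_names = nodes)
}
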