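#' Logistic outcome model with Wald odds-ratio intervals
#'
#' Maximum-likelihood logistic regression of a binary outcome on the index
#' score and covariates, reporting per-term beta, Wald standard error and
#' p-value, and `OR = exp(beta)` with the 95% Wald interval
#' `exp(beta +/- 1.96 * SE)`.
#'
#' @param data Data frame holding all columns.
#' @param outcome Name of the binary outcome column.
#' @param terms Character vector of predictor column names.
#' @return A `regression_result`: data frame (`term`, `beta`, `se`,
#'   `p_value`, `or`, `or_lower`, `or_upper`) with attributes `outcome`,
#'   `model_kind = "logistic"`, `n_used`.
#' @export
fit_logistic <- function(data, outcome, terms) {
  d <- data[, c(outcome, terms), drop = FALSE]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  y <- d[[outcome]]
  if (length(unique(y)) < 2)
    stop("outcome '", outcome, "' has a single class", call. = FALSE)
  x <- as.matrix(d[, terms, drop = FALSE])
  if (qr(cbind(1, x))$rank < ncol(x) + 1)
    stop("design matrix is rank deficient (collinear terms among: ",
         paste(terms, collapse = ", "), ")", call. = FALSE)
  f <- stats::as.formula(paste(outcome, "~",
                               paste(sprintf("`%s`", terms),
                                     collapse = " + ")))
  fit <- suppressWarnings(stats::glm(f, data = d,
                                     family = stats::binomial()))
  mu <- stats::fitted(fit)
  if (!fit$converged || any(mu > 1 - 1e-8) || any(mu < 1e-8)) {
    if (max(abs(stats::coef(fit)[-1])) > 15)
      stop("logistic fit did not converge cleanly (possible complete ",
           "separation); check predictors: ",
           paste(terms, collapse = ", "), call. = FALSE)
  }
  cf <- summary(fit)$coefficients
  cf <- cf[-1, , drop = FALSE]   # drop intercept from the report
  out <- data.frame(term = terms, beta = cf[, 1], se = cf[, 2],
                    p_value = cf[, 4], or = exp(cf[, 1]),
                    or_lower = exp(cf[, 1] - 1.96 * cf[, 2]),
                    or_upper = exp(cf[, 1] + 1.96 * cf[, 2]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "outcome") <- outcome
  attr(out, "model_kind") <- "logistic"
  attr(out, "n_used") <- nrow(d)
  class(out) <- c("regression_result", class(out))
  out
}

#' Linear outcome model
#'
#' Least-squares regression of a continuous outcome on the index score and
#' covariates, with coefficient t-tests.
#'
#' @inheritParams fit_logistic
#' @return A `regression_result` data frame (`term`, `beta`, `se`,
#'   `p_value`) with attributes `outcome`, `model_kind = "linear"`,
#'   `n_used`.
#' @export
fit_linear <- function(data, outcome, terms) {
  d <- data[, c(outcome, terms), drop = FALSE]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  x <- as.matrix(d[, terms, drop = FALSE])
  if (qr(cbind(1, x))$rank < ncol(x) + 1)
    stop("design matrix is rank deficient (collinear terms among: ",
         paste(terms, collapse = ", "), ")", call. = FALSE)
  f <- stats::as.formula(paste(outcome, "~",
                               paste(sprintf("`%s`", terms),
                                     collapse = " + ")))
  fit <- stats::lm(f, data = d)
  cf <- summary(fit)$coefficients[-1, , drop = FALSE]
  out <- data.frame(term = terms, beta = cf[, 1], se = cf[, 2],
                    p_value = cf[, 4], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "outcome") <- outcome
  attr(out, "model_kind") <- "linear"
  attr(out, "n_used") <- nrow(d)
  class(out) <- c("regression_result", class(out))
  out
}

#' Compare a full and a reduced multimorbidity index across all outcomes
#'
#' Scores both indices, then fits the per-outcome model (linear for
#' continuous outcomes, logistic for binary or dichotomized ordinal ones)
#' for each index on identical complete-case rows, and summarizes agreement
#' of the index term (sign match and significance match at `alpha`).
#'
#' @param dataset A [survey_dataset()].
#' @param index_full,index_reduced [mmi_definition()]s.
#' @param outcomes Outcome names (default: all role-`outcome` variables).
#' @param covariates Covariate names entered in every model.
#' @param alpha Significance level for the agreement summary.
#' @return An `index_comparison`: list with `results` (per outcome, a list
#'   with `full` and `reduced` regression results), `agreement` (data
#'   frame), `index_full`, `index_reduced`.
#' @export
compare_indices <- function(dataset, index_full, index_reduced,
                            outcomes = NULL,
                            covariates = c("OwnHome", "Incomplete", "Sex",
                                           "Age", "DaysSinceInjury"),
                            alpha = 0.05) {
  stopifnot(inherits(dataset, "survey_dataset"))
  specs <- dataset$specs
  if (is.null(outcomes)) outcomes <- specs$name[specs$role == "outcome"]
  vals <- dataset$values
  vals$MMI_full <- score_mmi(dataset, index_full)
  vals$MMI_reduced <- score_mmi(dataset, index_reduced)

  results <- list()
  agree <- list()
  for (oc in outcomes) {
    i <- match(oc, specs$name)
    kind <- specs$kind[i]
    d <- vals
    ocol <- oc
    if (kind == "ordinal") {
      scale <- if (max(specs$levels[[i]]) == 6) "lisat6" else "qol5"
      ocol <- paste0(oc, "_bin")
      d[[ocol]] <- dichotomize_outcome(d[[oc]], scale)
      kind <- "binary"
    }
    need <- c(ocol, covariates, "MMI_full", "MMI_reduced")
    d <- d[stats::complete.cases(d[, need, drop = FALSE]), , drop = FALSE]
    fitfun <- if (kind == "binary") fit_logistic else fit_linear
    rf <- tryCatch(fitfun(d, ocol, c(covariates, "MMI_full")),
                   error = function(e) e)
    rr <- tryCatch(fitfun(d, ocol, c(covariates, "MMI_reduced")),
                   error = function(e) e)
    results[[oc]] <- list(full = rf, reduced = rr)
    if (inherits(rf, "error") || inherits(rr, "error")) {
      agree[[oc]] <- data.frame(outcome = oc, sign_match = NA,
                                sig_match = NA, n_used = NA_integer_)
      next
    }
    stopifnot(attr(rf, "n_used") == attr(rr, "n_used"))
    bf <- rf$beta[rf$term == "MMI_full"]
    br <- rr$beta[rr$term == "MMI_reduced"]
    pf <- rf$p_value[rf$term == "MMI_full"]
    pr <- rr$p_value[rr$term == "MMI_reduced"]
    agree[[oc]] <- data.frame(outcome = oc,
                              sign_match = sign(bf) == sign(br),
                              sig_match = (pf < alpha) == (pr < alpha),
                              beta_full = bf, beta_reduced = br,
                              p_full = pf, p_reduced = pr,
                              n_used = attr(rf, "n_used"),
                              stringsAsFactors = FALSE)
  }
  agreement <- do.call(rbind, agree)
  rownames(agreement) <- NULL
  structure(list(results = results, agreement = agreement,
                 index_full = index_full, index_reduced = index_reduced,
                 covariates = covariates, alpha = alpha),
            class = "index_comparison")
}

#' @export
print.index_comparison <- function(x, ...) {
  cat("<index_comparison> MMI-", length(x$index_full$item_names), " vs MMI-",
      length(x$index_reduced$item_names), "\n", sep = "")
  print(x$agreement, digits = 3)
  invisible(x)
}

#' Write an index comparison as per-outcome CSV tables
#'
#' One CSV per outcome and arm, in the conventional layout
#' (term, beta, p, OR, CI bounds; OR columns empty for linear models).
#'
#' @param comparison An [compare_indices()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_comparison_csv <- function(comparison, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (oc in names(comparison$results)) {
    for (arm in c("full", "reduced")) {
      r <- comparison$results[[oc]][[arm]]
      if (inherits(r, "error")) next
      p <- file.path(dir, sprintf("regression_%s_%s.csv", oc, arm))
      utils::write.csv(as.data.frame(r), p, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
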