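#' Bivariate test of one SHC item against one outcome
#'
#' Binary outcomes are tested by the 2x2 chi-square test without continuity
#' correction, switching to Fisher's exact test when any expected cell count
#' is below five. Continuous outcomes are compared between item-present and
#' item-absent groups by the two-sample t-test, switching to the
#' Mann-Whitney U-test when a Shapiro-Wilk check (alpha = 0.05, groups
#' capped at 5000 observations) rejects normality in either group. The
#' test-selection rules depend only on expected counts / normality, never
#' on the observed significance.
#'
#' @param shc Binary 0/1 vector (the item).
#' @param outcome Outcome vector.
#' @param outcome_kind `"binary"` or `"continuous"`.
#' @return A one-row data frame: `test_used`, `statistic`, `p_value`,
#'   `n_used`, `degenerate`. Degenerate inputs (zero variance on either
#'   side) are flagged with a missing p-value rather than an error.
#' @export
bivariate_test <- function(shc, outcome,
                           outcome_kind = c("binary", "continuous")) {
  outcome_kind <- match.arg(outcome_kind)
  ok <- !is.na(shc) & !is.na(outcome)
  shc <- shc[ok]; outcome <- outcome[ok]
  n <- length(shc)
  res <- function(test, stat, p, degenerate = FALSE)
    data.frame(test_used = test, statistic = stat, p_value = p,
               n_used = n, degenerate = degenerate,
               stringsAsFactors = FALSE)
  if (n < 4 || length(unique(shc)) < 2 ||
      length(unique(outcome)) < 2)
    return(res("none", NA_real_, NA_real_, degenerate = TRUE))

  if (outcome_kind == "binary") {
    tab <- table(factor(shc, levels = 0:1), factor(outcome, levels = 0:1))
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      ft <- stats::fisher.test(tab)
      res("fisher_exact", unname(ft$estimate), ft$p.value)
    } else {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      res("chi_square", unname(ct$statistic), ct$p.value)
    }
  } else {
    g0 <- outcome[shc == 0]; g1 <- outcome[shc == 1]
    if (min(length(g0), length(g1)) < 3 ||
        stats::sd(g0) == 0 || stats::sd(g1) == 0)
      return(res("none", NA_real_, NA_real_, degenerate = TRUE))
    normal <- function(g) {
      if (length(g) > 5000) g <- g[seq_len(5000)]
      stats::shapiro.test(g)$p.value >= 0.05
    }
    if (normal(g0) && normal(g1)) {
      tt <- stats::t.test(g0, g1)
      res("t_test", unname(tt$statistic), tt$p.value)
    } else {
      wt <- suppressWarnings(stats::wilcox.test(g0, g1, exact = FALSE))
      res("mann_whitney", unname(wt$statistic), wt$p.value)
    }
  }
}

#' Screen every SHC item against every outcome
#'
#' @param dataset A [survey_dataset()].
#' @param shc_names Item names (default: all role-`shc` variables).
#' @param outcome_names Outcome names (default: all role-`outcome`
#'   variables). Ordinal outcomes are dichotomized per their scale before
#'   testing.
#' @param alpha Retained on the result for downstream use.
#' @return Long data frame (one row per item-outcome pair) of class
#'   `bivariate_screen`: `shc`, `outcome`, `test_used`, `statistic`,
#'   `p_value`, `n_used`, `degenerate`.
#' @export
screen_all <- function(dataset, shc_names = NULL, outcome_names = NULL,
                       alpha = 0.05) {
  stopifnot(inherits(dataset, "survey_dataset"))
  specs <- dataset$specs
  if (is.null(shc_names)) shc_names <- specs$name[specs$role == "shc"]
  if (is.null(outcome_names))
    outcome_names <- specs$name[specs$role == "outcome"]
  unknown <- setdiff(c(shc_names, outcome_names), specs$name)
  if (length(unknown))
    stop("unknown variable(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  vals <- dataset$values
  rows <- list()
  for (oc in outcome_names) {
    i <- match(oc, specs$name)
    y <- vals[[oc]]
    kind <- specs$kind[i]
    if (kind == "ordinal") {
      scale <- if (max(specs$levels[[i]]) == 6) "lisat6" else "qol5"
      y <- dichotomize_outcome(y, scale)
      kind <- "binary"
    }
    for (sh in shc_names) {
      r <- tryCatch(bivariate_test(vals[[sh]], y, kind),
                    error = function(e)
                      data.frame(test_used = "error", statistic = NA_real_,
                                 p_value = NA_real_, n_used = NA_integer_,
                                 degenerate = TRUE))
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(shc = sh, outcome = oc, stringsAsFactors = FALSE), r)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  class(out) <- c("bivariate_screen", class(out))
  out
}

#' Items not significant on any outcome
#'
#' Returns the SHC items whose screening p-values are at or above `alpha`
#' for every outcome (the bivariate null set feeding the short-form
#' derivation). Items with missing pairs are excluded with a warning.
#'
#' @param results A [screen_all()] table.
#' @param alpha Significance level (default 0.05).
#' @return Character vector of item names.
#' @export
null_items <- function(results, alpha = 0.05) {
  items <- unique(results$shc)
  n_out <- length(unique(results$outcome))
  keep <- character(0)
  dropped <- character(0)
  for (it in items) {
    p <- results$p_value[results$shc == it]
    if (length(p) < n_out || any(is.na(p))) {
      dropped <- c(dropped, it)
      next
    }
    if (all(p >= alpha)) keep <- c(keep, it)
  }
  if (length(dropped))
    warning("item(s) with incomplete screening excluded: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  keep
}
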