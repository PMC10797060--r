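#' Isolated nodes of a fitted network
#'
#' Nodes (restricted to `node_subset`) whose weight row is exactly zero,
#' i.e. zero degree in the fitted network — the item-removal criterion of
#' the network-driven short form.
#'
#' @param model A [network_model()].
#' @param node_subset Names to inspect (default: all nodes).
#' @return Character vector of isolated node names.
#' @export
isolated_nodes <- function(model, node_subset = model$node_names) {
  unknown <- setdiff(node_subset, model$node_names)
  if (length(unknown))
    stop("unknown node(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  deg <- rowSums(model$weights != 0)
  node_subset[deg[node_subset] == 0]
}

#' Derive the removal set from isolation sets and the bivariate null set
#'
#' @param isolation_sets List of per-model isolated-SHC name sets.
#' @param bivariate_null Names not significant on any outcome (from
#'   [null_items()]).
#' @param rule Combination rule:
#'   * `"null_and_any_isolated"` (default): items in the bivariate null set
#'     that are isolated in at least one fitted model — bivariate nullity is
#'     necessary, network isolation corroborates;
#'   * `"null_only"`: the bivariate null set as-is;
#'   * `"isolated_in_all"`: the intersection of all isolation sets.
#' @return Character vector of removed item names, with attributes `rule`
#'   and `inputs` recording the decision.
#' @export
derive_removal_set <- function(isolation_sets, bivariate_null,
                               rule = c("null_and_any_isolated",
                                        "null_only", "isolated_in_all")) {
  rule <- match.arg(rule)
  if (rule != "null_only" && length(isolation_sets) == 0)
    stop("isolation-based rules need at least one fitted model",
         call. = FALSE)
  removed <- switch(rule,
    null_and_any_isolated =
      intersect(bivariate_null,
                Reduce(union, isolation_sets, character(0))),
    null_only = as.character(bivariate_null),
    isolated_in_all = Reduce(intersect, isolation_sets))
  removed <- sort(unique(as.character(removed)))
  attr(removed, "rule") <- rule
  attr(removed, "inputs") <- list(isolation_sets = isolation_sets,
                                  bivariate_null = bivariate_null)
  removed
}

#' Configuration for the end-to-end analysis pipeline
#'
#' @param cohorts A single `survey_dataset`/`synthetic_cohort`, a list of
#'   them, or a list of [cohort_config()]s to be generated.
#' @param gamma_ggm,gamma_ising,gamma_mgm EBIC hyperparameters per family.
#' @param rule Removal rule for [derive_removal_set()].
#' @param alpha Screening significance level.
#' @param do_stability Run the bootstrap stability stage (slow)?
#' @param B_edges,B_drop Bootstrap sizes when `do_stability` is `TRUE`.
#' @param seed Integer seed for resampling stages.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohorts, gamma_ggm = 0.5, gamma_ising = 0.25,
                            gamma_mgm = 0.25,
                            rule = "null_and_any_isolated", alpha = 0.05,
                            do_stability = FALSE, B_edges = 1000L,
                            B_drop = 250L, seed = 1L) {
  if (inherits(cohorts, c("survey_dataset", "synthetic_cohort",
                          "cohort_config")))
    cohorts <- list(cohorts)
  structure(list(cohorts = cohorts, gamma_ggm = gamma_ggm,
                 gamma_ising = gamma_ising, gamma_mgm = gamma_mgm,
                 rule = rule, alpha = alpha, do_stability = do_stability,
                 B_edges = B_edges, B_drop = B_drop,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

resolve_cohort <- function(x) {
  if (inherits(x, "cohort_config")) return(generate_cohort(x)$dataset)
  if (inherits(x, "synthetic_cohort")) return(x$dataset)
  if (inherits(x, "survey_dataset")) return(x)
  stop("cannot interpret cohort input of class ", class(x)[1],
       call. = FALSE)
}

# Node tables for the three estimator families: the Ising network uses
# binary nodes only (ordinal outcomes dichotomized, continuous scores and
# age excluded); the GGM adds the continuous scores; the MGM adds age.
family_inputs <- function(dataset) {
  specs <- dataset$specs
  vals <- dataset$values
  shcs <- specs$name[specs$role == "shc"]
  bin <- as.data.frame(vals[, shcs, drop = FALSE])
  for (oc in specs$name[specs$role == "outcome"]) {
    i <- match(oc, specs$name)
    if (specs$kind[i] == "binary") {
      bin[[oc]] <- vals[[oc]]
    } else if (specs$kind[i] == "ordinal") {
      scale <- if (max(specs$levels[[i]]) == 6) "lisat6" else "qol5"
      bin[[oc]] <- dichotomize_outcome(vals[[oc]], scale)
    }
  }
  cont <- specs$name[specs$role == "outcome" & specs$kind == "continuous"]
  ggm <- cbind(bin, vals[, cont, drop = FALSE])
  mgm <- ggm
  if ("Age" %in% specs$name) mgm$Age <- vals$Age
  kinds <- ifelse(names(mgm) %in% c(cont, "Age"), "continuous", "binary")
  list(ising = bin, ggm = ggm, mgm = mgm, mgm_kinds = kinds, shcs = shcs)
}

#' Run the full network-to-short-form analysis pipeline
#'
#' Executes, per cohort: bivariate screening of every SHC item against the
#' five outcomes; the three network fits (GGM over SHCs + all outcomes,
#' Ising over binary nodes only, MGM over the mixed node set including
#' age); centrality tables; optional bootstrap stability; and per-model
#' isolation sets. Removal sets derived per cohort are unioned into one
#' generalized reduced index, and the full and reduced indices are compared
#' by outcome regressions on every cohort.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result`: `cohorts` (per-cohort list
#'   with `screen`, `models`, `centrality`, `stability`, `isolation_sets`,
#'   `bivariate_null`, `removal_set`), `shortform` (a `shortform_report`),
#'   `comparison` (per-cohort [compare_indices()] results), `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(tag, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage [", tag, "] failed: ", conditionMessage(e),
           call. = FALSE))
  }
  cohort_results <- list()
  isolation_all <- list()
  null_all <- list()
  removal_union <- character(0)
  shcs_ref <- NULL

  for (ci in seq_along(config$cohorts)) {
    dataset <- stage("coding", resolve_cohort(config$cohorts[[ci]]))
    label <- dataset$cohort_label
    inputs <- family_inputs(dataset)
    shcs_ref <- inputs$shcs

    screen <- stage("screening", screen_all(dataset, alpha = config$alpha))
    bnull <- null_items(screen, alpha = config$alpha)

    models <- list(
      ggm = stage("fit_ggm", fit_ggm(inputs$ggm, gamma = config$gamma_ggm)),
      ising = stage("fit_ising",
                    fit_ising(inputs$ising, gamma = config$gamma_ising)),
      mgm = stage("fit_mgm", fit_mgm(inputs$mgm, inputs$mgm_kinds,
                                     gamma = config$gamma_mgm)))
    centr <- lapply(models, centrality_table)
    iso <- lapply(models, isolated_nodes, node_subset = inputs$shcs)

    stab <- NULL
    if (isTRUE(config$do_stability))
      stab <- stage("stability", stability_report(
        inputs$ggm, function(d) fit_ggm(d, gamma = config$gamma_ggm),
        B_edges = config$B_edges, B_drop = config$B_drop,
        seed = config$seed + ci))

    removed <- stage("removal",
                     derive_removal_set(iso, bnull, rule = config$rule))
    removal_union <- union(removal_union, removed)
    isolation_all[[label]] <- iso
    null_all[[label]] <- bnull
    cohort_results[[label]] <- list(dataset = dataset, screen = screen,
                                    bivariate_null = bnull, models = models,
                                    centrality = centr, stability = stab,
                                    isolation_sets = iso,
                                    removal_set = removed)
  }

  retained <- setdiff(shcs_ref, removal_union)
  index_full <- mmi_definition(shcs_ref)
  index_reduced <- mmi_definition(retained)
  shortform <- structure(list(isolation_sets = isolation_all,
                              bivariate_null = null_all,
                              removal_set = sort(removal_union),
                              retained_index = index_reduced,
                              rule_used = list(rule = config$rule,
                                               alpha = config$alpha)),
                         class = "shortform_report")

  comparison <- lapply(cohort_results, function(cr)
    stage("comparison", compare_indices(cr$dataset, index_full,
                                        index_reduced)))

  structure(list(cohorts = cohort_results, shortform = shortform,
                 comparison = comparison, config = config),
            class = "pipeline_result")
}

#' @export
print.shortform_report <- function(x, ...) {
  cat("<shortform_report> rule:", x$rule_used$rule, "\n  removed (",
      length(x$removal_set), "): ",
      paste(x$removal_set, collapse = ", "), "\n  retained index: MMI-",
      length(x$retained_index$item_names), "\n", sep = "")
  invisible(x)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>", length(x$cohorts), "cohort(s)\n")
  print(x$shortform)
  invisible(x)
}

#' Serialize a pipeline result to a directory
#'
#' Writes the short-form report and run manifest as JSON, the retained
#' index as a one-column text list, each fitted network as JSON + edge-list
#' CSV, the screening tables and centrality tables as CSV, and the
#' regression comparisons as CSV.
#'
#' @param result A [run_pipeline()] result.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_pipeline <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sf <- result$shortform
  jsonlite::write_json(
    list(removal_set = sf$removal_set,
         retained_index = sf$retained_index$item_names,
         rule_used = sf$rule_used,
         bivariate_null = sf$bivariate_null,
         isolation_sets = sf$isolation_sets),
    file.path(dir, "shortform_report.json"), auto_unbox = TRUE, digits = NA)
  writeLines(sf$retained_index$item_names,
             file.path(dir, "retained_index.txt"))
  jsonlite::write_json(
    list(seed = result$config$seed, rule = result$config$rule,
         alpha = result$config$alpha,
         gamma = list(ggm = result$config$gamma_ggm,
                      ising = result$config$gamma_ising,
                      mgm = result$config$gamma_mgm),
         r_version = as.character(getRversion()),
         package_version = as.character(
           utils::packageVersion("mminet"))),
    file.path(dir, "run_manifest.json"), auto_unbox = TRUE)
  for (label in names(result$cohorts)) {
    cr <- result$cohorts[[label]]
    utils::write.csv(as.data.frame(cr$screen),
                     file.path(dir, sprintf("screen_%s.csv", label)),
                     row.names = FALSE)
    for (fam in names(cr$models)) {
      write_network_json(cr$models[[fam]],
                         file.path(dir, sprintf("network_%s_%s.json",
                                                label, fam)),
                         edges_csv = file.path(dir,
                                               sprintf("edges_%s_%s.csv",
                                                       label, fam)))
      utils::write.csv(as.data.frame(cr$centrality[[fam]]),
                       file.path(dir, sprintf("centrality_%s_%s.csv",
                                              label, fam)),
                       row.names = FALSE)
    }
    write_comparison_csv(result$comparison[[label]],
                         file.path(dir, paste0("comparison_", label)))
  }
  invisible(dir)
}
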