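test_that("isolated_nodes uses an exact zero-degree criterion", {
  w0 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  m0 <- network_model("ising", w0, gamma = 0.25)
  expect_setequal(isolated_nodes(m0), letters[1:4])

  w1 <- w0; w1[1, 2] <- w1[2, 1] <- 1e-9
  m1 <- network_model("ising", w1, gamma = 0.25)
  expect_setequal(isolated_nodes(m1), c("c", "d"))
  expect_setequal(isolated_nodes(m1, c("a", "c")), "c")
  expect_error(isolated_nodes(m1, "nope"), "nope")
})

test_that("removal-set rules combine isolation and bivariate nullity", {
  iso <- list(c("A"), character(0), c("A", "C"))
  expect_setequal(derive_removal_set(iso, c("A", "B")), "A")

  known_null <- c("Can", "DVT", "Dia", "HBP", "LD")
  out <- derive_removal_set(list(), known_null, rule = "null_only")
  expect_setequal(out, known_null)
  expect_length(out, 5)

  expect_setequal(derive_removal_set(iso, c("A", "C"),
                                     rule = "isolated_in_all"),
                  character(0))
  expect_setequal(derive_removal_set(list(c("A", "B"), c("A")), "Z",
                                     rule = "isolated_in_all"), "A")

  # no-op inputs
  expect_length(derive_removal_set(list(character(0)), character(0)), 0)
  # isolation-based rules need models
  expect_error(derive_removal_set(list(), "A"), "at least one")
  # provenance recorded
  expect_identical(attr(out, "rule"), "null_only")
})

test_that("reduced-index scores equal full scores minus the removed items", {
  sc <- generate_cohort(cohort_config(n = 200, seed = 19))
  removed <- c("Can", "DVT", "Dia", "HBP", "LD")
  full <- mmi_definition(shc_labels())
  reduced <- mmi_definition(setdiff(shc_labels(), removed))
  s_full <- score_mmi(sc$dataset, full)
  s_red <- score_mmi(sc$dataset, reduced)
  rem_sum <- rowSums(sc$dataset$values[, removed])
  expect_identical(s_red, as.integer(s_full - rem_sum))
  expect_length(reduced$item_names, 25)
})

test_that("the pipeline is deterministic and structurally complete", {
  cfg <- pipeline_config(cohort_config(n = 400, seed = 21), seed = 3)
  pr1 <- run_pipeline(cfg)
  pr2 <- run_pipeline(cfg)
  expect_identical(pr1$shortform$removal_set, pr2$shortform$removal_set)
  expect_identical(pr1$cohorts[[1]]$models$ggm$weights,
                   pr2$cohorts[[1]]$models$ggm$weights)

  cr <- pr1$cohorts[[1]]
  expect_named(cr$models, c("ggm", "ising", "mgm"))
  expect_equal(nrow(cr$screen), 150)
  # Ising node set excludes the continuous scores and age
  expect_false(any(c("PCS", "MCS", "Age") %in%
                     cr$models$ising$node_names))
  expect_true(all(c("PCS", "MCS") %in% cr$models$ggm$node_names))
  expect_true("Age" %in% cr$models$mgm$node_names)
  # retained index partitions the instrument
  expect_setequal(c(pr1$shortform$removal_set,
                    pr1$shortform$retained_index$item_names),
                  shc_labels())
  # comparison ran on all five outcomes with matched rows
  ag <- pr1$comparison[[1]]$agreement
  expect_equal(nrow(ag), 5)
  expect_true(all(ag$n_used == ag$n_used[1]))
})

test_that("pipeline artifacts serialize to a results directory", {
  dir <- withr::local_tempdir()
  pr <- run_pipeline(pipeline_config(cohort_config(n = 300, seed = 22)))
  write_pipeline(pr, dir)
  expect_true(file.exists(file.path(dir, "shortform_report.json")))
  expect_true(file.exists(file.path(dir, "retained_index.txt")))
  expect_true(file.exists(file.path(dir, "run_manifest.json")))
  expect_true(file.exists(file.path(dir, "network_synthetic_ggm.json")))
  rep <- jsonlite::fromJSON(file.path(dir, "shortform_report.json"))
  expect_setequal(c(rep$removal_set, rep$retained_index), shc_labels())
})

test_that("a no-structure cohort mostly yields an empty removal set", {
  # zero planted network and no outcome links: isolation is ubiquitous but
  # bivariate nullity must hold on all five outcomes simultaneously, so the
  # default rule removes only chance items; just require no systematic
  # removal of connected items (there are none) and rule sanity
  tn <- make_truth_network(shc_labels())
  tn$fields <- rep(stats::qlogis(0.35), 30)
  tn$isolated <- character(0)
  sc <- generate_cohort(cohort_config(n = 1000, truth = tn,
                                      outcome_effect = 0, seed = 23))
  pr <- run_pipeline(pipeline_config(sc))
  # every SHC is isolated in truth; removals can only come from the
  # bivariate null set
  expect_true(all(pr$shortform$removal_set %in%
                    pr$cohorts[[1]]$bivariate_null))
})
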