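test_that("SHC responses code to 0/1 with 'do not know' counted as absent", {
  expect_identical(code_shc(c("present", "absent", "do_not_know")),
                   c(1L, 0L, 0L))
  expect_identical(code_shc(c("present", NA, "missing")), c(1L, NA, NA))
  expect_identical(code_shc(c(0, 1, NA)), c(0L, 1L, NA))
  expect_error(code_shc("maybe"), "maybe")
  expect_error(code_shc(c(0, 2)), "non-binary")
})

test_that("ordinal ratings dichotomize at the satisfied cut of each scale", {
  expect_identical(dichotomize_outcome(1:6, "lisat6"),
                   c(0L, 0L, 0L, 0L, 1L, 1L))
  expect_identical(dichotomize_outcome(1:5, "qol5"),
                   c(0L, 0L, 0L, 1L, 1L))
  expect_identical(dichotomize_outcome(c(NA, 5L), "qol5"), c(NA, 1L))
  # configurable QoL cut
  expect_identical(dichotomize_outcome(3L, "qol5", qol_cut = 3L), 1L)
  expect_error(dichotomize_outcome(7, "lisat6"), "out of range")
  expect_error(dichotomize_outcome(0, "qol5"), "out of range")
})

test_that("MMI score is the item sum, bounded by index size, NA-propagating", {
  n <- 20
  vals <- as.data.frame(matrix(1L, n, 30, dimnames = list(NULL, shc_labels())))
  specs <- do.call(survey_specs,
                   lapply(shc_labels(), variable_spec, kind = "binary",
                          role = "shc"))
  ds <- survey_dataset(vals, specs)
  full <- mmi_definition(shc_labels())
  expect_identical(score_mmi(ds, full), rep(30L, n))

  vals0 <- vals; vals0[] <- 0L
  expect_identical(score_mmi(survey_dataset(vals0, specs), full),
                   rep(0L, n))

  reduced <- mmi_definition(setdiff(shc_labels(),
                                    c("Can", "DVT", "Dia", "HBP", "LD")))
  expect_identical(score_mmi(ds, reduced), rep(25L, n))

  vals_na <- vals; vals_na[1, "AD"] <- NA
  s <- score_mmi(survey_dataset(vals_na, specs), full)
  expect_true(is.na(s[1]))
  expect_identical(s[-1], rep(30L, n - 1))

  expect_error(score_mmi(ds, mmi_definition("NotAnItem")), "NotAnItem")
})

test_that("adding a present condition never decreases the MMI score", {
  specs <- do.call(survey_specs,
                   lapply(shc_labels(), variable_spec, kind = "binary",
                          role = "shc"))
  full <- mmi_definition(shc_labels())
  set.seed(42)
  for (rep in 1:20) {
    vals <- as.data.frame(matrix(rbinom(10 * 30, 1, 0.4), 10, 30,
                                 dimnames = list(NULL, shc_labels())))
    s0 <- score_mmi(survey_dataset(vals, specs), full)
    i <- sample.int(10, 1); j <- sample(shc_labels(), 1)
    vals[i, j] <- 1L
    s1 <- score_mmi(survey_dataset(vals, specs), full)
    expect_true(all(s1 >= s0))
  }
})

test_that("variable specs enforce the coding invariants", {
  expect_error(variable_spec("AD", "continuous", "shc"), "binary")
  expect_error(variable_spec("x", "binary", "covariate", levels = c(1, 2)),
               "levels")
  expect_error(variable_spec("x", "ordinal", "outcome", levels = c(1, 3)),
               "consecutive")
  expect_error(survey_specs(variable_spec("a", "binary", "shc"),
                            variable_spec("a", "binary", "shc")),
               "duplicate")
})

test_that("cohort CSV round-trips with coding applied on load", {
  specs <- survey_specs(
    variable_spec("AD", "binary", "shc"),
    variable_spec("BI", "binary", "shc"),
    variable_spec("PCS", "continuous", "outcome"))
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,AD,BI,PCS,Extra",
               "1,present,absent,40.5,x",
               "2,do_not_know,present,33.1,y",
               "3,absent,do_not_know,28.0,z"), tmp)
  expect_warning(ds <- load_cohort(tmp, specs), "Extra")
  expect_identical(ds$values$AD, c(1L, 0L, 0L))
  expect_identical(ds$values$BI, c(0L, 1L, 0L))
  expect_equal(dim(ds$values), c(3L, 4L))   # id + 3 declared

  # full write/load round trip preserves coded values
  out <- withr::local_tempfile(fileext = ".csv")
  write_cohort(ds, out)
  expect_true(file.exists(paste0(out, ".meta.json")))
  ds2 <- load_cohort(out, specs, cohort_label = ds$cohort_label)
  expect_identical(ds2$values, ds$values)

  # schema errors
  specs_more <- rbind(specs, variable_spec("MCS", "continuous", "outcome"))
  expect_error(load_cohort(tmp, specs_more), "MCS")
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,AD,BI,PCS", "1,present,absent,notanumber"), bad)
  expect_error(load_cohort(bad, specs), "row 1")
})

test_that("spec files and bundled example cohort load and code correctly", {
  specs <- read_variable_specs(system.file("extdata", "example_specs.json",
                                           package = "mminet"))
  expect_equal(nrow(specs), 8)
  expect_identical(specs$levels[[match("LiSAT", specs$name)]], 1:6)
  ds <- load_cohort(system.file("extdata", "example_cohort.csv",
                                package = "mminet"), specs)
  expect_identical(ds$values$AD, c(1L, 0L, 0L, 1L, 0L, 1L))   # do_not_know -> 0
  expect_identical(ds$values$UTI[4], 0L)
  expect_equal(nrow(ds$values), 6)
})

test_that("survey_dataset validates binary columns and duplicate ids", {
  specs <- survey_specs(variable_spec("AD", "binary", "shc"))
  expect_error(survey_dataset(data.frame(AD = c(0, 2)), specs), "0/1")
  expect_error(survey_dataset(data.frame(id = c(1, 1), AD = c(0, 1)), specs),
               "duplicate")
})
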