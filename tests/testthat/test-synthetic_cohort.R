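test_that("truth networks are symmetric with exactly the listed edges", {
  tn <- make_truth_network(paste0("V", 1:4),
                           data.frame(i = 1, j = 2, weight = 0.5))
  expect_identical(rowSums(tn$weights != 0), c(V1 = 1, V2 = 1, V3 = 0,
                                               V4 = 0))
  expect_identical(tn$weights[1, 2], 0.5)
  expect_identical(tn$weights, t(tn$weights))

  empty <- make_truth_network(paste0("V", 1:3))
  expect_true(all(empty$weights == 0))

  expect_error(
    make_truth_network(paste0("V", 1:4),
                       data.frame(i = 3, j = 4, weight = 0.4),
                       isolated = "V4"),
    "isolated")
})

test_that("Gaussian sampler reproduces the planted partial correlations", {
  # empty graph: all pairwise correlations near zero
  tn0 <- make_truth_network(paste0("V", 1:5), kinds = "continuous")
  x0 <- sample_gaussian(tn0, 10000, seed = 1)
  r <- cor(x0)
  expect_lt(max(abs(r[upper.tri(r)])), 0.05)

  # single planted edge: sample partial correlation near 0.5 (the oracle is
  # the inverse of the implied precision matrix)
  tn1 <- make_truth_network(paste0("V", 1:4),
                            data.frame(i = 1, j = 2, weight = 0.5),
                            kinds = "continuous")
  x1 <- sample_gaussian(tn1, 20000, seed = 2)
  K <- solve(cor(x1))
  pc12 <- -K[1, 2] / sqrt(K[1, 1] * K[2, 2])
  expect_lt(abs(pc12 - 0.5), 0.03)

  # determinism
  expect_identical(sample_gaussian(tn1, 100, seed = 7),
                   sample_gaussian(tn1, 100, seed = 7))

  # non-PD truth rejected with the offending eigenvalue named
  bad <- make_truth_network(paste0("V", 1:3),
                            data.frame(i = c(1, 1, 2), j = c(2, 3, 3),
                                       weight = 0.9),
                            kinds = "continuous")
  expect_error(sample_gaussian(bad, 10), "eigenvalue")
})

test_that("Gibbs sampler matches exhaustive Ising enumeration", {
  # zero fields, zero couplings: fair coins
  tn0 <- make_truth_network(paste0("V", 1:4))
  tn0$fields <- rep(0, 4)
  x0 <- sample_ising_gibbs(tn0, 10000, seed = 1)
  expect_true(all(colMeans(x0) > 0.47 & colMeans(x0) < 0.53))

  # 2-node coupling 1.0: P(both equal) matches enumeration
  tn2 <- make_truth_network(c("a", "b"),
                            data.frame(i = "a", j = "b", weight = 1))
  tn2$fields <- c(0, 0)
  x2 <- sample_ising_gibbs(tn2, 20000, seed = 2)
  ex <- ising_exact(tn2$weights, tn2$fields)
  p_eq_true <- sum(ex$probs[ex$states[, 1] == ex$states[, 2]])
  expect_lt(abs(mean(x2[, 1] == x2[, 2]) - p_eq_true), 0.02)
  # positive coupling implies positive phi correlation (enumeration sign)
  expect_gt(cor(x2[, 1], x2[, 2]), 0)

  # determinism
  expect_identical(sample_ising_gibbs(tn2, 50, seed = 9),
                   sample_ising_gibbs(tn2, 50, seed = 9))

  # continuous node rejected
  tnc <- make_truth_network(c("a", "b"), kinds = c("binary", "continuous"))
  expect_error(sample_ising_gibbs(tnc, 10), "binary")
})

test_that("sampled pairwise moments converge to enumeration values", {
  tn <- make_truth_network(paste0("V", 1:5),
                           data.frame(i = c(1, 2, 3), j = c(2, 3, 4),
                                      weight = c(1, -0.8, 0.6)))
  tn$fields <- rep(-0.3, 5)
  mom <- ising_exact_moments(tn$weights, tn$fields)
  x <- sample_ising_gibbs(tn, 20000, seed = 3)
  expect_lt(max(abs(colMeans(x) - mom$marginals)), 0.03)
  emp_pair <- crossprod(x) / nrow(x)
  expect_lt(max(abs(emp_pair - mom$pair)), 0.03)
})

test_that("generated cohorts honour the planted outcome structure", {
  # null outcome effect: index uncorrelated with every outcome
  sc0 <- generate_cohort(cohort_config(n = 5000, outcome_effect = 0,
                                       seed = 11))
  v <- sc0$dataset$values
  mmi <- score_mmi(sc0$dataset, mmi_definition(shc_labels()))
  for (oc in c("FNCNR", "PCS", "MCS", "LiSAT", "QoL"))
    expect_lt(abs(cor(mmi, v[[oc]])), 0.05)

  # positive effect: logistic fit of the unmet-need flag on the index
  # recovers a positive coefficient
  sc1 <- generate_cohort(cohort_config(n = 3000, seed = 12))
  v1 <- sc1$dataset$values
  mmi1 <- score_mmi(sc1$dataset, mmi_definition(shc_labels()))
  cf <- coef(glm(v1$FNCNR ~ mmi1, family = binomial()))
  expect_gt(cf[["mmi1"]], 0)

  # planted isolated items: truth rows all zero, and empirically
  # near-independent of the other items
  iso <- sc1$truth$isolated
  expect_true(all(rowSums(sc1$truth$weights[iso, ]) == 0))
  phi <- cor(v1[, shc_labels()])
  others <- setdiff(shc_labels(), iso)
  expect_lt(max(abs(phi[iso, others])), 0.08)

  # reproducibility and the minimum-size guard
  sc1b <- generate_cohort(cohort_config(n = 3000, seed = 12))
  expect_identical(sc1$dataset$values, sc1b$dataset$values)
  expect_error(cohort_config(n = 5), "at least 10")
})
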