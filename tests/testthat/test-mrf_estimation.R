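test_that("GGM at vanishing penalty matches the closed-form partial correlation", {
  # three standardized variables with all pairwise correlations 0.5:
  # (r_xy - r_xz r_zy) / sqrt((1 - r_xz^2)(1 - r_zy^2)) = 0.25/0.75 = 1/3
  S <- matrix(0.5, 3, 3); diag(S) <- 1
  m <- ggm_from_correlation(S, n = 1000, gamma = 0.5, n_lambda = 60,
                            lambda_min_ratio = 1e-6)
  expect_lt(max(abs(m$weights[upper.tri(m$weights)] - 1 / 3)), 1e-6)
})

test_that("GGM returns empty networks on independent data and recovers planted edges", {
  empties <- vapply(1:5, function(s) {
    tn0 <- make_truth_network(paste0("V", 1:8), kinds = "continuous")
    x <- sample_gaussian(tn0, 5000, seed = 30 + s)
    sum(fit_ggm(x)$weights != 0) == 0
  }, logical(1))
  expect_gte(sum(empties), 4)

  tn1 <- make_truth_network(paste0("V", 1:6),
                            data.frame(i = 1, j = 2, weight = 0.5),
                            kinds = "continuous")
  x1 <- sample_gaussian(tn1, 5000, seed = 77)
  m <- fit_ggm(x1)
  expect_gt(m$weights[1, 2], 0)
  expect_lt(abs(m$weights[1, 2] - 0.5), 0.1)
})

test_that("fitted weight matrices satisfy the structural invariants", {
  tn <- ggm_truth_p10()
  x <- sample_gaussian(tn, 2000, seed = 4)
  for (m in list(fit_ggm(x),
                 fit_ising(sample_ising_gibbs(ising_truth_p10(), 2000,
                                              seed = 5)))) {
    expect_identical(m$weights, t(m$weights))
    expect_true(all(diag(m$weights) == 0))
  }
  mg <- fit_ggm(x)
  expect_true(all(abs(mg$weights) <= 1))
  # weights -> precision pattern -> weights is idempotent
  w <- mg$weights
  K2 <- -w; diag(K2) <- 1
  expect_equal(precision_to_pcor(K2), w, tolerance = 1e-12)
})

test_that("edge counts are non-increasing in gamma", {
  tn <- ggm_truth_p10(weight = 0.2)
  x <- sample_gaussian(tn, 800, seed = 6)
  ne <- vapply(c(0, 0.5, 1), function(g) sum(fit_ggm(x, gamma = g)$weights != 0),
               numeric(1))
  expect_true(all(diff(ne) <= 0))

  xb <- sample_ising_gibbs(ising_truth_p10(), 800, seed = 7)
  nei <- vapply(c(0, 0.5, 1),
                function(g) sum(fit_ising(xb, gamma = g)$weights != 0),
                numeric(1))
  expect_true(all(diff(nei) <= 0))
})

test_that("GGM input validation names the offending column", {
  x <- cbind(a = rnorm(50), b = rep(1, 50))
  expect_error(fit_ggm(x), "b")
  expect_warning(fit_ggm(matrix(rnorm(5 * 6), 5,
                                dimnames = list(NULL, paste0("v", 1:6)))),
                 "n <= p")
})

test_that("Ising fits are empty under independence and recover a planted coupling", {
  tn0 <- make_truth_network(paste0("V", 1:4))
  tn0$fields <- rep(0, 4)
  x0 <- sample_ising_gibbs(tn0, 5000, seed = 8)
  expect_true(all(fit_ising(x0)$weights == 0))

  tn2 <- make_truth_network(c("a", "b"),
                            data.frame(i = "a", j = "b", weight = 1))
  tn2$fields <- c(0, 0)
  x2 <- sample_ising_gibbs(tn2, 5000, seed = 9)
  m2 <- fit_ising(x2)
  expect_gt(m2$weights[1, 2], 0)
  expect_lt(abs(m2$weights[1, 2] - 1), 0.2)

  expect_error(fit_ising(cbind(a = c(0, 1, 2, 1), b = c(0, 1, 0, 1))),
               "a")
  expect_error(fit_ising(cbind(a = rep(1, 20), b = rbinom(20, 1, 0.5))),
               "constant")
})

test_that("nodewise symmetrization applies the AND/OR rules", {
  B <- matrix(0, 3, 3)
  B[1, 2] <- 0.8   # node 2 selected node 1 ...
  B[2, 1] <- 0.6   # ... and vice versa: kept under both rules
  B[3, 2] <- 0.4   # selected in one direction only
  wa <- symmetrize_nodewise(B, "AND")
  expect_equal(wa[1, 2], 0.7)
  expect_equal(wa[2, 3], 0)      # absent under AND
  wo <- symmetrize_nodewise(B, "OR")
  expect_equal(wo[1, 2], 0.7)
  expect_equal(wo[2, 3], 0.2)    # missing direction contributes 0 to the mean
  expect_identical(wa, t(wa))
})

test_that("MGM matches the single-type estimators on single-type data", {
  # all-continuous: same edge pattern as the GGM
  tn <- make_truth_network(paste0("V", 1:6),
                           data.frame(i = c(1, 3, 5), j = c(2, 4, 6),
                                      weight = 0.4),
                           kinds = "continuous")
  x <- sample_gaussian(tn, 4000, seed = 10)
  pat_mgm <- fit_mgm(x, kinds = rep("continuous", 6))$weights != 0
  pat_ggm <- fit_ggm(x)$weights != 0
  expect_identical(pat_mgm, pat_ggm)

  # all-binary: same edge pattern as the Ising fit
  tb <- make_truth_network(paste0("V", 1:6),
                           data.frame(i = c(1, 3, 5), j = c(2, 4, 6),
                                      weight = 1.2))
  tb$fields <- rep(-0.5, 6)
  xb <- sample_ising_gibbs(tb, 4000, seed = 11)
  pat_mgmb <- fit_mgm(xb, kinds = rep("binary", 6))$weights != 0
  pat_isi <- fit_ising(xb)$weights != 0
  expect_identical(pat_mgmb, pat_isi)
})

test_that("MGM recovers a planted binary-to-continuous edge", {
  set.seed(12)
  n <- 5000
  b <- rbinom(n, 1, 0.4)
  x <- cbind(b = b,
             y = b * 1 + rnorm(n),          # shift of 1 SD of the noise
             z = rnorm(n), u = rnorm(n))
  m <- fit_mgm(x, kinds = c("binary", rep("continuous", 3)))
  expect_gt(m$weights["b", "y"], 0)
  expect_true(all(m$weights["z", c("b", "y", "u")] == 0))

  expect_error(fit_mgm(cbind(a = c(1, 2, 3, 1), b = rnorm(4)),
                       kinds = c("ordinal", "continuous")),
               "unsupported")
})
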