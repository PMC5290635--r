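test_that("a tight single cluster fits with k = 1 and weight 1", {
  x <- withr::with_seed(7, matrix(rnorm(300, mean = 0.8, sd = 0.01), ncol = 3))
  fit <- fit_mixture(x, k = 1, family = "spherical", seed = 1)
  expect_equal(fit$k, 1)
  expect_equal(unname(fit$weights), 1)
  expect_equal(unname(fit$means[1, ]), colMeans(x), tolerance = 1e-6)
  expect_true(all(fit$assignments == 1))
})

test_that("well-separated components are recovered with >= 99% accuracy", {
  d <- two_blob_data(n_each = 200, sep = 5, seed = 3)
  for (fam in c("spherical", "diagonal", "full")) {
    fit <- fit_mixture(d$x, k = 2, family = fam, seed = 5)
    expect_gte(binary_accuracy(fit$assignments, d$labels), 0.99)
  }
})

test_that("preconditions: k > n errors, identical rows with k > 1 error", {
  x <- matrix(rnorm(9), 3, 3)
  expect_error(fit_mixture(x, k = 5), "n = 3")
  same <- matrix(0.5, 10, 3)
  expect_error(fit_mixture(same, k = 2), "degenerate")
  expect_silent(fit <- fit_mixture(same, k = 1))
})

test_that("EM log-likelihood is non-decreasing and responsibilities sum to 1", {
  d <- two_blob_data(n_each = 60, sep = 3, seed = 11)
  for (fam in c("spherical", "diagonal", "full")) {
    fit <- fit_mixture(d$x, k = 2, family = fam, seed = 2)
    expect_true(all(diff(fit$loglik_trace) >= -1e-8 * abs(fit$loglik)))
    expect_equal(rowSums(fit$responsibilities), rep(1, nrow(d$x)),
                 tolerance = 1e-9)
    expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
    expect_equal(fit$bic, fit$n_params * log(fit$n) - 2 * fit$loglik)
    expect_equal(fit$assignments, max.col(fit$responsibilities,
                                          ties.method = "first"))
  }
})

test_that("nested covariance families order the log-likelihood at the k = 1 MLE", {
  x <- withr::with_seed(9, {
    z <- matrix(rnorm(600), ncol = 3)
    z %*% matrix(c(1, .5, 0, 0, 1, .3, 0, 0, 1), 3, 3)  # correlated
  })
  ll <- vapply(c("spherical", "diagonal", "full"), function(fam)
    fit_mixture(x, 1, fam)$loglik, numeric(1))
  expect_true(ll["full"] >= ll["diagonal"] - 1e-9)
  expect_true(ll["diagonal"] >= ll["spherical"] - 1e-9)
})

test_that("fits are deterministic given the seed", {
  d <- two_blob_data(n_each = 50, sep = 4, seed = 21)
  f1 <- fit_mixture(d$x, 2, "diagonal", seed = 13)
  f2 <- fit_mixture(d$x, 2, "diagonal", seed = 13)
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(f1$assignments, f2$assignments)
})

test_that("BIC selects two components on two-component data in >= 90% of seeds", {
  hits <- 0
  for (s in 1:20) {
    d <- two_blob_data(n_each = 200, sep = 5, seed = 100 + s)
    fit <- select_model(d$x, k_max = 6, seed = s, n_restarts = 3)
    hits <- hits + (fit$k == 2)
  }
  expect_gte(hits, 18)
})

test_that("BIC penalty prefers k = 1 on small pure-noise data, and k_max = 1 is identity", {
  x <- withr::with_seed(5, matrix(rnorm(30), 10, 3))
  fit <- select_model(x, k_max = 3, seed = 1)
  expect_equal(fit$k, 1)
  fit1 <- select_model(x, k_max = 1, seed = 1)
  ref <- fit_mixture(x, 1, "spherical", seed = 1)
  expect_equal(fit1$k, 1)
  expect_equal(fit1$loglik, ref$loglik, tolerance = 1e-9)
})

test_that("mixture fit agrees with the mclust reference on separated data", {
  library(mclust)
  d <- two_blob_data(n_each = 150, sep = 6, seed = 31)
  ours <- fit_mixture(d$x, 2, "full", seed = 2)
  ref <- mclust::Mclust(d$x, G = 2, modelNames = "VVV", verbose = FALSE)
  expect_equal(ours$loglik, ref$loglik, tolerance = 1e-3)
  expect_gte(binary_accuracy(ours$assignments, ref$classification), 0.99)
})

test_that("trajectory classification follows the presence rules", {
  expect_equal(trajectory_class(c(0.92, 0.88, 0.85)), "preserved")
  expect_equal(trajectory_class(c(0.60, 0.03, 0.01)), "lost")
  expect_equal(trajectory_class(c(0.02, 0.04, 0.45)), "emerged@3")
  expect_equal(trajectory_class(c(0.01, 0.45, 0.5)), "emerged@2")
  expect_equal(trajectory_class(c(0.5, 0.01, 0.6)), "transient")
  expect_equal(trajectory_class(c(0.01, 0.5, 0.01)), "transient")
  expect_equal(trajectory_class(c(0.05, 0.04, 0.02)), "transient")
  # threshold is a parameter
  expect_equal(trajectory_class(c(0.3, 0.3, 0.3), presence_threshold = 0.5),
               "transient")
})

test_that("evolution classes are invariant to component relabeling", {
  sim <- simulate_patient(seed = 17)
  ccf <- assemble_ccf_matrix(sim$variants_by_timepoint, sim$segments_by_timepoint,
                             sim$metas, depths_by_timepoint = sim$depths_by_timepoint)
  fit <- fit_mixture(ccf, 4, "diagonal", seed = 1)
  cl <- classify_clusters(fit)
  perm <- c(3, 1, 4, 2)
  fit2 <- fit
  fit2$means <- fit$means[perm, ]
  fit2$weights <- fit$weights[perm]
  fit2$covariances <- fit$covariances[perm]
  fit2$responsibilities <- fit$responsibilities[, perm]
  fit2$assignments <- max.col(fit2$responsibilities, ties.method = "first")
  cl2 <- classify_clusters(fit2)
  expect_setequal(paste(cl$evo_class, cl$size), paste(cl2$evo_class, cl2$size))
})
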