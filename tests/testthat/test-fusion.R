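test_that("gaussian density matches the closed form", {
  expect_equal(gaussian_density(0, 0, 1), 0.3989423, tolerance = 1e-6)
  expect_equal(gaussian_density(1, 0, 1), 0.2419707, tolerance = 1e-6)
  # symmetry about the mean
  for (d in c(0.1, 1, 2.5)) {
    expect_equal(gaussian_density(2 + d, 2, 0.7), gaussian_density(2 - d, 2, 0.7))
  }
  expect_error(gaussian_density(0, 0, 0), "positive")
})

test_that("batch standardization unifies score columns", {
  s <- matrix(c(0.2, 0.8, 0.8, 0.2), ncol = 2)  # rows sum to 1
  out <- unify_scores(list(s), batch_size = 64)
  expect_equal(out$scores[[1]][, 1], c(-1, 1))  # population std of {.2,.8} is .3
  expect_equal(out$scores[[1]][, 2], c(1, -1))
  # constant columns map to zeros under the unit-scale convention
  const <- matrix(c(0.5, 0.5, 0.5, 0.5), ncol = 2)
  expect_warning(out2 <- unify_scores(list(const), batch_size = 2),
                 "zero-variance")
  expect_true(all(out2$scores[[1]] == 0))
  # frozen statistics reproduce the fitted values exactly
  again <- unify_scores(list(s), unifier = out$unifier)
  expect_identical(again$scores[[1]], out$scores[[1]])
})

test_that("EM recovers a two-component Gaussian mixture", {
  set.seed(31)
  m <- 5000
  comp <- rbinom(m, 1, 0.5)
  y <- rnorm(m, mean = ifelse(comp == 1, 3, 0), sd = 1)
  # two mixture components observing the same scalar; quantile init breaks
  # the symmetry
  fit <- em_mixture(cbind(y, y),
                    mu = matrix(quantile(y, c(0.25, 0.75)), ncol = 1),
                    var = matrix(1, 2, 1), max_iter = 200, tol = 1e-8)
  mu_hat <- sort(fit$mu[, 1])
  expect_lt(abs(mu_hat[1] - 0), 0.1)
  expect_lt(abs(mu_hat[2] - 3), 0.1)
  expect_lt(max(abs(fit$weights - 0.5)), 0.05)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  # the log-likelihood trace never decreases
  expect_true(all(diff(fit$loglik) >= -1e-8))
})

test_that("EM log-likelihood is monotone over many random initializations", {
  set.seed(77)
  y <- c(rnorm(150, -1, 0.7), rnorm(150, 2, 1.2))
  for (rep in 1:100) {
    w0 <- runif(2); w0 <- w0 / sum(w0)
    fit <- em_mixture(cbind(y, y), weights = w0,
                      mu = matrix(rnorm(2, sd = 3), ncol = 1),
                      var = matrix(runif(2, 0.1, 4), ncol = 1),
                      max_iter = 30, tol = 0)
    expect_true(all(diff(fit$loglik) >= -1e-8))
    expect_true(all(fit$weights >= 0))
    expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  }
})

test_that("single-component fusion keeps weight 1", {
  set.seed(5)
  rn <- function(x) x / rowSums(x)
  s <- rn(matrix(runif(40), ncol = 4))
  labels <- factor(sample(letters[1:4], 10, replace = TRUE),
                   levels = letters[1:4])
  fp <- fit_fusion(list(s), labels, max_iter = 50)
  expect_equal(fp$weights, 1)
  fused <- fuse_predict(list(s), fp)
  expect_equal(unname(fused), unname(s), tolerance = 1e-12)
})

test_that("fusion combines component probabilities by learned weights", {
  # two components with opposite hard predictions fuse to symmetry under
  # equal weights
  a <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE)
  b <- matrix(c(0, 1, 1, 0), 2, byrow = TRUE)
  params <- structure(list(weights = c(0.5, 0.5), n_components = 2,
                           class_levels = c("x", "y")),
                      class = "dsn_fusion")
  expect_equal(unname(fuse_predict(list(a, b), params)),
               matrix(0.5, 2, 2))
  params$weights <- c(1, 0)
  expect_equal(unname(fuse_predict(list(a, b), params)), unname(a))
  expect_error(fuse_predict(list(a), params), "component count mismatch")
})

test_that("an accurate component is not hurt by uniform companions", {
  set.seed(13)
  m <- 200
  labels <- factor(sample(c("a", "b", "c"), m, replace = TRUE))
  perfect <- matrix(0.01, m, 3, dimnames = list(NULL, levels(labels)))
  perfect[cbind(seq_len(m), as.integer(labels))] <- 0.98
  perfect <- perfect / rowSums(perfect)
  uniform <- matrix(1 / 3, m, 3)
  # the uniform components are constant columns by construction
  fp <- suppressWarnings(fit_fusion(list(perfect, uniform, uniform), labels))
  expect_gte(fp$weights[1], 1 / 3)
  fused <- fuse_predict(list(perfect, uniform, uniform), fp)
  acc_fused <- mean(max.col(fused, "first") == as.integer(labels))
  acc_perfect <- mean(max.col(perfect, "first") == as.integer(labels))
  expect_gte(acc_fused, acc_perfect)
  expect_true(all(abs(rowSums(fused) - 1) < 1e-9))
})

test_that("fusion on classifier-like scores converges with a trace", {
  set.seed(21)
  m <- 300
  labels <- factor(sample(c("a", "b"), m, replace = TRUE))
  noisy <- function(q) {
    p <- matrix(runif(m * 2, 0.05, 0.3), m, 2)
    hit <- runif(m) < q
    p[cbind(which(hit), as.integer(labels)[hit])] <- 1
    p / rowSums(p)
  }
  comps <- list(noisy(0.9), noisy(0.6))
  fp <- fit_fusion(comps, labels, max_iter = 100, tol = 1e-6)
  expect_true(all(diff(fp$loglik) >= -1e-8))
  expect_lte(fp$iterations, 100)
  expect_equal(sum(fp$weights), 1, tolerance = 1e-9)
  expect_true(all(fp$var >= 1e-6 - 1e-12))
})
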