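test_that("Latin hypercube sampling stratifies each dimension", {
  x <- latin_hypercube(4, 1, seed = 3)
  expect_equal(sort(floor(x * 4)), 0:3)   # one point per quartile
  ## determinism under a fixed seed
  expect_identical(latin_hypercube(7, 2, seed = 9),
                   latin_hypercube(7, 2, seed = 9))
  ## stratification bound: empirical CDF within 1/n of uniform
  n <- 1000
  X <- latin_hypercube(n, 2, seed = 5)
  for (d in 1:2) {
    s <- sort(X[, d])
    expect_lt(max(abs(s - (seq_len(n) - 0.5) / n)), 1 / n)
  }
  ## bounds mapping
  b <- matrix(c(2, -1, 6, 1), 2, 2)
  Xb <- latin_hypercube(50, 2, bounds = b, seed = 1)
  expect_true(all(Xb[, 1] >= 2 & Xb[, 1] <= 6))
  expect_true(all(Xb[, 2] >= -1 & Xb[, 2] <= 1))
})

test_that("GP posterior interpolates and reverts to the prior", {
  X <- matrix(c(0.1, 0.3, 0.5, 0.7, 0.9), ncol = 1)
  y <- sin(6 * X[, 1])
  gp <- gp_posterior(X, y)
  pr <- gp$predict(X)
  expect_equal(pr$mean, y, tolerance = 1e-4)
  expect_true(all(pr$var <= 1e-6))
  ## far from all data: mean -> prior mean, variance -> prior amplitude
  far <- gp$predict(matrix(1e4, 1, 1))
  expect_equal(far$mean, mean(y), tolerance = 1e-8)
  expect_equal(far$var, gp$amp2, tolerance = 1e-8 * max(1, gp$amp2))
})

test_that("GP posterior algebra matches an independent dense-solve oracle", {
  set.seed(8)
  X <- matrix(runif(5), ncol = 1)
  y <- cos(4 * X[, 1]) + 0.3 * X[, 1]
  gp <- gp_posterior(X, y)
  Xs <- matrix(seq(0, 1, length.out = 11), ncol = 1)
  pr <- gp$predict(Xs)
  ## hand-rolled dense GP with the same hyperparameters, plain solve()
  k <- function(A, B) {
    r <- abs(outer(A[, 1], B[, 1], `-`)) / gp$ls
    gp$amp2 * (1 + sqrt(5) * r + 5 * r^2 / 3) * exp(-sqrt(5) * r)
  }
  K <- k(X, X) + diag(gp$jitter, 5)
  mu <- mean(y) + k(Xs, X) %*% solve(K, y - mean(y))
  var <- gp$amp2 - diag(k(Xs, X) %*% solve(K, t(k(Xs, X))))
  expect_equal(pr$mean, as.numeric(mu), tolerance = 1e-8)
  expect_equal(pr$var, pmax(as.numeric(var), 0), tolerance = 1e-8)
})

test_that("expected improvement matches closed forms and Monte Carlo", {
  ## zero variance at the incumbent: EI = 0
  expect_equal(expected_improvement(1.0, 0, 1.0), 0)
  ## pure exploitation limit: mean = best - 1, sd = 0 -> EI = 1
  expect_equal(expected_improvement(-1, 0, 0), 1)
  expect_true(all(expected_improvement(rnorm(50), abs(rnorm(50)), 0.2) >= 0))
  ## Monte-Carlo oracle: E[max(best - Y, 0)], Y ~ N(mean, sd^2)
  set.seed(12)
  for (k in 1:5) {
    m <- rnorm(1); s <- runif(1, 0.2, 2); best <- rnorm(1)
    yv <- pmax(best - rnorm(1e6, m, s), 0)
    mc <- mean(yv); se <- stats::sd(yv) / sqrt(1e6)
    expect_lt(abs(expected_improvement(m, s, best) - mc), 3 * se + 1e-8)
  }
})

test_that("admixture optimization recovers known optima at the stated budgets", {
  ## 1-D: budget 10 LHS + 3 EI points
  res <- optimize_admixture(function(b, cc) (b - 0.3)^2,
                            opt_config("1d", seed = 2))
  expect_equal(res$n_evaluations, 13L)
  expect_lt(abs(res$best_point[["b_epc"]] - 0.3), 0.05)
  expect_equal(res$best_point[["c_epc"]], 1 - res$best_point[["b_epc"]])
  ## 2-D: budget 40 + 20
  res2 <- optimize_admixture(function(b, cc) (b - 0.5)^2 + (cc - 0.5)^2,
                             opt_config("2d", seed = 4))
  expect_equal(res2$n_evaluations, 60L)
  expect_lt(max(abs(res2$best_point - 0.5)), 0.1)
  ## constant objective: budget accounting still exact
  resc <- optimize_admixture(function(b, cc) 1, opt_config("1d", seed = 6))
  expect_equal(resc$n_evaluations, 13L)
  expect_equal(resc$best_value, 1)
})

test_that("optimization is deterministic and caches repeated points", {
  obj_calls <- 0L
  obj <- function(b, cc) { obj_calls <<- obj_calls + 1L; (b - 0.4)^2 }
  r1 <- optimize_admixture(obj, opt_config("1d", seed = 11))
  calls1 <- obj_calls
  expect_lte(calls1, 13L)   # cache can only reduce distinct evaluations
  obj_calls <- 0L
  r2 <- optimize_admixture(obj, opt_config("1d", seed = 11))
  expect_identical(r1$points, r2$points)
  expect_identical(r1$values, r2$values)
  expect_identical(r1$best_point, r2$best_point)
  ## failed evaluations are recorded and skipped
  bad <- function(b, cc) if (b > 0.8) stop("fail") else (b - 0.3)^2
  rb <- optimize_admixture(bad, opt_config("1d", seed = 2))
  expect_equal(rb$n_evaluations, 13L)
  expect_true(any(!is.finite(rb$values)) || all(rb$points[, 1] <= 0.8))
  expect_true(is.finite(rb$best_value))
})

test_that("a synthetic linear PA model admixture is recovered within 0.05", {
  ## objective: RMSD of a PA model linear in (b, c) with known optimum at
  ## b* = 0.8 (1-D diagonal)
  entries <- load_dataset("PA21")[1:8, ]
  set.seed(21)
  slope <- runif(8, 5, 9)
  pa_model <- function(b, cc) entries$pa_exp_kcal +
    slope * (b - 0.8) + 0.5 * slope * (cc - 0.2)
  obj <- function(b, cc) {
    pa <- stats::setNames(pa_model(b, cc), entries$label)
    evaluate_dataset(entries, pa)$summary$RMSD
  }
  res <- optimize_admixture(obj, opt_config("1d", seed = 17))
  expect_lt(abs(res$best_point[["b_epc"]] - 0.8), 0.05)
})
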