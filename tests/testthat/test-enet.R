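# Shared fixture: a small standardized regression problem.
enet_fixture <- function(n = 6, p = 3, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  X <- scale(X)
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  y <- 100 + 50 * X[, 1] - 30 * X[, 2] + rnorm(n, 0, 5)
  list(X = X, y = y)
}

test_that("soft-thresholding shrinks toward zero", {
  expect_equal(soft_threshold(3, 1), 2)
  expect_equal(soft_threshold(-0.5, 1), 0)
  expect_equal(soft_threshold(-3, 1), -2)
  for (x in c(-2.5, 0, 1.3)) expect_equal(soft_threshold(x, 0), x)
})

test_that("the unpenalized fit equals ordinary least squares", {
  fx <- enet_fixture()
  fit <- fit_elastic_net(fx$X, fx$y, alpha_mix = 0.5, lambda_penalty = 0,
                         tol = 1e-12)
  ols <- coef(lm(fx$y ~ fx$X))
  expect_equal(unname(fit$weights), unname(ols[-1]), tolerance = 1e-6)
  expect_equal(fit$intercept, unname(ols[1]), tolerance = 1e-6)
  # single-predictor case: weight equals the OLS slope
  one <- fit_elastic_net(fx$X[, 1, drop = FALSE], fx$y, 0.5, 0, tol = 1e-12)
  expect_equal(unname(one$weights),
               unname(coef(lm(fx$y ~ fx$X[, 1]))[2]), tolerance = 1e-8)
})

test_that("penalties at or above lambda_max zero every weight", {
  fx <- enet_fixture()
  lmax <- max(abs(crossprod(fx$X, fx$y - mean(fx$y)))) / (6 * 0.5)
  for (lam in c(lmax, lmax * 2)) {
    fit <- fit_elastic_net(fx$X, fx$y, alpha_mix = 0.5, lambda_penalty = lam)
    expect_equal(unname(fit$weights), rep(0, 3))
    expect_equal(fit$intercept, mean(fx$y))
  }
})

test_that("the solution minimises the stated objective (derivative-free oracle)", {
  fx <- enet_fixture()
  for (lam in c(0.1, 1, 10)) {
    fit <- fit_elastic_net(fx$X, fx$y, alpha_mix = 0.5, lambda_penalty = lam,
                           tol = 1e-12)
    ours <- enet_objective(fx$X, fx$y, fit$intercept, fit$weights, 0.5, lam)
    # oracle: Nelder-Mead from the zero vector, never touching our solver
    obj <- function(b) {
      r <- fx$y - mean(fx$y) - as.vector(fx$X %*% b)
      sum(r^2) / 12 + lam * (0.5 * sum(abs(b)) + 0.25 * sum(b^2))
    }
    nm <- optim(rep(0, 3), obj, method = "Nelder-Mead",
                control = list(maxit = 50000, reltol = 1e-14))
    nm <- optim(nm$par, obj, method = "Nelder-Mead",
                control = list(maxit = 50000, reltol = 1e-14))
    expect_lte(ours, nm$value + 1e-6)
    expect_equal(ours, nm$value, tolerance = 1e-6)
  }
})

test_that("the objective never increases across coordinate-descent sweeps", {
  fx <- enet_fixture(n = 30, p = 8, seed = 2)
  for (lam in c(0.01, 0.5, 5)) {
    fit <- fit_elastic_net(fx$X, fx$y, alpha_mix = 0.5, lambda_penalty = lam,
                           trace = TRUE)
    tr <- fit$objective_trace
    expect_true(all(diff(tr) <= 1e-12))
  }
})

test_that("coefficients agree with an independent elastic-net implementation", {
  fx <- enet_fixture(n = 40, p = 6, seed = 3)
  # glmnet standardizes the response internally (1/n sd) and rescales the
  # penalty with it; on a unit-variance response that standardization is the
  # identity and both solvers minimise the same objective
  yc <- fx$y - mean(fx$y)
  ys <- yc / sqrt(mean(yc^2))
  for (lam in c(0.02, 0.2)) {
    fit <- fit_elastic_net(fx$X, ys, alpha_mix = 0.5, lambda_penalty = lam,
                           tol = 1e-12)
    g <- glmnet::glmnet(fx$X, ys, alpha = 0.5, lambda = lam,
                        standardize = FALSE, thresh = 1e-16)
    expect_equal(unname(fit$weights), as.vector(coef(g))[-1],
                 tolerance = 1e-6)
  }
})

test_that("weights vanish at lambda_max and sparsify monotonically along the path", {
  # orthogonal design: each coordinate is an independent soft-threshold, so
  # the count of active weights can only grow as the penalty relaxes (with a
  # correlated design, sign crossings can briefly re-zero a weight, which is
  # why this is a fixture property rather than a theorem)
  set.seed(4)
  n <- 32; p <- 8
  Q <- qr.Q(qr(matrix(rnorm(n * p), n, p))) * sqrt(n)
  b_true <- c(8, -6, 4, -3, 2, -1, 0.5, -0.2)
  y <- 100 + as.vector(Q %*% b_true) + rnorm(n, 0, 0.5)
  lmax <- max(abs(crossprod(Q, y - mean(y)))) / (n * 0.5)
  grid <- exp(seq(log(lmax), log(lmax * 1e-4), length.out = 40))
  path <- nmrclock:::enet_path(Q, y, 0.5, grid)
  # weights within float noise of the lambda_max stationarity boundary count
  # as zero
  nz <- colSums(abs(path$beta) > 1e-8)
  expect_equal(nz[1], 0)                      # all zero at lambda_max
  expect_true(all(diff(nz) >= 0))             # grid is descending in lambda
})

test_that("lambda selection behaves at the grid and signal extremes", {
  fx <- enet_fixture(n = 20, p = 4, seed = 5)
  # trivial grid returns lambda_max
  sel1 <- select_lambda(fx$X, fx$y, alpha_mix = 0.5, n_lambda = 1)
  lmaxs <- nmrclock:::lambda_max(nmrclock:::standardize_columns(fx$X)$X,
                                 fx$y, 0.5)
  expect_equal(sel1$lambda, lmaxs)
  # an exact linear signal survives selection with a nonzero weight
  y_lin <- 10 + 3 * fx$X[, 2]
  sel2 <- select_lambda(fx$X, y_lin, alpha_mix = 0.5, n_lambda = 50)
  fit <- fit_elastic_net(scale(fx$X), y_lin, 0.5, sel2$lambda)
  expect_true(fit$weights[2] != 0)
  # degenerate response is an explicit error
  expect_error(select_lambda(fx$X, rep(1, 20), 0.5), "zero variance")
})

test_that("the 1-SE rule shrinks pure noise to the empty model", {
  hits <- 0
  for (s in 1:50) {
    set.seed(s)
    X <- matrix(rnorm(20 * 5), 20, 5)
    y <- rnorm(20)
    sel <- select_lambda(X, y, alpha_mix = 0.5, n_lambda = 40)
    std <- nmrclock:::standardize_columns(X)
    fit <- fit_elastic_net(std$X, y, 0.5, sel$lambda)
    if (all(abs(fit$weights) < 1e-8)) hits <- hits + 1
  }
  expect_gte(hits, 45)  # >= 90% of seeds
})
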