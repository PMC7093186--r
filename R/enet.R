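#' Soft-thresholding operator
#'
#' The coordinate-descent kernel of the elastic net:
#' `sign(z) * max(|z| - gamma, 0)`.
#'
#' @param z Numeric.
#' @param gamma Non-negative threshold.
#' @return `z` shrunk toward zero by `gamma`.
#' @export
#' @examples
#' soft_threshold(3, 1)    # 2
#' soft_threshold(-0.5, 1) # 0
soft_threshold <- function(z, gamma) {
  stopifnot(all(gamma >= 0))
  sign(z) * pmax(abs(z) - gamma, 0)
}

#' Fit the elastic net at a fixed penalty by cyclic coordinate descent
#'
#' Minimises
#' `(1/2n) * sum((y - b0 - X b)^2) + lambda * (alpha * |b|_1 + (1-alpha)/2 * |b|_2^2)`
#' by cyclic coordinate descent with the soft-threshold update.  `X` must be
#' column-centred (typically also scaled to unit sd), so the intercept is
#' `mean(y)`.  Convergence is declared when the largest absolute coefficient
#' change in a full sweep drops below `tol`; non-convergence at `max_iter`
#' is an error reporting the last sweep's delta.
#'
#' @param X Column-centred numeric matrix, no missing values, n >= 2.
#' @param y Response (ages in weeks).
#' @param alpha_mix L1/L2 mixing weight in `[0, 1]` (1 = lasso, 0 = ridge).
#' @param lambda_penalty Non-negative overall penalty.
#' @param tol Convergence tolerance on coefficients.
#' @param max_iter Maximum full sweeps.
#' @param trace If `TRUE`, also return the objective value after every sweep.
#' @return List with `intercept`, `weights`, `n_sweeps`, and (if traced)
#'   `objective_trace`.
#' @export
fit_elastic_net <- function(X, y, alpha_mix = 0.5, lambda_penalty,
                            tol = 1e-8, max_iter = 100000L, trace = FALSE) {
  X <- as.matrix(X)
  stopifnot(!anyNA(X), !anyNA(y), nrow(X) == length(y), nrow(X) >= 2,
            alpha_mix >= 0, alpha_mix <= 1, lambda_penalty >= 0)
  fit <- enet_cd_path_cpp(X, as.numeric(y), alpha_mix,
                          as.numeric(lambda_penalty), tol,
                          as.integer(max_iter), trace)
  if (!fit$converged[1]) {
    stop("coordinate descent did not converge in ", max_iter,
         " sweeps (last max coefficient change ",
         format(fit$last_delta[1]), ")")
  }
  out <- list(intercept = fit$intercept,
              weights = setNames(fit$beta[, 1], colnames(X)),
              n_sweeps = fit$sweeps[1])
  if (trace) out$objective_trace <- fit$objective_trace[[1]]
  out
}

#' Elastic-net objective value
#'
#' @inheritParams fit_elastic_net
#' @param intercept,weights Model coefficients.
#' @return The penalised objective (scalar).
#' @export
enet_objective <- function(X, y, intercept, weights, alpha_mix,
                           lambda_penalty) {
  r <- y - intercept - as.vector(as.matrix(X) %*% weights)
  sum(r^2) / (2 * length(y)) +
    lambda_penalty * (alpha_mix * sum(abs(weights)) +
                        (1 - alpha_mix) / 2 * sum(weights^2))
}

# Standardise columns; drops zero-sd columns. Returns list(X, center, scale,
# kept). sd uses the n-1 denominator.
standardize_columns <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  kept <- which(scl > 0)
  Xs <- sweep(sweep(X[, kept, drop = FALSE], 2, ctr[kept], "-"),
              2, scl[kept], "/")
  list(X = Xs, center = ctr[kept], scale = scl[kept], kept = kept)
}

# Smallest penalty that zeroes every coefficient (standardised X).
lambda_max <- function(X, y, alpha_mix) {
  stopifnot(alpha_mix > 0)
  max(abs(crossprod(X, y - mean(y)))) / (nrow(X) * alpha_mix)
}

# Fit a whole descending lambda path with warm starts (standardised X).
enet_path <- function(X, y, alpha_mix, lambdas, tol = 1e-7,
                      max_iter = 100000L) {
  fit <- enet_cd_path_cpp(as.matrix(X), as.numeric(y), alpha_mix,
                          as.numeric(lambdas), tol, as.integer(max_iter),
                          FALSE)
  list(beta = fit$beta, intercept = fit$intercept, converged = fit$converged)
}

#' Choose the elastic-net penalty by cross-validation (1-SE rule)
#'
#' Builds a grid of `n_lambda` penalties log-spaced on
#' `[lambda_max * 1e-4, lambda_max]`, where `lambda_max` is the smallest
#' penalty that zeroes every coefficient on the full data.  For each
#' held-out fold the remaining samples are re-standardised, the whole path is
#' fitted with warm starts, and the held-out squared error recorded.  The
#' returned penalty is the LARGEST one whose mean CV error is within one
#' standard error of the minimum (ties resolved toward more shrinkage).
#' Folds default to leave-one-out, which is deterministic at small n.
#'
#' @param X Raw (unstandardised) feature matrix, no missing values.
#' @param y Response (ages in weeks); must have positive variance.
#' @param alpha_mix L1/L2 mixing weight, must be > 0 for a finite
#'   `lambda_max`.
#' @param n_lambda Grid size (default 100; `n_lambda = 1` returns
#'   `lambda_max`).
#' @param folds Optional list of validation index vectors; default LOO.
#' @return List of class `lambda_cv` with `lambda`, `lambda_grid`, `cvm`,
#'   `cvse`.
#' @export
select_lambda <- function(X, y, alpha_mix = 0.5, n_lambda = 100L,
                          folds = NULL) {
  X <- as.matrix(X)
  stopifnot(!anyNA(X), nrow(X) == length(y), nrow(X) >= 3, alpha_mix > 0)
  if (var(y) == 0) stop("degenerate response: y has zero variance")
  full <- standardize_columns(X)
  if (length(full$kept) == 0) stop("no feature with positive variance")
  lmax <- lambda_max(full$X, y, alpha_mix)
  if (n_lambda == 1) {
    grid <- lmax
  } else {
    grid <- exp(seq(log(lmax), log(lmax * 1e-4), length.out = n_lambda))
  }
  if (is.null(folds)) folds <- as.list(seq_along(y))
  # convergence threshold on the response scale: coefficients are in weeks,
  # so demand precision far below a week rather than an absolute epsilon
  tol_path <- 1e-4 * sd(y)
  errs <- matrix(NA_real_, length(folds), length(grid))
  for (f in seq_along(folds)) {
    val <- folds[[f]]
    tr <- setdiff(seq_along(y), val)
    std <- standardize_columns(X[tr, , drop = FALSE])
    if (length(std$kept) == 0) {
      errs[f, ] <- mean((y[val] - mean(y[tr]))^2)
      next
    }
    path <- enet_path(std$X, y[tr], alpha_mix, grid, tol = tol_path)
    Xv <- sweep(sweep(X[val, std$kept, drop = FALSE], 2, std$center, "-"),
                2, std$scale, "/")
    pred <- path$intercept + Xv %*% path$beta
    errs[f, ] <- colMeans((y[val] - pred)^2)
  }
  cvm <- colMeans(errs)
  cvse <- apply(errs, 2, sd) / sqrt(nrow(errs))
  i_min <- which.min(cvm)
  ok <- which(cvm <= cvm[i_min] + cvse[i_min])
  lambda <- max(grid[ok])  # grid is descending: largest lambda within 1 SE
  structure(list(lambda = lambda, lambda_grid = grid, cvm = cvm, cvse = cvse),
            class = "lambda_cv")
}
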