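# Shared trainer: impute -> standardise -> select lambda -> coordinate
# descent -> back-transform weights to the original fraction scale.
# Returns the full clock parameter set; X is raw fractions (may contain NA).
train_clock <- function(X, y, alpha_mix = 0.5, n_lambda = 100L,
                        lambda_penalty = NULL) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), nrow(X) >= 2)
  all_missing <- colSums(!is.na(X)) == 0
  if (any(all_missing)) {
    warning("site(s) missing in every training sample dropped: ",
            paste(colnames(X)[all_missing], collapse = ", "))
    X <- X[, !all_missing, drop = FALSE]
  }
  imp <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- imp[j]
  std <- standardize_columns(X)
  if (length(std$kept) == 0 || var(y) == 0) {
    # nothing to regress on: constant model at the mean training age
    return(list(site_ids = character(0), weights = numeric(0),
                intercept = mean(y), alpha_mix = alpha_mix,
                lambda_penalty = 0, center = numeric(0), scale = numeric(0),
                weights_std = numeric(0), imputation_means = imp))
  }
  if (is.null(lambda_penalty)) {
    lambda_penalty <- select_lambda(X[, std$kept, drop = FALSE], y,
                                    alpha_mix = alpha_mix,
                                    n_lambda = n_lambda)$lambda
  }
  fit <- fit_elastic_net(std$X, y, alpha_mix = alpha_mix,
                         lambda_penalty = lambda_penalty,
                         tol = 1e-6 * max(sd(y), 1))
  w_std <- fit$weights
  w_orig <- w_std / std$scale
  list(site_ids = colnames(X)[std$kept], weights = unname(w_orig),
       intercept = fit$intercept - sum(w_std * std$center / std$scale),
       alpha_mix = alpha_mix, lambda_penalty = lambda_penalty,
       center = unname(std$center), scale = unname(std$scale),
       weights_std = unname(w_std), imputation_means = imp)
}

#' Fit the elastic-net age clock
#'
#' Trains a multivariate age predictor on the selected CpGs: missing
#' fractions are imputed with training-set per-site means, predictors are
#' standardised to unit variance within the training set, the penalty is
#' chosen by leave-one-out cross-validation with the 1-SE rule
#' ([select_lambda()]), and coefficients are fitted by cyclic coordinate
#' descent.  Weights are reported on the original fraction scale (weeks per
#' unit methylation fraction).
#'
#' @param mm A `meth_matrix` or plain samples x sites matrix (training set).
#' @param ages Ages in weeks aligned to the rows.
#' @param sites Optional character vector restricting the clock to these
#'   sites (e.g. the [select_admps()] output); default: all columns.
#' @param alpha_mix L1/L2 mixing weight (default 0.5, an equal mix).
#' @param n_lambda Penalty grid size for [select_lambda()].
#' @param lambda_penalty Optional fixed penalty, bypassing selection.
#' @return An object of class `clock_model`.
#' @export
fit_clock <- function(mm, ages, sites = NULL, alpha_mix = 0.5,
                      n_lambda = 100L, lambda_penalty = NULL) {
  frac <- if (inherits(mm, "meth_matrix")) mm$fraction else as.matrix(mm)
  if (!is.null(sites)) {
    missing_sites <- setdiff(sites, colnames(frac))
    if (length(missing_sites)) stop("site(s) not in matrix: ",
                                    paste(missing_sites, collapse = ", "))
    frac <- frac[, sites, drop = FALSE]
  }
  model <- train_clock(frac, ages, alpha_mix = alpha_mix,
                       n_lambda = n_lambda, lambda_penalty = lambda_penalty)
  model$imputation_site_ids <- colnames(frac)
  model$n_train <- length(ages)
  structure(model, class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat("clock_model:", length(x$site_ids), "sites,",
      sum(x$weights != 0), "nonzero weights; alpha =", x$alpha_mix,
      ", lambda =", format(x$lambda_penalty, digits = 4),
      "; trained on", x$n_train, "samples\n")
  invisible(x)
}

#' Predict ages from a fitted clock
#'
#' Missing cells (and model sites entirely absent from the input) are imputed
#' with the training-set per-site means; at least one model site must be
#' present.  Predictions are the plain linear model output and are not
#' clamped — negative predicted ages are possible and reported as-is.
#'
#' @param model A `clock_model`.
#' @param mm A `meth_matrix` or plain matrix with named columns.
#' @return Named numeric vector of predicted ages in weeks.
#' @export
predict_ages <- function(model, mm) {
  stopifnot(inherits(model, "clock_model"))
  frac <- if (inherits(mm, "meth_matrix")) mm$fraction else as.matrix(mm)
  if (length(model$site_ids) == 0) {
    return(setNames(rep(model$intercept, nrow(frac)), rownames(frac)))
  }
  present <- model$site_ids %in% colnames(frac)
  if (!any(present)) stop("none of the clock's sites are present in the input")
  X <- matrix(rep(model$imputation_means[model$site_ids], each = nrow(frac)),
              nrow(frac), length(model$site_ids),
              dimnames = list(rownames(frac), model$site_ids))
  for (s in model$site_ids[present]) {
    v <- frac[, s]
    X[!is.na(v), s] <- v[!is.na(v)]
  }
  setNames(as.vector(model$intercept + X %*% model$weights), rownames(frac))
}

#' Leave-one-out cross-validated age predictions
#'
#' For each sample the full training procedure — imputation means,
#' standardisation, penalty selection and coordinate descent — is re-run on
#' the other `n - 1` samples only, and the held-out sample's age predicted
#' from that model.  No information from the held-out sample leaks into its
#' own fold.
#'
#' @inheritParams fit_clock
#' @return Named numeric vector of out-of-fold predicted ages (weeks), in
#'   input row order.
#' @export
loocv_predict <- function(mm, ages, sites = NULL, alpha_mix = 0.5,
                          n_lambda = 100L) {
  frac <- if (inherits(mm, "meth_matrix")) mm$fraction else as.matrix(mm)
  stopifnot(nrow(frac) == length(ages), nrow(frac) >= 4)
  if (!is.null(sites)) frac <- frac[, sites, drop = FALSE]
  n <- nrow(frac)
  pred <- setNames(numeric(n), rownames(frac))
  for (i in seq_len(n)) {
    model <- train_clock(frac[-i, , drop = FALSE], ages[-i],
                         alpha_mix = alpha_mix, n_lambda = n_lambda)
    x <- frac[i, model$site_ids]
    x[is.na(x)] <- model$imputation_means[model$site_ids][is.na(x)]
    pred[i] <- if (length(model$site_ids)) {
      model$intercept + sum(model$weights * x)
    } else {
      model$intercept
    }
  }
  pred
}

#' Prediction accuracy metrics
#'
#' Pearson correlation, RMSE (root mean squared error), MAD (mean absolute
#' deviation of the errors) and MAE (median absolute error) of predicted vs
#' actual age, all in weeks, plus the OLS slope/intercept of predicted on
#' actual (the epigenetic ageing-rate line).
#'
#' @param predicted,actual Equal-length age vectors in weeks, n >= 2.
#' @return A list of class `metric_set`: `pearson_r`, `rmse_weeks`,
#'   `mad_weeks`, `mae_weeks`, `n`, `fitted_slope`, `fitted_intercept`.
#' @export
evaluate_predictions <- function(predicted, actual) {
  stopifnot(length(predicted) == length(actual), length(actual) >= 2)
  err <- predicted - actual
  r <- if (var(predicted) == 0 || var(actual) == 0) NA_real_ else
    cor(predicted, actual)
  fit <- if (var(actual) > 0) lm(predicted ~ actual) else NULL
  structure(list(
    pearson_r = r,
    rmse_weeks = sqrt(mean(err^2)),
    mad_weeks = mean(abs(err)),
    mae_weeks = median(abs(err)),
    n = length(actual),
    fitted_slope = if (is.null(fit)) NA_real_ else unname(coef(fit)[2]),
    fitted_intercept = if (is.null(fit)) NA_real_ else unname(coef(fit)[1])
  ), class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf(paste0("n = %d; R = %.3f; RMSE = %.2f weeks; ",
                     "MAD = %.2f; MAE = %.2f; slope = %.3f\n"),
              x$n, x$pearson_r, x$rmse_weeks, x$mad_weeks, x$mae_weeks,
              x$fitted_slope))
  invisible(x)
}

#' Relative epigenetic ageing rate of a tissue
#'
#' OLS slope of predicted on actual age with a t-based 95% confidence
#' interval.  A slope below 1 whose interval excludes 1 indicates the tissue
#' accumulates methylation drift more slowly than the tissue the clock was
#' trained on.
#'
#' @param predicted,actual Age vectors in weeks, n >= 3.
#' @param level Confidence level (default 0.95).
#' @return List with `slope`, `ci_lower`, `ci_upper`, `excludes_one`,
#'   `intercept`, `n`.
#' @export
estimate_tissue_rate <- function(predicted, actual, level = 0.95) {
  stopifnot(length(predicted) == length(actual), length(actual) >= 3)
  fit <- lm(predicted ~ actual)
  ci <- suppressWarnings(confint(fit, "actual", level = level))
  slope <- unname(coef(fit)["actual"])
  lo <- ci[1]; hi <- ci[2]
  if (anyNA(c(lo, hi))) { lo <- slope; hi <- slope }  # perfect fit: zero-width
  list(slope = slope, ci_lower = lo, ci_upper = hi,
       excludes_one = (hi < 1) || (lo > 1),
       intercept = unname(coef(fit)["(Intercept)"]), n = length(actual))
}

#' Serialise / restore a clock model as JSON
#'
#' Numbers are written at full precision so a round trip reproduces
#' predictions exactly.
#'
#' @param model A `clock_model`.
#' @param path File path.
#' @export
write_clock <- function(model, path) {
  stopifnot(inherits(model, "clock_model"))
  obj <- unclass(model)
  obj$format_version <- 1L
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_clock
#' @export
read_clock <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$format_version <- NULL
  for (f in c("weights", "center", "scale", "weights_std"))
    obj[[f]] <- as.numeric(obj[[f]])
  obj$imputation_means <- unlist(obj$imputation_means)
  obj$site_ids <- as.character(obj$site_ids)
  structure(obj, class = "clock_model")
}
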