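#' Per-CpG association with age
#'
#' Ordinary least squares of methylation fraction on age gives the drift
#' slope and intercept; the p-value is the two-sided t-test on that slope
#' with `n_used - 2` degrees of freedom, and `pearson_r` is the correlation
#' of the non-missing pairs.  Because the single-site age errors are reported
#' on the week scale, a second OLS of age on methylation (the inverse
#' regression) supplies in-sample residuals from which the week-scale RMSE
#' (root mean squared), MAD (mean absolute) and MAE (median absolute) are
#' computed.  Missing fractions are dropped pairwise.
#'
#' Degenerate inputs: fewer than 3 non-missing pairs marks the site unusable
#' (`usable = FALSE`, everything else `NA`); zero variance in the fractions
#' yields slope 0, p-value 1 and `NA` week-scale errors.
#'
#' @param fractions Numeric vector of methylation fractions (may contain
#'   `NA`).
#' @param ages Ages in weeks, same length.
#' @param site_id Optional site label carried into the result.
#' @return A one-row data.frame with `site_id`, `n_used`,
#'   `slope_meth_per_week`, `intercept`, `pearson_r`, `p_value`,
#'   `age_rmse_weeks`, `age_mad_weeks`, `age_mae_weeks`, `usable`.
#' @export
fit_site <- function(fractions, ages, site_id = NA_character_) {
  stopifnot(length(fractions) == length(ages))
  ok <- !is.na(fractions) & !is.na(ages)
  x <- ages[ok]
  y <- fractions[ok]
  n <- length(x)
  out <- data.frame(site_id = site_id, n_used = n,
                    slope_meth_per_week = NA_real_, intercept = NA_real_,
                    pearson_r = NA_real_, p_value = NA_real_,
                    age_rmse_weeks = NA_real_, age_mad_weeks = NA_real_,
                    age_mae_weeks = NA_real_, usable = FALSE,
                    stringsAsFactors = FALSE)
  if (n < 3) return(out)
  out$usable <- TRUE
  if (var(y) == 0) {
    out$slope_meth_per_week <- 0
    out$intercept <- y[1]
    out$p_value <- 1
    return(out)
  }
  fit <- lm(y ~ x)
  # a perfectly linear site trips summary()'s essentially-perfect-fit warning
  cf <- suppressWarnings(summary(fit))$coefficients
  out$slope_meth_per_week <- cf["x", "Estimate"]
  out$intercept <- cf["(Intercept)", "Estimate"]
  out$p_value <- cf["x", "Pr(>|t|)"]
  out$pearson_r <- cor(x, y)
  inv <- lm(x ~ y)
  res <- residuals(inv)
  out$age_rmse_weeks <- sqrt(mean(res^2))
  out$age_mad_weeks <- mean(abs(res))
  out$age_mae_weeks <- median(abs(res))
  out
}

#' Scan every CpG of a methylation matrix for age association
#'
#' Applies [fit_site()] column-wise.
#'
#' @param mm A `meth_matrix`, or a plain samples x sites numeric matrix.
#' @param ages Ages in weeks aligned to the rows.
#' @return A data.frame with one [fit_site()] row per site.
#' @export
admp_scan <- function(mm, ages) {
  frac <- if (inherits(mm, "meth_matrix")) mm$fraction else mm
  stopifnot(nrow(frac) == length(ages))
  ids <- colnames(frac)
  if (is.null(ids)) ids <- sprintf("site%03d", seq_len(ncol(frac)))
  do.call(rbind, lapply(seq_len(ncol(frac)), function(j) {
    fit_site(frac[, j], ages, site_id = ids[j])
  }))
}

#' Select age-associated CpGs (aDMPs)
#'
#' Sites with an age-association p-value strictly below `alpha`, ordered by
#' ascending p-value.  No multiple-testing correction is applied — the
#' selection mirrors a raw per-site `p < 0.05` screen.  Unusable sites are
#' excluded; an empty selection is allowed but warned about.
#'
#' @param stats An [admp_scan()] data.frame.
#' @param alpha Significance threshold (strict inequality).
#' @return Character vector of selected `site_id`s, most significant first.
#' @export
select_admps <- function(stats, alpha = 0.05) {
  stopifnot(nrow(stats) >= 1)
  ok <- stats$usable & !is.na(stats$p_value) & stats$p_value < alpha
  sel <- stats[ok, , drop = FALSE]
  sel <- sel[order(sel$p_value), , drop = FALSE]
  if (nrow(sel) == 0) warning("no site passed the aDMP screen at alpha = ",
                              alpha)
  sel$site_id
}
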