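#' Linear methylation-drift generative model
#'
#' Formalises the age signal the clock assumes: at an age-associated CpG
#' (aDMP) the expected methylation fraction drifts linearly with age,
#' `p_ij = m0_j + s_j * r_tissue(i) * age_i`, with per-(sample, site)
#' Gaussian biological noise and a tissue-specific rate multiplier
#' (`r_liver = 1` by convention; skin drifts slower).  Non-aDMP sites have
#' slope zero.
#'
#' If `site_params` is supplied it is used as-is; otherwise `n_admps` sites
#' are chosen at random, given slopes uniform on `slope_range` (random sign),
#' and baselines placed so the trajectory stays inside `[0, 1]` over a
#' naked-mole-rat lifespan (rising sites start low, falling sites start
#' high).
#'
#' @param panel An `amplicon_panel`.
#' @param n_admps Number of age-associated sites to plant.
#' @param slope_range Range of |slope| in methylation fraction per week.
#' @param sigma_b Biological noise sd (fraction units) per sample-site.
#' @param conversion_efficiency Probability an unmethylated C is bisulfite
#'   converted to T.
#' @param sequencing_error_rate Per-base substitution probability.
#' @param target_coverage Simulated reads per region per sample.
#' @param tissue_rates Named positive multipliers of the drift rate per
#'   tissue; liver is the reference at 1.
#' @param seed Integer seed for the site parameter draw.
#' @param site_params Optional data.frame with `site_id`, `m0`, `slope`,
#'   `is_admp` overriding the random draw.
#' @return An object of class `drift_model`.
#' @export
drift_model <- function(panel, n_admps = 23L, slope_range = c(3e-4, 7e-4),
                        sigma_b = 0.03, conversion_efficiency = 0.99,
                        sequencing_error_rate = 0.001, target_coverage = 200L,
                        tissue_rates = c(liver = 1, skin = 0.6),
                        seed = 1L, site_params = NULL) {
  stopifnot(inherits(panel, "amplicon_panel"),
            sigma_b >= 0, target_coverage >= 1,
            conversion_efficiency >= 0, conversion_efficiency <= 1,
            sequencing_error_rate >= 0, sequencing_error_rate <= 1,
            all(tissue_rates > 0))
  n_sites <- nrow(panel$sites)
  if (is.null(site_params)) {
    stopifnot(n_admps >= 0, n_admps <= n_sites)
    set.seed(seed)
    admp_idx <- sort(sample.int(n_sites, n_admps))
    slope <- numeric(n_sites)
    m0 <- runif(n_sites, 0.1, 0.9)
    sgn <- sample(c(-1, 1), n_admps, replace = TRUE)
    mag <- runif(n_admps, slope_range[1], slope_range[2])
    slope[admp_idx] <- sgn * mag
    m0[admp_idx] <- ifelse(sgn > 0, runif(n_admps, 0.05, 0.25),
                           runif(n_admps, 0.75, 0.95))
    site_params <- data.frame(
      site_id = panel$sites$site_id, m0 = m0, slope = slope,
      is_admp = seq_len(n_sites) %in% admp_idx, stringsAsFactors = FALSE
    )
  } else {
    stopifnot(identical(sort(site_params$site_id), sort(panel$sites$site_id)),
              all(site_params$m0 >= 0), all(site_params$m0 <= 1))
    site_params <- site_params[match(panel$sites$site_id,
                                     site_params$site_id), , drop = FALSE]
    rownames(site_params) <- NULL
  }
  structure(
    list(site_params = site_params, tissue_rates = tissue_rates,
         sigma_b = sigma_b, conversion_efficiency = conversion_efficiency,
         sequencing_error_rate = sequencing_error_rate,
         target_coverage = as.integer(target_coverage)),
    class = "drift_model"
  )
}

#' @export
print.drift_model <- function(x, ...) {
  cat("drift_model:", sum(x$site_params$is_admp), "aDMPs /",
      nrow(x$site_params), "sites; sigma_b =", x$sigma_b,
      "; coverage =", x$target_coverage, "\n")
  invisible(x)
}

#' True per-sample, per-site methylation probabilities
#'
#' Evaluates the drift model: `p_ij = clamp(m0_j + s_j * r_t(i) * age_i +
#' eps_ij, 0, 1)` with `eps_ij ~ N(0, sigma_b^2)`.
#'
#' @param panel An `amplicon_panel`.
#' @param cohort A cohort data.frame ([draw_cohort()]).
#' @param model A `drift_model`.
#' @param seed Integer seed for the biological noise.
#' @return A numeric matrix, samples x sites, with dimnames
#'   (`sample_id`, `site_id`); all entries in `[0, 1]`.
#' @export
true_methylation <- function(panel, cohort, model, seed = 1L) {
  stopifnot(inherits(model, "drift_model"))
  sp <- model$site_params
  rate <- model$tissue_rates[cohort$tissue]
  if (anyNA(rate)) stop("cohort tissue not present in model$tissue_rates")
  set.seed(seed)
  n <- nrow(cohort)
  p <- nrow(sp)
  drift <- outer(unname(rate) * cohort$age_weeks, sp$slope)
  eps <- matrix(rnorm(n * p, 0, model$sigma_b), n, p)
  m <- sweep(drift + eps, 2, sp$m0, "+")
  m <- pmin(pmax(m, 0), 1)
  dimnames(m) <- list(cohort$sample_id, sp$site_id)
  m
}

#' Write / read the ground-truth site table
#'
#' TSV with columns `site_id`, `m0`, `slope`, `is_admp`.
#'
#' @param model A `drift_model`.
#' @param path File path.
#' @export
write_truth <- function(model, path) {
  write.table(model$site_params, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("site_id", "m0", "slope", "is_admp") %in% names(df)))
  df$is_admp <- as.logical(df$is_admp)
  df
}
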