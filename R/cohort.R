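#' Draw a synthetic cohort of aged animals
#'
#' Ages are drawn uniformly on `[age_min, age_max]` weeks and sorted
#' ascending; sample ids are deterministic in the seed.
#'
#' @param n_samples Number of animals (>= 2).
#' @param age_min,age_max Age range in weeks, `age_min < age_max`.
#' @param tissue `"liver"` or `"skin"`.
#' @param batch `"set1"` or `"set2"`.
#' @param seed Integer seed.
#' @return A data.frame with columns `sample_id`, `age_weeks`, `tissue`,
#'   `batch`.
#' @export
#' @examples
#' draw_cohort(24, 39, 1144, "liver", "set1", seed = 7)
draw_cohort <- function(n_samples, age_min, age_max,
                        tissue = c("liver", "skin"),
                        batch = c("set1", "set2"), seed = 1L) {
  tissue <- match.arg(tissue)
  batch <- match.arg(batch)
  stopifnot(n_samples >= 2, age_min < age_max, age_min > 0)
  set.seed(seed)
  ages <- sort(runif(n_samples, age_min, age_max))
  data.frame(
    sample_id = sprintf("%s_%s_%02d", tissue, batch, seq_len(n_samples)),
    age_weeks = ages, tissue = tissue, batch = batch,
    stringsAsFactors = FALSE
  )
}

#' Write / read a sample sheet
#'
#' Tab-separated with header `sample_id  age_weeks  tissue  batch`.
#'
#' @param samples A cohort data.frame as returned by [draw_cohort()].
#' @param path File path.
#' @export
write_samples <- function(samples, path) {
  stopifnot(all(c("sample_id", "age_weeks", "tissue", "batch") %in%
                  names(samples)))
  write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_samples
#' @export
read_samples <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(age_weeks = "character"))
  need <- c("sample_id", "age_weeks", "tissue", "batch")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample sheet missing column(s): ",
                         paste(miss, collapse = ", "))
  age <- suppressWarnings(as.numeric(df$age_weeks))
  bad <- which(is.na(age) | !nzchar(df$age_weeks))
  if (length(bad)) {
    stop("non-numeric or missing age_weeks in sample sheet row(s) ",
         paste(bad, collapse = ", "), " (sample ",
         paste(df$sample_id[bad], collapse = ", "), ")")
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in sample sheet: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  df$age_weeks <- age
  df[, need]
}
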