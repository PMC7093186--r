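#' Simulate bisulfite-converted amplicon reads
#'
#' Emits one FASTQ per sample.  For every sample and region,
#' `model$target_coverage` single-end reads spanning the full amplicon are
#' generated from the original-top strand.  Per read, each CpG cytosine is
#' methylated with probability `probs[sample, site]` independently; bisulfite
#' conversion then turns every unmethylated cytosine (CpG or not) into T with
#' probability `conversion_efficiency` (a conversion failure leaves it as C),
#' while methylated CpG cytosines stay C.  Finally each base is substituted by
#' one of the other three bases with probability `sequencing_error_rate`.
#' Read names encode `sample|region|index` so provenance is traceable, and
#' qualities are a constant Phred+33 "I".
#'
#' The returned ledger records, for every (sample, site), how many reads drew
#' the methylated state — with `sequencing_error_rate = 0` and
#' `conversion_efficiency = 1` downstream counting must reproduce it exactly.
#'
#' @param panel An `amplicon_panel`.
#' @param cohort A cohort data.frame; rows must match `rownames(probs)`.
#' @param probs Samples x sites methylation probability matrix
#'   ([true_methylation()]).
#' @param model A `drift_model` (conversion, error and coverage parameters).
#' @param outdir Directory for the FASTQ files (created if needed).
#' @param seed Integer seed.
#' @return Invisibly, a list with `files` (named FASTQ paths) and `ledger`
#'   (data.frame `sample_id`, `site_id`, `n_meth_drawn`, `n_reads`).
#' @export
simulate_reads <- function(panel, cohort, probs, model, outdir, seed = 1L) {
  stopifnot(inherits(panel, "amplicon_panel"), inherits(model, "drift_model"),
            nrow(probs) == nrow(cohort),
            ncol(probs) == nrow(panel$sites))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  ce <- model$conversion_efficiency
  err <- model$sequencing_error_rate
  R <- model$target_coverage
  bases <- c("A", "C", "G", "T")

  region_chars <- lapply(panel$regions$sequence,
                         function(s) strsplit(s, "")[[1]])
  names(region_chars) <- panel$regions$region_id

  files <- character(nrow(cohort))
  names(files) <- cohort$sample_id
  ledger <- vector("list", nrow(cohort))

  for (i in seq_len(nrow(cohort))) {
    sid <- cohort$sample_id[i]
    all_reads <- character(0)
    all_names <- character(0)
    led <- list()
    for (g in seq_len(nrow(panel$regions))) {
      rid <- panel$regions$region_id[g]
      chars <- region_chars[[rid]]
      L <- length(chars)
      M <- matrix(chars, nrow = L, ncol = R)
      site_rows <- which(panel$sites$region_id == rid)
      cpg_pos <- panel$sites$offset[site_rows] + 1L
      # CpG cytosines: methylated stays C, unmethylated converts C -> T
      for (k in seq_along(site_rows)) {
        j <- site_rows[k]
        meth <- runif(R) < probs[i, j]
        unconv <- runif(R) >= ce            # conversion failures stay C
        M[cpg_pos[k], !meth & !unconv] <- "T"
        led[[length(led) + 1L]] <- data.frame(
          sample_id = sid, site_id = panel$sites$site_id[j],
          n_meth_drawn = sum(meth), n_reads = R, stringsAsFactors = FALSE
        )
      }
      # non-CpG cytosines are always unmethylated
      other_c <- setdiff(which(chars == "C"), cpg_pos)
      if (length(other_c)) {
        conv <- matrix(runif(length(other_c) * R) < ce, length(other_c), R)
        sub <- M[other_c, , drop = FALSE]
        sub[conv] <- "T"
        M[other_c, ] <- sub
      }
      if (err > 0) {
        hit <- which(runif(L * R) < err)
        if (length(hit)) {
          # substitute with one of the other three bases, uniformly
          cur <- match(M[hit], bases)
          M[hit] <- bases[(cur - 1L + sample.int(3L, length(hit),
                                                 replace = TRUE)) %% 4L + 1L]
        }
      }
      reads <- vapply(seq_len(R), function(cix) paste(M[, cix], collapse = ""),
                      character(1))
      all_reads <- c(all_reads, reads)
      all_names <- c(all_names, sprintf("%s|%s|read%04d", sid, rid, seq_len(R)))
    }
    fq <- file.path(outdir, paste0(sid, ".fastq"))
    dna <- Biostrings::DNAStringSet(setNames(all_reads, all_names))
    qual <- Biostrings::BStringSet(vapply(nchar(all_reads),
                                          function(n) strrep("I", n),
                                          character(1)))
    Biostrings::writeXStringSet(dna, fq, format = "fastq", qualities = qual)
    files[i] <- fq
    ledger[[i]] <- do.call(rbind, led)
  }
  invisible(list(files = files, ledger = do.call(rbind, ledger)))
}

#' Simulate per-CpG methylation counts directly
#'
#' Count-level shortcut past read simulation: for every (sample, site) the
#' methylated count is a binomial draw at `target_coverage` trials with
#' success probability `p + (1 - p) * (1 - conversion_efficiency)` — the
#' probability a read shows C at the site, i.e. the methylation probability
#' inflated by conversion failures.  Sequencing errors are not modelled at
#' this level.
#'
#' @inheritParams simulate_reads
#' @return A data.frame of count records (`sample_id`, `site_id`,
#'   `count_methylated`, `count_unmethylated`).
#' @export
simulate_counts <- function(panel, cohort, probs, model, seed = 1L) {
  stopifnot(nrow(probs) == nrow(cohort), ncol(probs) == nrow(panel$sites))
  set.seed(seed)
  ce <- model$conversion_efficiency
  R <- model$target_coverage
  p_obs <- probs + (1 - probs) * (1 - ce)
  cm <- matrix(rbinom(length(p_obs), R, as.vector(p_obs)), nrow(p_obs))
  data.frame(
    sample_id = rep(cohort$sample_id, times = ncol(p_obs)),
    site_id = rep(panel$sites$site_id, each = nrow(p_obs)),
    count_methylated = as.vector(cm),
    count_unmethylated = R - as.vector(cm),
    stringsAsFactors = FALSE
  )
}
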