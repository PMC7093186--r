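#' Assign bisulfite reads to amplicon regions
#'
#' Each read is compared against every region's bisulfite-space reference:
#' the region sequence with all cytosines collapsed to T except CpG
#' cytosines, which may legitimately read as C (methylated) or T
#' (unmethylated) and are treated as C/T wildcards.  The read goes to the
#' region with the smallest Hamming distance (a length difference is charged
#' one mismatch per missing/extra base); reads whose best distance exceeds
#' `ceil(max_mismatch_frac * read_length)` are discarded and counted.  Ties
#' are broken toward the lowest region index with a warning.
#'
#' @param reads A named character vector of read sequences, or a path to a
#'   FASTQ file.
#' @param panel An `amplicon_panel`.
#' @param max_mismatch_frac Mismatch ceiling as a fraction of read length.
#' @return A list with `groups` (named list, region_id -> character vector of
#'   read sequences), `discarded` (count) and `n_ties`.
#' @export
assign_reads <- function(reads, panel, max_mismatch_frac = 0.1) {
  stopifnot(inherits(panel, "amplicon_panel"), nrow(panel$regions) >= 1)
  if (length(reads) == 1 && !grepl("^[ACGTN]+$", reads) && file.exists(reads)) {
    fq <- Biostrings::readDNAStringSet(reads, format = "fastq")
    reads <- setNames(as.character(fq), names(fq))
  }
  n_regions <- nrow(panel$regions)
  empty <- setNames(rep(list(character(0)), n_regions),
                    panel$regions$region_id)
  if (length(reads) == 0) {
    return(list(groups = empty, discarded = 0L, n_ties = 0L))
  }

  rl <- nchar(reads)
  Lmax <- max(rl, nchar(panel$regions$sequence))
  # pad with N so the char matrix is rectangular; N never matches a ref base
  padded <- strsplit(vapply(reads, function(r)
    paste0(r, strrep("N", Lmax - nchar(r))), character(1), USE.NAMES = FALSE), "")
  mat <- matrix(unlist(padded), nrow = Lmax)

  dist <- matrix(NA_real_, length(reads), n_regions)
  for (g in seq_len(n_regions)) {
    chars <- strsplit(panel$regions$sequence[g], "")[[1]]
    L <- length(chars)
    cpg_pos <- panel$sites$offset[panel$sites$region_id ==
                                    panel$regions$region_id[g]] + 1L
    collapsed <- ifelse(chars == "C", "T", chars)
    collapsed[cpg_pos] <- "C"                     # wildcard: C or T both match
    sub <- mat[seq_len(L), , drop = FALSE]
    mism <- colSums(sub != collapsed)
    mism <- mism - colSums(sub[cpg_pos, , drop = FALSE] == "T")
    # reads shorter than L already pay via N padding; longer reads pay extra
    dist[, g] <- mism + pmax(rl - L, 0L)
  }
  best_d <- do.call(pmin, as.data.frame(dist))
  best_g <- max.col(-dist, ties.method = "first")
  ties <- rowSums(dist == best_d) > 1L
  keep <- best_d <= ceiling(max_mismatch_frac * rl)
  if (any(ties & keep)) {
    warning(sum(ties & keep), " read(s) tied between regions; ",
            "assigned to the lowest region index")
  }
  groups <- empty
  for (g in seq_len(n_regions)) {
    sel <- keep & best_g == g
    groups[[g]] <- reads[sel]
  }
  list(groups = groups, discarded = sum(!keep), n_ties = sum(ties & keep))
}

#' Count methylated / unmethylated calls per CpG
#'
#' Reads are amplicon-aligned at the region start, so the base over a CpG is
#' simply the read character at the site offset: C increments the methylated
#' count, T the unmethylated count, and any other base (sequencing error,
#' N, or a read too short to reach the offset) is excluded from both.
#'
#' @param groups Per-region read groups as returned by [assign_reads()].
#' @param panel An `amplicon_panel`.
#' @param sample_id Sample label attached to every record.
#' @return A data.frame of count records with one row per panel site:
#'   `sample_id`, `site_id`, `count_methylated`, `count_unmethylated`.
#' @export
count_methylation <- function(groups, panel, sample_id) {
  out <- panel$sites[, c("site_id", "region_id", "offset")]
  out$count_methylated <- 0L
  out$count_unmethylated <- 0L
  for (g in seq_len(nrow(panel$regions))) {
    rid <- panel$regions$region_id[g]
    reads <- groups[[rid]]
    if (is.null(reads) || length(reads) == 0) next
    rows <- which(out$region_id == rid)
    for (k in rows) {
      pos <- out$offset[k] + 1L
      base <- substr(reads, pos, pos)
      out$count_methylated[k] <- sum(base == "C")
      out$count_unmethylated[k] <- sum(base == "T")
    }
  }
  data.frame(sample_id = sample_id, site_id = out$site_id,
             count_methylated = out$count_methylated,
             count_unmethylated = out$count_unmethylated,
             stringsAsFactors = FALSE)
}

#' Coverage filter
#'
#' Drops records whose coverage (methylated + unmethylated) is strictly below
#' `min_coverage`; a site at exactly the threshold is retained.  Dropped
#' records surface as missing cells in [build_matrix()].  The filter is
#' idempotent and monotone in `min_coverage`.
#'
#' @param records Count records (see [count_methylation()]).
#' @param min_coverage Minimum informative reads per site (default 50).
#' @return The filtered records.
#' @export
filter_coverage <- function(records, min_coverage = 50L) {
  stopifnot(min_coverage >= 1)
  cov <- records$count_methylated + records$count_unmethylated
  records[cov >= min_coverage, , drop = FALSE]
}

#' Assemble the sample x CpG methylation matrix
#'
#' @param records Count records, typically after [filter_coverage()].
#' @param cohort Cohort data.frame fixing the row order.
#' @param panel An `amplicon_panel` fixing the column order.
#' @return An object of class `meth_matrix`: list with `fraction` (samples x
#'   sites, `NA` where a site is missing in a sample), `coverage` (same
#'   shape), `sample_ids`, `site_ids`.
#' @export
build_matrix <- function(records, cohort, panel) {
  if (anyDuplicated(paste(records$sample_id, records$site_id))) {
    stop("duplicate (sample_id, site_id) record(s)")
  }
  unknown_s <- setdiff(records$sample_id, cohort$sample_id)
  unknown_j <- setdiff(records$site_id, panel$sites$site_id)
  if (length(unknown_s)) stop("records reference unknown sample(s): ",
                              paste(unknown_s, collapse = ", "))
  if (length(unknown_j)) stop("records reference unknown site(s): ",
                              paste(unknown_j, collapse = ", "))
  n <- nrow(cohort)
  p <- nrow(panel$sites)
  frac <- matrix(NA_real_, n, p,
                 dimnames = list(cohort$sample_id, panel$sites$site_id))
  cov <- matrix(NA_integer_, n, p, dimnames = dimnames(frac))
  ri <- match(records$sample_id, cohort$sample_id)
  ci <- match(records$site_id, panel$sites$site_id)
  total <- records$count_methylated + records$count_unmethylated
  idx <- cbind(ri, ci)
  cov[idx] <- as.integer(total)
  frac[idx] <- ifelse(total > 0, records$count_methylated / total, NA_real_)
  structure(list(fraction = frac, coverage = cov,
                 sample_ids = cohort$sample_id,
                 site_ids = panel$sites$site_id),
            class = "meth_matrix")
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat("meth_matrix:", length(x$sample_ids), "samples x",
      length(x$site_ids), "sites;", sum(is.na(x$fraction)), "missing cells\n")
  invisible(x)
}

#' Extract methylation from FASTQ files for a whole cohort
#'
#' Convenience wrapper: [assign_reads()] + [count_methylation()] per sample,
#' [filter_coverage()], [build_matrix()].
#'
#' @param fastq_files Named character vector, `sample_id` -> FASTQ path.
#' @param panel An `amplicon_panel`.
#' @param cohort Cohort data.frame.
#' @param min_coverage Coverage cut-off (default 50).
#' @return A list with `matrix` (`meth_matrix`), `records` (pre-filter
#'   counts) and `discarded` (reads dropped per sample).
#' @export
extract_methylation <- function(fastq_files, panel, cohort,
                                min_coverage = 50L) {
  stopifnot(all(cohort$sample_id %in% names(fastq_files)))
  recs <- vector("list", nrow(cohort))
  disc <- setNames(integer(nrow(cohort)), cohort$sample_id)
  for (i in seq_len(nrow(cohort))) {
    sid <- cohort$sample_id[i]
    asg <- assign_reads(fastq_files[[sid]], panel)
    disc[i] <- asg$discarded
    recs[[i]] <- count_methylation(asg$groups, panel, sid)
  }
  records <- do.call(rbind, recs)
  kept <- filter_coverage(records, min_coverage)
  list(matrix = build_matrix(kept, cohort, panel),
       records = records, discarded = disc)
}

#' Write / read per-sample coverage files (Bismark coverage dialect)
#'
#' Tab-separated, one line per CpG:
#' `scaffold  start  end  methylation_percent  count_methylated
#' count_unmethylated`, with 1-based inclusive positions (start == end for a
#' single cytosine) and the percentage written with 6 decimal places.  The
#' reader reconstructs `site_id` as `"scaffold:start"`, errors on a malformed
#' line naming its line number, and warns when the stated percentage
#' disagrees with the counts by more than 0.01.
#'
#' @param records Count records for one sample.
#' @param path File path.
#' @param sample_id Sample label the reader attaches to the records.
#' @return `read_coverage_file()` returns a count-record data.frame.
#' @export
write_coverage_file <- function(records, path) {
  parts <- strsplit(records$site_id, ":", fixed = TRUE)
  scaf <- vapply(parts, `[`, character(1), 1L)
  pos <- as.integer(vapply(parts, `[`, character(1), 2L))
  total <- records$count_methylated + records$count_unmethylated
  pct <- ifelse(total > 0, 100 * records$count_methylated / total, 0)
  lines <- sprintf("%s\t%d\t%d\t%.6f\t%d\t%d", scaf, pos, pos, pct,
                   records$count_methylated, records$count_unmethylated)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_coverage_file
#' @export
read_coverage_file <- function(path, sample_id) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  out <- data.frame(sample_id = rep(sample_id, n),
                    site_id = character(n),
                    count_methylated = integer(n),
                    count_unmethylated = integer(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 6) {
      stop("malformed coverage line ", i, " in ", path,
           ": expected 6 tab-separated fields, got ", length(f))
    }
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    pct <- suppressWarnings(as.numeric(f[4]))
    cm <- suppressWarnings(as.numeric(f[5]))
    cu <- suppressWarnings(as.numeric(f[6]))
    if (anyNA(c(start, end, pct, cm, cu))) {
      stop("malformed coverage line ", i, " in ", path,
           ": non-numeric field")
    }
    if (cm < 0 || cu < 0) {
      stop("malformed coverage line ", i, " in ", path, ": negative count")
    }
    total <- cm + cu
    if (total > 0 && abs(pct - 100 * cm / total) > 0.01) {
      warning("coverage line ", i, " in ", path,
              ": stated percent ", pct, " inconsistent with counts")
    }
    out$site_id[i] <- paste0(f[1], ":", start)
    out$count_methylated[i] <- as.integer(cm)
    out$count_unmethylated[i] <- as.integer(cu)
  }
  out
}

#' Write / read the methylation matrix as TSV
#'
#' First column `sample_id`, one column per site, `NA` for missing cells.
#' Coverage is not stored in this format; a matrix read back has an all-`NA`
#' coverage slot.
#'
#' @param mm A `meth_matrix`.
#' @param path File path.
#' @export
write_matrix <- function(mm, path) {
  df <- data.frame(sample_id = mm$sample_ids, mm$fraction,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "sample_id") stop("matrix TSV must start with sample_id")
  frac <- as.matrix(df[, -1, drop = FALSE])
  mode(frac) <- "numeric"
  rownames(frac) <- df$sample_id
  structure(list(fraction = frac,
                 coverage = matrix(NA_integer_, nrow(frac), ncol(frac),
                                   dimnames = dimnames(frac)),
                 sample_ids = df$sample_id, site_ids = colnames(frac)),
            class = "meth_matrix")
}
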