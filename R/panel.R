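#' Generate a synthetic amplicon panel
#'
#' Creates an amplicon reference panel in the style of a targeted
#' bisulfite-PCR assay: `n_regions` amplicon sequences on distinct synthetic
#' scaffolds, together holding exactly `total_cpgs` CpG dinucleotides at known
#' offsets.  CpGs are split evenly across regions (the remainder assigned
#' round-robin to the first regions).  Background sequence is random but
#' scanned and repaired so it contains no CG dinucleotide other than the
#' planted sites — the count of "CG" substrings across the panel therefore
#' equals `total_cpgs` exactly.
#'
#' @param n_regions Number of amplicon regions (>= 1).
#' @param total_cpgs Total number of CpG sites across the panel
#'   (>= `n_regions`, so every region carries at least one site).
#' @param region_length Length of every region in bp; must leave room to place
#'   the per-region CpGs at least 2 bp apart.
#' @param seed Integer seed; the panel is a deterministic function of its
#'   arguments.
#' @param scaffold_prefix Prefix for the synthetic scaffold names.
#'
#' @return An object of class `amplicon_panel`: a list with
#'   * `regions`: data.frame with `region_id`, `scaffold`, `start`, `end`
#'     (1-based inclusive genomic coordinates) and `sequence`;
#'   * `sites`: data.frame with `site_id` (`"scaffold:pos"`, 1-based position
#'     of the C), `region_id` and `offset` (0-based offset of the C within the
#'     region sequence).
#' @export
#' @examples
#' panel <- make_panel(12, 51, 300, seed = 1)
#' nrow(panel$regions)  # 12
#' nrow(panel$sites)    # 51
make_panel <- function(n_regions, total_cpgs, region_length, seed = 1L,
                       scaffold_prefix = "scaffold") {
  stopifnot(n_regions >= 1, total_cpgs >= n_regions, region_length >= 2)
  per_region <- rep(total_cpgs %/% n_regions, n_regions)
  extra <- total_cpgs %% n_regions
  if (extra > 0) per_region[seq_len(extra)] <- per_region[seq_len(extra)] + 1L
  k_max <- max(per_region)
  # offsets drawn via the gap transform below need L - 1 - 2*(k-1) >= k slots
  if (region_length - 1L - 2L * (k_max - 1L) < k_max) {
    stop("infeasible geometry: cannot place ", k_max, " CpGs >= 2 bp apart ",
         "in a region of length ", region_length, " bp")
  }

  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  regions <- vector("list", n_regions)
  sites <- vector("list", n_regions)
  starts <- sort(sample.int(2000000L, n_regions)) + 100000L
  for (g in seq_len(n_regions)) {
    k <- per_region[g]
    L <- region_length
    # sorted distinct draws + growing shifts guarantee >= 2 bp spacing
    pos_c <- sort(sample.int(L - 1L - 2L * (k - 1L), k)) + 2L * (seq_len(k) - 1L)
    s <- sample(bases, L, replace = TRUE)
    s[pos_c] <- "C"
    s[pos_c + 1L] <- "G"
    # repair pass: kill every CG the background created by accident
    for (i in seq_len(L - 1L)) {
      if (s[i] == "C" && s[i + 1L] == "G" && !(i %in% pos_c)) {
        s[i + 1L] <- sample(c("A", "T"), 1L)
      }
    }
    seq_str <- paste(s, collapse = "")
    region_id <- sprintf("amp%02d", g)
    scaffold <- sprintf("%s_%03d", scaffold_prefix, g)
    regions[[g]] <- data.frame(
      region_id = region_id, scaffold = scaffold,
      start = starts[g], end = starts[g] + L - 1L,
      sequence = seq_str, stringsAsFactors = FALSE
    )
    sites[[g]] <- data.frame(
      site_id = sprintf("%s:%d", scaffold, starts[g] + pos_c - 1L),
      region_id = region_id, offset = pos_c - 1L, stringsAsFactors = FALSE
    )
  }
  panel <- structure(
    list(regions = do.call(rbind, regions), sites = do.call(rbind, sites)),
    class = "amplicon_panel"
  )
  validate_panel(panel)
  panel
}

validate_panel <- function(panel) {
  stopifnot(inherits(panel, "amplicon_panel"))
  reg <- panel$regions
  st <- panel$sites
  if (anyDuplicated(st$site_id)) stop("duplicate site_id in panel")
  if (!all(st$region_id %in% reg$region_id)) stop("site references unknown region")
  if (!all(reg$region_id %in% st$region_id)) stop("region without any CpG site")
  for (i in seq_len(nrow(st))) {
    seq_str <- reg$sequence[reg$region_id == st$region_id[i]]
    dinuc <- substr(seq_str, st$offset[i] + 1L, st$offset[i] + 2L)
    if (dinuc != "CG") {
      stop("site ", st$site_id[i], " does not point at a CG dinucleotide")
    }
  }
  invisible(panel)
}

#' @export
print.amplicon_panel <- function(x, ...) {
  cat("amplicon_panel:", nrow(x$regions), "regions,", nrow(x$sites),
      "CpG sites,", nchar(x$regions$sequence[1]), "bp per region\n")
  invisible(x)
}

#' Write / read an amplicon panel as FASTA + BED
#'
#' The FASTA holds one record per region (id = `region_id`); the BED holds the
#' genomic intervals (0-based half-open, name = `region_id`).  `read_panel()`
#' reconstructs the CpG site table by scanning the sequences for CG
#' dinucleotides, which is lossless because a panel contains no CG outside its
#' site list.
#'
#' @param panel An `amplicon_panel`.
#' @param fasta_path,bed_path File paths.
#' @return `write_panel()` returns the paths invisibly; `read_panel()` returns
#'   an `amplicon_panel`.
#' @export
write_panel <- function(panel, fasta_path, bed_path) {
  validate_panel(panel)
  seqs <- Biostrings::DNAStringSet(setNames(panel$regions$sequence,
                                            panel$regions$region_id))
  Biostrings::writeXStringSet(seqs, fasta_path)
  gr <- GenomicRanges::GRanges(
    seqnames = panel$regions$scaffold,
    ranges = IRanges::IRanges(start = panel$regions$start,
                              end = panel$regions$end),
    name = panel$regions$region_id
  )
  rtracklayer::export.bed(gr, bed_path)
  invisible(c(fasta = fasta_path, bed = bed_path))
}

#' @rdname write_panel
#' @export
read_panel <- function(fasta_path, bed_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  gr <- rtracklayer::import.bed(bed_path)
  bed <- data.frame(
    region_id = gr$name,
    scaffold = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  ord <- match(names(seqs), bed$region_id)
  if (anyNA(ord)) stop("FASTA and BED region ids do not match")
  bed <- bed[ord, , drop = FALSE]
  bed$sequence <- as.character(seqs)
  sites <- lapply(seq_len(nrow(bed)), function(g) {
    hits <- Biostrings::matchPattern("CG", seqs[[g]])
    off <- BiocGenerics::start(hits) - 1L
    data.frame(
      site_id = sprintf("%s:%d", bed$scaffold[g], bed$start[g] + off),
      region_id = bed$region_id[g], offset = off, stringsAsFactors = FALSE
    )
  })
  panel <- structure(
    list(regions = bed[, c("region_id", "scaffold", "start", "end", "sequence")],
         sites = do.call(rbind, sites)),
    class = "amplicon_panel"
  )
  rownames(panel$regions) <- NULL
  validate_panel(panel)
  panel
}
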