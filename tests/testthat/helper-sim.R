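# Shared fixture builders for the test suite.  Everything is generated in
# code from fixed seeds; nothing is read from disk.

# A small panel + drift model + cohort, cheap enough for per-test use.
tiny_study <- function(n_regions = 4, total_cpgs = 10, region_length = 120,
                       n_samples = 8, seed = 42, ...) {
  panel <- make_panel(n_regions, total_cpgs, region_length, seed = seed)
  extra <- list(...)
  if (!"n_admps" %in% names(extra)) {
    extra$n_admps <- max(1L, total_cpgs %/% 2L)
  }
  model <- do.call(drift_model,
                   c(list(panel = panel, seed = seed + 1), extra))
  cohort <- draw_cohort(n_samples, 39, 1144, "liver", "set1", seed = seed + 2)
  list(panel = panel, model = model, cohort = cohort)
}

# Full-size study-condition matrix: 51 sites / 23 planted aDMPs, n = 24
# livers aged 39-1144 weeks, sigma_b = 0.03, binomial counts at 200x.
study_matrix <- function(seed, tissue = "liver", n = 24,
                         age_min = 39, age_max = 1144,
                         panel = NULL, model = NULL, read_level = FALSE) {
  if (is.null(panel)) panel <- make_panel(12, 51, 300, seed = 1)
  if (is.null(model)) model <- drift_model(panel, n_admps = 23, seed = 1)
  cohort <- draw_cohort(n, age_min, age_max, tissue,
                        if (tissue == "liver") "set1" else "set2",
                        seed = seed)
  probs <- true_methylation(panel, cohort, model, seed = seed + 500)
  counts <- simulate_counts(panel, cohort, probs, model, seed = seed + 900)
  kept <- filter_coverage(counts, 50)
  list(panel = panel, model = model, cohort = cohort, probs = probs,
       matrix = build_matrix(kept, cohort, panel))
}

# Independent oracle for read assignment: literal Hamming distance of a read
# against one region's bisulfite-collapsed reference, written without any of
# the package's vectorised machinery.
oracle_bisulfite_distance <- function(read, region_seq, cpg_offsets) {
  rs <- strsplit(read, "")[[1]]
  gs <- strsplit(region_seq, "")[[1]]
  L <- max(length(rs), length(gs))
  d <- abs(length(rs) - length(gs))
  for (i in seq_len(min(length(rs), length(gs)))) {
    ref <- gs[i]
    is_cpg_c <- (i - 1) %in% cpg_offsets
    if (is_cpg_c) {
      if (!(rs[i] %in% c("C", "T"))) d <- d + 1
    } else {
      if (ref == "C") ref <- "T"
      if (rs[i] != ref) d <- d + 1
    }
  }
  d
}
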