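test_that("error-free reads are assigned back to their source region", {
  st <- tiny_study(sigma_b = 0, conversion_efficiency = 1,
                   sequencing_error_rate = 0, target_coverage = 8,
                   n_samples = 2)
  probs <- true_methylation(st$panel, st$cohort, st$model, seed = 1)
  sim <- simulate_reads(st$panel, st$cohort, probs, st$model,
                        tempfile(), seed = 1)
  asg <- assign_reads(sim$files[1], st$panel)
  expect_equal(asg$discarded, 0L)  # closed world: every read finds its home
  for (rid in names(asg$groups)) {
    nm <- names(asg$groups[[rid]])
    src <- vapply(strsplit(nm, "|", fixed = TRUE), `[`, character(1), 2)
    expect_true(all(src == rid))
  }
  total <- sum(lengths(asg$groups)) + asg$discarded
  expect_equal(total, 8L * nrow(st$panel$regions))
})

test_that("assignment distances match an explicit Hamming oracle", {
  st <- tiny_study(n_regions = 3, total_cpgs = 6, region_length = 80)
  set.seed(99)
  random_reads <- vapply(1:5, function(i)
    paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE), collapse = ""),
    character(1))
  names(random_reads) <- paste0("rnd", 1:5)
  # oracle: per-read minimum distance over all collapsed references
  oracle_min <- vapply(random_reads, function(r) {
    min(vapply(seq_len(3), function(g) {
      offs <- st$panel$sites$offset[
        st$panel$sites$region_id == st$panel$regions$region_id[g]]
      oracle_bisulfite_distance(r, st$panel$regions$sequence[g], offs)
    }, numeric(1)))
  }, numeric(1))
  asg <- assign_reads(random_reads, st$panel)
  # random 80-mers sit ~45 mismatches away; all must exceed ceil(8) and drop
  expect_true(all(oracle_min > ceiling(0.1 * 80)))
  expect_equal(asg$discarded, 5L)

  # a true read must be at oracle distance 0 from its own region
  probs <- matrix(1, 1, 6, dimnames = list("s1", st$panel$sites$site_id))
  co <- st$cohort[1, , drop = FALSE]; co$sample_id <- "s1"
  clean <- drift_model(st$panel, n_admps = 6, sigma_b = 0,
                       conversion_efficiency = 1,
                       sequencing_error_rate = 0, target_coverage = 1,
                       seed = 1)
  sim <- simulate_reads(st$panel, co, probs, clean, tempfile(), seed = 4)
  reads <- as.character(Biostrings::readDNAStringSet(sim$files[1],
                                                     format = "fastq"))
  offs1 <- st$panel$sites$offset[
    st$panel$sites$region_id == st$panel$regions$region_id[1]]
  expect_equal(oracle_bisulfite_distance(reads[1],
                                         st$panel$regions$sequence[1], offs1),
               0)
})

test_that("empty input yields empty groups and zero discards", {
  st <- tiny_study()
  asg <- assign_reads(character(0), st$panel)
  expect_equal(asg$discarded, 0L)
  expect_true(all(lengths(asg$groups) == 0))
})

test_that("methylation counting reads C as methylated and T as not", {
  panel <- make_panel(1, 2, 60, seed = 8)
  seq_str <- panel$regions$sequence[1]
  offs <- panel$sites$offset
  mk_read <- function(states) {  # states: "C" or "T" per site
    s <- strsplit(seq_str, "")[[1]]
    s[s == "C"] <- "T"
    s[offs + 1] <- states
    paste(s, collapse = "")
  }
  groups <- list(amp01 = setNames(
    c(replicate(7, mk_read(c("C", "C"))), replicate(3, mk_read(c("T", "C")))),
    paste0("r", 1:10)))
  rec <- count_methylation(groups, panel, "s1")
  expect_equal(rec$count_methylated, c(7L, 10L))
  expect_equal(rec$count_unmethylated, c(3L, 0L))
  frac <- rec$count_methylated /
    (rec$count_methylated + rec$count_unmethylated)
  expect_equal(frac, c(0.7, 1.0))
  # an ambiguous base is excluded from both counts
  odd <- strsplit(mk_read(c("C", "C")), "")[[1]]
  odd[offs[1] + 1] <- "N"
  groups$amp01[1] <- paste(odd, collapse = "")
  rec2 <- count_methylation(groups, panel, "s1")
  expect_equal(rec2$count_methylated[1] + rec2$count_unmethylated[1], 9L)
})

test_that("coverage is conserved end to end when error = 0", {
  st <- tiny_study(sigma_b = 0, conversion_efficiency = 1,
                   sequencing_error_rate = 0, target_coverage = 30,
                   n_samples = 2)
  probs <- true_methylation(st$panel, st$cohort, st$model, seed = 6)
  sim <- simulate_reads(st$panel, st$cohort, probs, st$model,
                        tempfile(), seed = 6)
  for (i in 1:2) {
    asg <- assign_reads(sim$files[i], st$panel)
    rec <- count_methylation(asg$groups, st$panel, st$cohort$sample_id[i])
    expect_true(all(rec$count_methylated + rec$count_unmethylated == 30L))
    # count-level agreement with the simulator's internal ledger
    led <- sim$ledger[sim$ledger$sample_id == st$cohort$sample_id[i], ]
    m <- merge(rec, led, by = "site_id")
    expect_equal(m$count_methylated, m$n_meth_drawn)
  }
})

test_that("coverage filter boundary: 49 dropped, 50 kept; idempotent and monotone", {
  rec <- data.frame(sample_id = "s", site_id = c("a:1", "a:2", "a:3"),
                    count_methylated = c(20L, 25L, 60L),
                    count_unmethylated = c(29L, 25L, 40L))
  kept <- filter_coverage(rec, 50)
  expect_equal(kept$site_id, c("a:2", "a:3"))     # 49 dropped, 50 retained
  expect_equal(filter_coverage(kept, 50), kept)   # idempotent
  expect_equal(filter_coverage(rec, 1), rec)      # identity at min_coverage 1
  # monotone: raising the threshold never un-hides a record
  for (thr in c(1, 40, 50, 51, 100, 101)) {
    expect_true(all(filter_coverage(rec, thr)$site_id %in%
                      filter_coverage(rec, max(thr - 10, 1))$site_id))
  }
})

test_that("matrix assembly preserves ratios and flags missing cells", {
  panel <- make_panel(1, 3, 80, seed = 2)
  cohort <- draw_cohort(2, 100, 1000, "liver", "set1", seed = 2)
  rec <- expand.grid(sample_id = cohort$sample_id,
                     site_id = panel$sites$site_id,
                     stringsAsFactors = FALSE)
  set.seed(1)
  rec$count_methylated <- rpois(6, 60)
  rec$count_unmethylated <- rpois(6, 60)
  mm <- build_matrix(rec, cohort, panel)
  expect_equal(dim(mm$fraction), c(2L, 3L))
  expect_false(anyNA(mm$fraction))
  for (k in seq_len(nrow(rec))) {
    expect_equal(mm$fraction[rec$sample_id[k], rec$site_id[k]],
                 rec$count_methylated[k] /
                   (rec$count_methylated[k] + rec$count_unmethylated[k]))
  }
  mm2 <- build_matrix(rec[-1, ], cohort, panel)
  expect_equal(sum(is.na(mm2$fraction)), 1L)
  expect_error(build_matrix(rbind(rec, rec[1, ]), cohort, panel), "duplicate")
})

test_that("coverage files round-trip and diagnose malformed input", {
  rec <- data.frame(sample_id = "s1",
                    site_id = c("JH602136:8746439", "scaffold_001:1200"),
                    count_methylated = c(88L, 10L),
                    count_unmethylated = c(12L, 90L))
  path <- tempfile(fileext = ".cov")
  write_coverage_file(rec, path)
  back <- read_coverage_file(path, "s1")
  expect_equal(back, rec)

  # the documented dialect parses field-by-field
  writeLines("JH602136\t8746439\t8746439\t88.0\t88\t12", path)
  one <- read_coverage_file(path, "sX")
  expect_equal(one$site_id, "JH602136:8746439")
  expect_equal(one$count_methylated, 88L)
  expect_equal(one$count_unmethylated, 12L)

  writeLines(c("JH602136\t1\t1\t50.0\t5\t5", "bad\tline"), path)
  expect_error(read_coverage_file(path, "s"), "line 2")
  writeLines("JH602136\t1\t1\t50.0\t-5\t5", path)
  expect_error(read_coverage_file(path, "s"), "negative count")
  writeLines("JH602136\t1\t1\t10.0\t5\t5", path)
  expect_warning(read_coverage_file(path, "s"), "inconsistent")
})

test_that("matrix TSV round-trips including missing cells", {
  st <- study_matrix(seed = 21, n = 6)
  mm <- st$matrix
  mm$fraction[2, 5] <- NA
  path <- tempfile(fileext = ".tsv")
  write_matrix(mm, path)
  back <- read_matrix(path)
  expect_equal(back$fraction, mm$fraction)
  expect_equal(back$sample_ids, mm$sample_ids)
  expect_equal(back$site_ids, mm$site_ids)
})

test_that("extraction recovers the planted probabilities within binomial error", {
  st <- tiny_study(n_regions = 3, total_cpgs = 9, n_samples = 4,
                   sigma_b = 0, conversion_efficiency = 1,
                   sequencing_error_rate = 0, target_coverage = 400)
  probs <- true_methylation(st$panel, st$cohort, st$model, seed = 8)
  sim <- simulate_reads(st$panel, st$cohort, probs, st$model,
                        tempfile(), seed = 8)
  ext <- extract_methylation(sim$files, st$panel, st$cohort, min_coverage = 50)
  dev <- abs(ext$matrix$fraction - probs)
  bound <- 3 * sqrt(probs * (1 - probs) / 400) + 1e-12
  expect_gte(mean(dev <= bound), 0.99)
})
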