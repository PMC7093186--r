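#' Default pipeline configuration
#'
#' The default run reproduces the study design the package targets: a
#' 12-amplicon / 51-CpG panel, a 24-liver training cohort aged 39-1,144
#' weeks, a 19-liver validation cohort and a 20-skin cohort aged 43-1,196
#' weeks, 23 planted aDMPs drifting linearly with age, 200x target coverage
#' against a 50x filter, and an elastic net with an equal L1/L2 mix.
#'
#' @param seed Master seed; each stage derives its own sub-seed from it.
#' @param outdir Output directory.
#' @return A nested configuration list (see [run_pipeline()]).
#' @export
default_config <- function(seed = 1L, outdir = tempfile("nmrclock_run_")) {
  list(
    seed = as.integer(seed),
    outdir = outdir,
    stages = c("simulate", "extract", "select", "fit", "predict",
               "evaluate", "rate"),
    read_level = TRUE,
    panel = list(n_regions = 12L, total_cpgs = 51L, region_length = 300L),
    drift = list(n_admps = 23L, slope_min = 3e-4, slope_max = 7e-4,
                 sigma_b = 0.03, conversion_efficiency = 0.99,
                 sequencing_error_rate = 0.001, target_coverage = 200L,
                 rate_liver = 1, rate_skin = 0.6),
    cohorts = list(
      list(name = "liver_set1", n = 24L, age_min = 39, age_max = 1144,
           tissue = "liver", batch = "set1", role = "train"),
      list(name = "liver_set2", n = 19L, age_min = 43, age_max = 1196,
           tissue = "liver", batch = "set2", role = "test"),
      list(name = "skin", n = 20L, age_min = 43, age_max = 1196,
           tissue = "skin", batch = "set2", role = "rate")
    ),
    min_coverage = 50L,
    admp_alpha = 0.05,
    enet = list(alpha_mix = 0.5, n_lambda = 100L)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Unspecified keys fall back to [default_config()]; unknown keys are
#' rejected.
#'
#' @param path YAML file.
#' @return A validated configuration list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_config(), user)
  validate_config(cfg)
}

validate_config <- function(config) {
  ref <- default_config()
  unknown <- setdiff(names(config), names(ref))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  for (sec in c("panel", "drift", "enet")) {
    bad <- setdiff(names(config[[sec]]), names(ref[[sec]]))
    if (length(bad)) stop("unknown config key(s) in '", sec, "': ",
                          paste(bad, collapse = ", "))
  }
  known_stages <- ref$stages
  bad <- setdiff(config$stages, known_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stopifnot(is.numeric(config$seed), length(config$seed) == 1)
  config
}

stage_seed <- function(config, stage) {
  # fixed small offsets keep every derived seed well below 2^31
  off <- c(simulate = 101L, extract = 211L, select = 307L, fit = 401L,
           predict = 503L, evaluate = 601L, rate = 701L)
  as.integer(config$seed) * 1000L + off[[stage]]
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in fixed order — simulate, extract, select,
#' fit, predict, evaluate, rate — inside `config$outdir`, and writes a
#' `manifest.json` recording the effective configuration, per-file MD5
#' checksums, the package version and every derived seed.  Re-running with an
#' identical configuration reproduces byte-identical outputs.  A stage
#' failure aborts with the stage name; files the failed stage had begun to
#' write are moved to a `quarantine/` subdirectory.
#'
#' Stage artifacts (synthetic mode): panel FASTA/BED and ground-truth site
#' table, per-cohort sample sheets and FASTQ files (`simulate`); per-sample
#' coverage files and per-cohort matrix TSVs (`extract`); the aDMP report and
#' selected-site list for the training cohort (`select`); the clock JSON and
#' LOOCV predictions (`fit`); predictions for the other cohorts (`predict`);
#' per-cohort metric JSONs (`evaluate`); the skin ageing-rate JSON (`rate`).
#'
#' With `config$read_level = FALSE` the simulate/extract pair operates on
#' binomial count draws ([simulate_counts()]) instead of FASTQ reads.
#'
#' @param config Configuration list (see [default_config()]).
#' @return Invisibly, a list with `outdir`, `manifest` and the in-memory
#'   stage results (`results`).
#' @export
run_pipeline <- function(config = default_config()) {
  config <- validate_config(config)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- intersect(c("simulate", "extract", "select", "fit", "predict",
                        "evaluate", "rate"), config$stages)
  state <- new.env(parent = emptyenv())
  state$files <- character(0)
  state$seeds <- list()

  run_stage <- function(name, fun) {
    if (!name %in% stages) return(invisible(NULL))
    before <- list.files(outdir, recursive = TRUE, full.names = TRUE)
    ok <- FALSE
    on.exit({
      if (!ok) {
        after <- list.files(outdir, recursive = TRUE, full.names = TRUE)
        newf <- setdiff(after, before)
        if (length(newf)) {
          qdir <- file.path(outdir, "quarantine")
          dir.create(qdir, showWarnings = FALSE)
          file.rename(newf, file.path(qdir, basename(newf)))
        }
      }
    }, add = TRUE)
    res <- tryCatch(fun(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    ok <- TRUE
    res
  }

  res <- list()

  res$simulate <- run_stage("simulate", function() {
    sd0 <- stage_seed(config, "simulate")
    state$seeds$simulate <- sd0
    pc <- config$panel
    panel <- make_panel(pc$n_regions, pc$total_cpgs, pc$region_length,
                        seed = sd0)
    write_panel(panel, file.path(outdir, "panel.fasta"),
                file.path(outdir, "panel.bed"))
    dc <- config$drift
    model <- drift_model(
      panel, n_admps = dc$n_admps,
      slope_range = c(dc$slope_min, dc$slope_max), sigma_b = dc$sigma_b,
      conversion_efficiency = dc$conversion_efficiency,
      sequencing_error_rate = dc$sequencing_error_rate,
      target_coverage = dc$target_coverage,
      tissue_rates = c(liver = dc$rate_liver, skin = dc$rate_skin),
      seed = sd0 + 1L
    )
    write_truth(model, file.path(outdir, "truth_sites.tsv"))
    cohorts <- list()
    for (k in seq_along(config$cohorts)) {
      cc <- config$cohorts[[k]]
      cohort <- draw_cohort(cc$n, cc$age_min, cc$age_max, cc$tissue,
                            cc$batch, seed = sd0 + 10L + k)
      write_samples(cohort, file.path(outdir,
                                      paste0("samples_", cc$name, ".tsv")))
      probs <- true_methylation(panel, cohort, model, seed = sd0 + 20L + k)
      entry <- list(name = cc$name, role = cc$role, cohort = cohort,
                    probs = probs)
      if (isTRUE(config$read_level)) {
        sim <- simulate_reads(panel, cohort, probs, model,
                              outdir = file.path(outdir, "fastq", cc$name),
                              seed = sd0 + 30L + k)
        entry$fastq <- sim$files
        entry$ledger <- sim$ledger
      } else {
        entry$counts <- simulate_counts(panel, cohort, probs, model,
                                        seed = sd0 + 30L + k)
      }
      cohorts[[cc$name]] <- entry
    }
    list(panel = panel, model = model, cohorts = cohorts)
  })

  res$extract <- run_stage("extract", function() {
    sim <- res$simulate
    if (is.null(sim)) stop("simulate outputs not available in this run")
    panel <- sim$panel
    out <- list()
    for (nm in names(sim$cohorts)) {
      entry <- sim$cohorts[[nm]]
      if (!is.null(entry$fastq)) {
        ext <- extract_methylation(entry$fastq, panel, entry$cohort,
                                   min_coverage = config$min_coverage)
        mm <- ext$matrix
        covdir <- file.path(outdir, "coverage", nm)
        dir.create(covdir, showWarnings = FALSE, recursive = TRUE)
        for (sid in entry$cohort$sample_id) {
          write_coverage_file(ext$records[ext$records$sample_id == sid, ],
                              file.path(covdir, paste0(sid, ".cov")))
        }
      } else {
        kept <- filter_coverage(entry$counts, config$min_coverage)
        mm <- build_matrix(kept, entry$cohort, panel)
      }
      write_matrix(mm, file.path(outdir, paste0("matrix_", nm, ".tsv")))
      out[[nm]] <- mm
    }
    out
  })

  train_name <- NULL
  for (cc in config$cohorts) if (identical(cc$role, "train")) train_name <- cc$name
  if (is.null(train_name)) train_name <- config$cohorts[[1]]$name

  res$select <- run_stage("select", function() {
    mm <- res$extract[[train_name]]
    if (is.null(mm)) stop("extract outputs not available in this run")
    ages <- res$simulate$cohorts[[train_name]]$cohort$age_weeks
    stats <- admp_scan(mm, ages)
    write.table(stats, file.path(outdir, "admp_report.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    sel <- select_admps(stats, alpha = config$admp_alpha)
    writeLines(sel, file.path(outdir, "selected_sites.txt"))
    list(stats = stats, selected = sel)
  })

  res$fit <- run_stage("fit", function() {
    if (is.null(res$select)) stop("select outputs not available in this run")
    mm <- res$extract[[train_name]]
    ages <- res$simulate$cohorts[[train_name]]$cohort$age_weeks
    sel <- res$select$selected
    model <- fit_clock(mm, ages, sites = sel,
                       alpha_mix = config$enet$alpha_mix,
                       n_lambda = config$enet$n_lambda)
    write_clock(model, file.path(outdir, "model.json"))
    loocv <- loocv_predict(mm, ages, sites = sel,
                           alpha_mix = config$enet$alpha_mix,
                           n_lambda = config$enet$n_lambda)
    write_predictions(loocv, ages, file.path(outdir, "loocv_pred.tsv"))
    list(model = model, loocv = loocv)
  })

  res$predict <- run_stage("predict", function() {
    if (is.null(res$fit)) stop("fit outputs not available in this run")
    preds <- list()
    for (nm in names(res$extract)) {
      if (nm == train_name) next
      p <- predict_ages(res$fit$model, res$extract[[nm]])
      write_predictions(p, res$simulate$cohorts[[nm]]$cohort$age_weeks,
                        file.path(outdir, paste0("pred_", nm, ".tsv")))
      preds[[nm]] <- p
    }
    preds
  })

  res$evaluate <- run_stage("evaluate", function() {
    if (is.null(res$fit)) stop("fit outputs not available in this run")
    mets <- list()
    ages1 <- res$simulate$cohorts[[train_name]]$cohort$age_weeks
    mets[[paste0("loocv_", train_name)]] <-
      evaluate_predictions(res$fit$loocv, ages1)
    for (nm in names(res$predict)) {
      mets[[nm]] <- evaluate_predictions(
        res$predict[[nm]], res$simulate$cohorts[[nm]]$cohort$age_weeks)
    }
    for (nm in names(mets)) {
      jsonlite::write_json(unclass(mets[[nm]]),
                           file.path(outdir, paste0("metrics_", nm, ".json")),
                           auto_unbox = TRUE, digits = NA)
    }
    mets
  })

  res$rate <- run_stage("rate", function() {
    if (is.null(res$predict)) stop("predict outputs not available in this run")
    rates <- list()
    for (cc in config$cohorts) {
      if (!identical(cc$role, "rate")) next
      nm <- cc$name
      rate <- estimate_tissue_rate(
        res$predict[[nm]], res$simulate$cohorts[[nm]]$cohort$age_weeks)
      jsonlite::write_json(rate, file.path(outdir,
                                           paste0("rate_", nm, ".json")),
                           auto_unbox = TRUE, digits = NA)
      rates[[nm]] <- rate
    }
    rates
  })

  files <- sort(list.files(outdir, recursive = TRUE))
  files <- files[files != "manifest.json"]
  sums <- tools::md5sum(file.path(outdir, files))
  manifest <- list(
    package_version = as.character(packageVersion("nmrclock")),
    config = config[setdiff(names(config), "outdir")],
    stages_run = stages,
    seeds = state$seeds,
    checksums = setNames(as.list(unname(sums)), files)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(outdir = outdir, manifest = manifest, results = res))
}

write_predictions <- function(predicted, actual, path) {
  df <- data.frame(sample_id = names(predicted),
                   predicted_age_weeks = unname(predicted),
                   actual_age_weeks = actual,
                   residual = unname(predicted) - actual,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a study's methylation matrix and sample metadata
#'
#' Real-data entry point: reads a methylation matrix TSV (first column
#' `sample_id`, one column per CpG, `NA` for cells below the coverage filter)
#' and a sample sheet (`sample_id`, `age_weeks`, `tissue`, `batch`).  Samples
#' present in only one of the two files are reported in a reconciliation
#' table; a missing or non-numeric age, or a duplicate sample id, is an
#' error.
#'
#' @param matrix_path Matrix TSV path (see [write_matrix()]).
#' @param samples_path Sample sheet path (see [write_samples()]).
#' @return List with `matrix` (a `meth_matrix` restricted to the shared
#'   samples, in sheet order), `samples` (likewise), and `reconciliation`
#'   (data.frame of `sample_id`, `where` for the unmatched ones; zero rows
#'   when the files agree).
#' @export
load_study_tables <- function(matrix_path, samples_path) {
  mm <- read_matrix(matrix_path)
  samples <- read_samples(samples_path)
  only_matrix <- setdiff(mm$sample_ids, samples$sample_id)
  only_sheet <- setdiff(samples$sample_id, mm$sample_ids)
  recon <- data.frame(
    sample_id = c(only_matrix, only_sheet),
    where = c(rep("matrix_only", length(only_matrix)),
              rep("sheet_only", length(only_sheet))),
    stringsAsFactors = FALSE
  )
  if (nrow(recon)) {
    message("sample sets differ between matrix and sheet (",
            nrow(recon), " unmatched); see $reconciliation")
  }
  shared <- intersect(samples$sample_id, mm$sample_ids)
  if (length(shared) == 0) stop("no samples shared between matrix and sheet")
  samples <- samples[samples$sample_id %in% shared, , drop = FALSE]
  idx <- match(samples$sample_id, mm$sample_ids)
  mm$fraction <- mm$fraction[idx, , drop = FALSE]
  mm$coverage <- mm$coverage[idx, , drop = FALSE]
  mm$sample_ids <- samples$sample_id
  list(matrix = mm, samples = samples, reconciliation = recon)
}
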