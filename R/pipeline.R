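# End-to-end pipeline: inputs -> preprocess -> reliability -> regression
# -> SOM profiles, with a reproducibility manifest.

#' Pipeline configuration
#'
#' Bundles every setting of the end-to-end analysis. Defaults are the
#' package's standard analysis settings: detection threshold 0.60, 1000
#' bootstrap resamples for ICC intervals, 25 imputed datasets, SOM
#' candidates from 4 to 25 profiles.
#'
#' @param input_dir Directory with `exposure.csv`, `chemicals.csv`,
#'   `covariates.csv` and optionally `exposure_repeated.csv`; `NULL` to
#'   simulate a cohort from `sim` instead.
#' @param sim A [sim_config()] used when `input_dir` is `NULL`; defaults
#'   to `sim_config(seed = seed)`.
#' @param detection_threshold Detection fraction for
#'   [filter_by_detection()].
#' @param n_boot Bootstrap resamples for [estimate_icc()].
#' @param imputation An [impute_spec()].
#' @param som_min,som_max SOM candidate profile-count range.
#' @param som_epochs Training epochs per candidate.
#' @param seed Global integer seed; stage seeds are derived from it.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, sim = NULL,
                            detection_threshold = 0.60, n_boot = 1000,
                            imputation = impute_spec(), som_min = 4,
                            som_max = 25, som_epochs = 100, seed = 1L) {
  if (is.null(input_dir) && is.null(sim)) sim <- sim_config(seed = seed)
  structure(list(input_dir = input_dir, sim = sim,
                 detection_threshold = detection_threshold,
                 n_boot = n_boot, imputation = imputation,
                 som_min = som_min, som_max = som_max,
                 som_epochs = som_epochs, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys mirror the arguments of [pipeline_config()]
#' (`input_dir`, `detection_threshold`, `n_boot`, `som_min`, `som_max`,
#' `som_epochs`, `seed`, and nested `imputation:` with `m`, `n_iter`,
#' `pmm_k`, plus nested `sim:` passed to [sim_config()]).
#'
#' @param path YAML file path.
#' @param seed Optional seed overriding the file's.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(seed)) y$seed <- seed
  if (is.null(y$seed)) y$seed <- 1L
  imp <- do.call(impute_spec, as.list(y$imputation))
  sim <- if (!is.null(y$sim)) {
    do.call(sim_config, c(as.list(y$sim), list(seed = y$seed)))
  } else NULL
  keep <- intersect(names(y), c("input_dir", "detection_threshold",
                                "n_boot", "som_min", "som_max",
                                "som_epochs", "seed"))
  do.call(pipeline_config, c(y[keep], list(imputation = imp, sim = sim)))
}

#' Run the full wristband analysis pipeline
#'
#' Executes preprocessing (detection summary, >threshold filter, counts,
#' batch-median standardization), reliability (Spearman matrix; ICCs when
#' a repeated-measures table is available), the multiply-imputed
#' regression suite, and SOM profile discovery with validity-consensus
#' size selection. All stage outputs are written as CSV under `out_dir`
#' together with `manifest.json` recording the seed, settings and
#' per-stage dimensions. A rerun with the same configuration and seed
#' produces byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return Invisibly, the manifest list (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  manifest <- list(package = "exposband",
                   version = as.character(utils::packageVersion("exposband")),
                   seed = config$seed,
                   settings = list(
                     detection_threshold = config$detection_threshold,
                     n_boot = config$n_boot,
                     m_imputations = config$imputation$m,
                     som_profiles = c(config$som_min, config$som_max)),
                   stages = list(), outputs = character(0))
  emit <- function(name) {
    manifest$outputs <<- c(manifest$outputs, name)
    file.path(out_dir, name)
  }

  # ---- inputs -------------------------------------------------------
  # stage results are assigned with <- from inside stage() closures
  em <- chemicals <- cov <- det <- filt <- std <- counts <- NULL
  sp <- icc <- suite <- sel <- rep_prof <- NULL
  repeated <- NULL
  if (is.null(config$input_dir)) {
    say("stage inputs: simulating cohort (seed %d)", config$sim$seed)
    cohort <- stage("inputs", simulate_cohort(config$sim))
    em <- cohort$matrix; chemicals <- cohort$chemicals
    cov <- cohort$covariates
    if (config$sim$n_repeated >= 2) {
      repeated <- simulate_repeated(config$sim)$matrix
    }
  } else {
    say("stage inputs: reading %s", config$input_dir)
    stage("inputs", {
      rd <- read_exposure_csv(file.path(config$input_dir, "exposure.csv"),
                              file.path(config$input_dir, "chemicals.csv"))
      em <- rd$matrix; chemicals <- rd$chemicals
      cov <- read_covariates(file.path(config$input_dir, "covariates.csv"))
      rp <- file.path(config$input_dir, "exposure_repeated.csv")
      if (file.exists(rp)) {
        repeated <- read_exposure_csv(
          rp, file.path(config$input_dir, "chemicals.csv"))$matrix
      }
    })
  }
  manifest$stages$inputs <- list(samples = nrow(em$concentrations),
                                 chemicals = ncol(em$concentrations),
                                 repeated = !is.null(repeated))

  # ---- preprocess ---------------------------------------------------
  say("stage preprocess: detection screen at > %.2f",
      config$detection_threshold)
  stage("preprocess", {
    det <- detection_frequency(em)
    utils::write.csv(det, emit("detection_summary.csv"), row.names = FALSE)
    filt <- filter_by_detection(em, config$detection_threshold)
    std <- batch_standardize(filt)
    utils::write.csv(
      data.frame(participant = std$participant, timepoint = std$timepoint,
                 batch = std$batch, std$values, check.names = FALSE),
      emit("standardized.csv"), row.names = FALSE)
    counts <- counts_per_wristband(em, chemicals)
    utils::write.csv(counts, emit("counts.csv"), row.names = FALSE)
  })
  manifest$stages$preprocess <- list(
    retained_chemicals = ncol(filt$concentrations),
    median_detects_per_wristband = stats::median(counts$total))

  # ---- reliability --------------------------------------------------
  say("stage reliability: Spearman structure%s",
      if (is.null(repeated)) " (no repeated data; ICC skipped)" else
        " + ICC bootstrap")
  stage("reliability", {
    sp <- spearman_matrix(std)
    utils::write.csv(data.frame(chemical = rownames(sp$rho), sp$rho,
                                check.names = FALSE),
                     emit("spearman.csv"), row.names = FALSE)
    if (!is.null(repeated)) {
      det_rep <- do.call(pmax, lapply(split(
        seq_along(repeated$timepoint), repeated$timepoint),
        function(i) colMeans(repeated$concentrations[i, , drop = FALSE] > 0)))
      keep <- which(det_rep > config$detection_threshold)
      std_rep <- batch_standardize(em_keep_chemicals(repeated, keep))
      icc <- icc_by_chemical(std_rep, n_boot = config$n_boot,
                              seed = config$seed + 1000L)
      utils::write.csv(icc, emit("icc.csv"), row.names = FALSE)
    } else icc <- NULL
  })
  manifest$stages$reliability <- list(
    spearman_median = unname(sp$summary$median),
    icc = if (is.null(icc)) "skipped (no repeated-measures data)" else
      list(chemicals = nrow(icc),
           median_icc = stats::median(icc$icc)))

  # ---- regression ---------------------------------------------------
  say("stage regression: %d models x %d imputations",
      ncol(std$values) + 15, config$imputation$m)
  stage("regression", {
    imp <- config$imputation
    imp$seed <- config$seed + 2000L
    wk1 <- std$timepoint == sort(unique(std$timepoint))[1]
    std1 <- std
    std1$values <- std1$values[wk1, , drop = FALSE]
    std1$participant <- std1$participant[wk1]
    std1$timepoint <- std1$timepoint[wk1]
    std1$batch <- std1$batch[wk1]
    wear <- if (!is.null(em$wear))
      data.frame(participant = em$participant, em$wear,
                 stringsAsFactors = FALSE) else NULL
    suite <- withCallingHandlers(
      run_model_suite(std1, counts, cov, imp, wear = wear),
      warning = function(w) {
        say("  warning: %s", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    long <- do.call(rbind, lapply(names(suite), function(nm) {
      p <- suite[[nm]]$pooled
      data.frame(model = nm, term = p$term, estimate = p$estimate,
                 ci_low = p$ci_low, ci_high = p$ci_high,
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(long, emit("models.csv"), row.names = FALSE)
  })
  manifest$stages$regression <- list(
    models = length(suite), skipped = attr(suite, "skipped"))

  # ---- SOM profiles -------------------------------------------------
  say("stage som: candidates %d-%d profiles", config$som_min,
      config$som_max)
  stage("som", {
    wk1 <- std$timepoint == sort(unique(std$timepoint))[1]
    std1 <- std
    std1$values <- std1$values[wk1, , drop = FALSE]
    std1$participant <- std1$participant[wk1]
    std1$timepoint <- std1$timepoint[wk1]
    std1$batch <- std1$batch[wk1]
    sel <- select_som_size(std1, config$som_min, config$som_max,
                            epochs = config$som_epochs,
                            seed = config$seed + 3000L)
    utils::write.csv(sel$report, emit("validity.csv"), row.names = FALSE)
    utils::write.csv(
      data.frame(node = seq_len(nrow(sel$fit$codebook)), sel$fit$codebook,
                 check.names = FALSE),
      emit("codebook.csv"), row.names = FALSE)
    utils::write.csv(
      data.frame(participant = std1$participant,
                 profile = sel$fit$assignment),
      emit("assignments.csv"), row.names = FALSE)
    rep_prof <- characterize_profiles(sel$fit, std1, cov)
    if (!is.null(rep_prof$covariates)) {
      utils::write.csv(rep_prof$covariates, emit("profile_report.csv"),
                       row.names = FALSE)
    }
  })
  chosen <- sel$report[sel$report$selected, ]
  manifest$stages$som <- list(
    grid = c(chosen$rows, chosen$cols),
    profiles_nodes = chosen$n_profiles,
    profiles_occupied = chosen$occupied,
    rare_profiles = length(rep_prof$rare))

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$outputs <- c(manifest$outputs, "manifest.json")
  say("pipeline complete: %d output files in %s",
      length(manifest$outputs), out_dir)
  invisible(manifest)
}
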