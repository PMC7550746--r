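# Synthetic wristband cohort generator with known ground truth.

#' Published summary of frequently detected wristband chemicals
#'
#' Per-chemical summary statistics published for a prospective pregnancy
#' cohort in which 255 participants wore a silicone wristband for one week
#' at ~12 gestational weeks and a subset of 20 wore a second wristband at
#' ~24 weeks: detection percentages, concentration medians and quartiles
#' (ng/g silicone), intraclass correlations between the two timepoints with
#' 95% bootstrap confidence intervals, and chemical category memberships,
#' for the 17 chemicals detected most frequently. Ships with the package
#' and seeds the defaults of [sim_config()], so the synthetic cohort
#' reproduces the detection and reliability structure reported for the
#' real deployment.
#'
#' @return Data frame with columns `chemical`, `casn`, `pct_detected_12wk`,
#'   `median_12wk`, `q1_12wk`, `q3_12wk`, `pct_detected_24wk`,
#'   `median_24wk`, `q1_24wk`, `q3_24wk`, `icc`, `icc_ci_low`,
#'   `icc_ci_high`, `categories` (semicolon-separated).
#' @export
frequent_chemicals <- function() {
  path <- system.file("extdata", "frequent_chemicals.csv",
                      package = "exposband", mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Simulation configuration for a synthetic wristband cohort
#'
#' Builds the configuration consumed by [simulate_cohort()] and
#' [simulate_repeated()]. Concentrations follow a base-10 lognormal model:
#' the log10 concentration of chemical c in participant i is
#' `log_mu[c] + profile shift + batch shift + covariate effects + noise`,
#' and values below the chemical's quantitation limit are recorded as 0
#' (non-detect). Defaults emulate the cohort the package was written for:
#' 255 participants, 40 chemicals of which the 17 most frequently detected
#' carry the published names, detection percentages, medians and
#' intraclass correlations of [frequent_chemicals()], 3 analytical
#' batches, and a 20-participant repeated-measures subsample at a second
#' timepoint.
#'
#' Per-chemical quantitation limits are derived from the detection targets:
#' `loq = 10^(log_mu - log_sigma * qnorm(det))`, so the expected detection
#' fraction of each chemical equals its target.
#'
#' @param n_participants Number of participants (default 255).
#' @param n_chemicals Number of chemicals (default 40; the first 17 are the
#'   published frequently detected chemicals, the rest are background
#'   screen chemicals with lower detection).
#' @param n_batches Number of analytical batches (default 3).
#' @param det Per-chemical target detection fraction (length
#'   `n_chemicals`).
#' @param log_mu Per-chemical mean of log10 concentration (log10 ng/g);
#'   default: log10 of the published medians for the named chemicals, 1.0
#'   for background chemicals.
#' @param log_sigma Per-chemical SD of log10 concentration (default 0.6,
#'   consistent with the published interquartile ratios).
#' @param loq Per-chemical quantitation limit (ng/g); default derived from
#'   `det` as above.
#' @param batch_shift_sd SD of the per-(batch, chemical) additive shift on
#'   the log10 scale (default 0.1).
#' @param profile_spec List of latent exposure profiles, each a list with
#'   elements `weight` (membership probability; weights sum to 1) and
#'   `shift` (named numeric vector of log10 shifts applied to that
#'   profile's members). The default plants a dominant low-exposure
#'   profile plus four smaller profiles elevated on one or two named
#'   chemicals, mirroring the published profile structure.
#' @param covariate_effects List of planted covariate effects, each a list
#'   with `covariate`, `level` (`NULL` for a numeric covariate, in which
#'   case the shift is per unit), `chemicals` (names or indices) and
#'   `shift` (log10 scale).
#' @param icc_targets Two-column matrix (`sigma2_between`, `sigma2_within`)
#'   per chemical for the repeated-measures design; default splits the
#'   cross-sectional log-scale variance according to the published ICCs
#'   (background chemicals get ICC 0.2).
#' @param n_repeated Number of participants with a second timepoint
#'   (default 20).
#' @param week_effect Fixed log10 shift of the second timepoint (default
#'   +0.2, matching the generally higher second-timepoint medians).
#' @param missing_rates Named vector of MCAR missingness rates for
#'   covariates (defaults reproduce the published reduced denominators for
#'   education, marital status and smoke exposure).
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration and seed.
#' @return An object of class `sim_config` (a list of the above, with
#'   derived fields `chemicals` — metadata data frame — and `true_icc`).
#' @seealso [simulate_cohort()], [simulate_repeated()]
#' @export
sim_config <- function(n_participants = 255, n_chemicals = 40,
                       n_batches = 3, det = NULL, log_mu = NULL,
                       log_sigma = 0.6, loq = NULL, batch_shift_sd = 0.1,
                       profile_spec = NULL, covariate_effects = NULL,
                       icc_targets = NULL, n_repeated = 20,
                       week_effect = 0.2, missing_rates = NULL, seed = 1L) {
  if (n_participants < 1 || n_chemicals < 1) {
    stop("degenerate configuration: need at least 1 participant and 1 chemical",
         call. = FALSE)
  }
  if (n_repeated > n_participants) {
    stop("n_repeated cannot exceed n_participants", call. = FALSE)
  }
  fc <- frequent_chemicals()
  n_named <- min(nrow(fc), n_chemicals)
  chem <- character(n_chemicals)
  chem[seq_len(n_named)] <- fc$chemical[seq_len(n_named)]
  casn <- character(n_chemicals)
  casn[seq_len(n_named)] <- fc$casn[seq_len(n_named)]
  cats <- character(n_chemicals)
  cats[seq_len(n_named)] <- fc$categories[seq_len(n_named)]
  if (n_chemicals > n_named) {
    idx <- seq.int(n_named + 1L, n_chemicals)
    chem[idx] <- sprintf("screen%03d", idx)
    casn[idx] <- sprintf("%d-%02d-%d", 100000L + idx, idx %% 100L,
                         idx %% 10L)
    pool <- chemical_categories()
    cats[idx] <- pool[(idx - 1L) %% length(pool) + 1L]
    # every third background chemical is multi-category
    two <- idx[idx %% 3L == 0L]
    cats[two] <- paste(cats[two], pool[two %% length(pool) + 1L], sep = ";")
  }
  chemicals <- validate_chemicals(
    data.frame(chemical = chem, casn = casn, categories = cats,
               stringsAsFactors = FALSE))

  if (is.null(det)) {
    det <- numeric(n_chemicals)
    det[seq_len(n_named)] <- fc$pct_detected_12wk[seq_len(n_named)] / 100
    if (n_chemicals > n_named) {
      det[seq.int(n_named + 1L, n_chemicals)] <-
        seq(0.55, 0.05, length.out = n_chemicals - n_named)
    }
  }
  log_sigma <- rep_len(log_sigma, n_chemicals)
  if (is.null(log_mu)) {
    log_mu <- rep(1.0, n_chemicals)
    log_mu[seq_len(n_named)] <- log10(pmax(fc$median_12wk[seq_len(n_named)], 10))
  }
  if (is.null(loq)) {
    loq <- 10^(log_mu - log_sigma * stats::qnorm(det))
  }
  loq <- rep_len(loq, n_chemicals)

  if (is.null(profile_spec)) {
    profile_spec <- default_profile_spec(chem)
  }
  w <- vapply(profile_spec, function(p) p$weight, 0)
  if (abs(sum(w) - 1) > 1e-8) {
    stop("profile weights must sum to 1", call. = FALSE)
  }
  if (is.null(covariate_effects)) {
    covariate_effects <- default_covariate_effects(chem)
  }
  if (is.null(icc_targets)) {
    icc <- rep(0.2, n_chemicals)
    icc[seq_len(n_named)] <- fc$icc[seq_len(n_named)]
    icc_targets <- cbind(sigma2_between = icc * log_sigma^2,
                         sigma2_within = (1 - icc) * log_sigma^2)
  }
  if (any(icc_targets < 0)) stop("variance components must be >= 0",
                                 call. = FALSE)
  if (is.null(missing_rates)) {
    missing_rates <- c(education = 0.30, marital = 0.28,
                       smoke_exposure = 0.31)
  }
  structure(
    list(n_participants = as.integer(n_participants),
         n_chemicals = as.integer(n_chemicals),
         n_batches = as.integer(n_batches),
         chemicals = chemicals, det = det, log_mu = log_mu,
         log_sigma = log_sigma, loq = loq,
         batch_shift_sd = batch_shift_sd, profile_spec = profile_spec,
         covariate_effects = covariate_effects, icc_targets = icc_targets,
         n_repeated = as.integer(n_repeated), week_effect = week_effect,
         missing_rates = missing_rates, seed = as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d participants x %d chemicals, %d batches, %d repeated\n",
    x$n_participants, x$n_chemicals, x$n_batches, x$n_repeated))
  cat(sprintf("  latent profiles: %d (weights %s)\n", length(x$profile_spec),
              paste(sprintf("%.2f", vapply(x$profile_spec, `[[`, 0, "weight")),
                    collapse = ", ")))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# dominant low-exposure profile + small profiles elevated on 1-2 chemicals,
# shaped like the published 12-profile map's interpretable profiles
default_profile_spec <- function(chem) {
  sh <- function(...) {
    v <- c(...)
    v[names(v) %in% chem]
  }
  list(
    list(weight = 0.62, shift = sh("Di-n-butyl phthalate" = -0.15)),
    list(weight = 0.05,
         shift = sh("Diisobutyl phthalate" = 0.9, "Di-n-butyl phthalate" = 0.9)),
    list(weight = 0.09, shift = sh("Butyl benzyl phthalate" = 0.9)),
    list(weight = 0.15,
         shift = sh("Galaxolide" = 0.9, "Benzyl benzoate" = 0.9)),
    list(weight = 0.09, shift = sh("2,4-Di-tert-butylphenol" = 0.9))
  )
}

# planted covariate effects (log10 shifts): nail polish on triphenyl
# phosphate and diethyl phthalate, summer benzophenone, seasonal deficits
# in background detections, small post-graduate deficit
default_covariate_effects <- function(chem) {
  bg <- chem[grepl("^screen", chem)]
  eff <- list(
    list(covariate = "nail_polish_use", level = "yes",
         chemicals = "Triphenyl phosphate", shift = 0.16),
    list(covariate = "nail_polish_use", level = "yes",
         chemicals = "Diethyl phthalate", shift = 0.18),
    list(covariate = "season", level = "summer",
         chemicals = "Benzophenone", shift = 0.13),
    list(covariate = "season", level = "summer", chemicals = bg,
         shift = -0.17),
    list(covariate = "season", level = "winter", chemicals = bg,
         shift = -0.13),
    list(covariate = "education", level = "any post-graduate",
         chemicals = bg, shift = -0.10)
  )
  Filter(function(e) length(e$chemicals) > 0, eff)
}

# draw per-participant covariates shaped like the cohort's Table-1-style
# marginals; season follows the wristband start date
draw_covariates <- function(n) {
  rcat <- function(levels, prob) {
    factor(sample(levels, n, replace = TRUE, prob = prob), levels = levels)
  }
  start <- as.Date("2017-03-01") + sample.int(640L, n, replace = TRUE)
  data.frame(
    participant = sprintf("P%03d", seq_len(n)),
    age_years = round(stats::rnorm(n, 31.5, 4.5), 1),
    bmi = round(stats::rlnorm(n, log(25.5), 0.22), 1),
    education = rcat(.covariate_levels$education, c(0.25, 0.44, 0.31)),
    marital = rcat(.covariate_levels$marital, c(0.82, 0.18)),
    race_ethnicity = rcat(.covariate_levels$race_ethnicity, c(0.78, 0.22)),
    parity = rcat(.covariate_levels$parity, c(0.47, 0.53)),
    smoke_exposure = rcat(.covariate_levels$smoke_exposure, c(0.86, 0.14)),
    nail_polish_use = rcat(.covariate_levels$nail_polish_use, c(0.5, 0.5)),
    handwashing_per_day = pmax(0, round(stats::rnorm(n, 9.5, 3))),
    gardening = rcat(.covariate_levels$gardening, c(0.75, 0.25)),
    gestational_age_start = pmin(20, pmax(10, round(stats::rnorm(n, 13.3, 1.8), 1))),
    start_date = start,
    stringsAsFactors = FALSE)
}

# log10 shift matrix (n x n_chem) implied by the planted covariate effects
covariate_shift_matrix <- function(cfg, cov, season) {
  chem <- cfg$chemicals$chemical
  shift <- matrix(0, nrow(cov), cfg$n_chemicals,
                  dimnames = list(NULL, chem))
  for (e in cfg$covariate_effects) {
    x <- if (identical(e$covariate, "season")) season else cov[[e$covariate]]
    w <- if (is.null(e$level)) {
      v <- as.numeric(x)
      ifelse(is.na(v), 0, v)
    } else {
      as.numeric(!is.na(x) & as.character(x) == e$level)
    }
    cols <- if (is.character(e$chemicals)) match(e$chemicals, chem) else e$chemicals
    cols <- cols[!is.na(cols)]
    shift[, cols] <- shift[, cols] + outer(w, rep(e$shift, length(cols)))
  }
  shift
}

#' Simulate a wristband cohort with known truth
#'
#' Draws covariates, latent profile memberships, batch effects and
#' left-censored lognormal concentrations according to a [sim_config()],
#' then applies MCAR missingness to the configured covariates. The
#' returned truth ledger records everything downstream stages try to
#' recover: profile labels, per-chemical true ICCs, and the planted
#' covariate effects both on the log10 scale and in SD units of the
#' standardized concentration scale.
#'
#' @param config A [sim_config()].
#' @return List with elements `matrix` (an [exposure_matrix()], timepoint
#'   `"week12"`), `covariates` (data frame including missing values),
#'   `chemicals` (metadata data frame) and `truth` (ledger list).
#' @examples
#' cohort <- simulate_cohort(sim_config(n_participants = 50, seed = 7))
#' cohort$matrix
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_participants
  p <- config$n_chemicals
  chem <- config$chemicals$chemical

  cov_full <- draw_covariates(n)
  season <- season_of(cov_full$start_date)

  w <- vapply(config$profile_spec, `[[`, 0, "weight")
  profile <- sample.int(length(w), n, replace = TRUE, prob = w)
  prof_shift <- matrix(0, length(w), p, dimnames = list(NULL, chem))
  for (k in seq_along(config$profile_spec)) {
    s <- config$profile_spec[[k]]$shift
    if (length(s) > 0) prof_shift[k, names(s)] <- s
  }

  batch <- sprintf("B%d", sample.int(config$n_batches, n, replace = TRUE))
  batch_eff <- matrix(stats::rnorm(config$n_batches * p, 0,
                                   config$batch_shift_sd),
                      config$n_batches, p)

  shift_cov <- covariate_shift_matrix(config, cov_full, season)
  noise <- matrix(stats::rnorm(n * p), n, p) *
    rep(config$log_sigma, each = n)
  logc <- rep(config$log_mu, each = n) + prof_shift[profile, , drop = FALSE] +
    batch_eff[as.integer(sub("^B", "", batch)), , drop = FALSE] +
    shift_cov + noise
  conc <- 10^logc
  conc[conc < rep(config$loq, each = n)] <- 0
  colnames(conc) <- chem

  wear <- data.frame(
    start_date = cov_full$start_date,
    duration_days = round(pmax(5, stats::rnorm(n, 7.0, 0.15)), 1),
    gestational_age_start = cov_full$gestational_age_start,
    wristband_size = sample(c("regular", "small"), n, replace = TRUE,
                            prob = c(0.49, 0.51)),
    season = season,
    stringsAsFactors = FALSE)

  em <- exposure_matrix(conc, cov_full$participant,
                        rep("week12", n), batch, wear)

  cov <- cov_full[setdiff(names(cov_full), "start_date")]
  for (v in names(config$missing_rates)) {
    hole <- stats::runif(n) < config$missing_rates[[v]]
    cov[[v]][hole] <- NA
  }

  true_icc <- config$icc_targets[, 1] /
    pmax(rowSums(config$icc_targets), .Machine$double.eps)
  names(true_icc) <- chem
  beta_sd <- lapply(config$covariate_effects, function(e) {
    cols <- if (is.character(e$chemicals)) match(e$chemicals, chem) else e$chemicals
    cols <- cols[!is.na(cols)]
    # effect size in SD units of the *log10* concentration; on the raw
    # standardized scale the lognormal tail attenuates this
    list(covariate = e$covariate, level = e$level,
         chemicals = chem[cols],
         shift_log10 = e$shift,
         beta_log_sd_units = e$shift / config$log_sigma[cols])
  })
  truth <- list(profile = stats::setNames(profile, cov_full$participant),
                icc = true_icc, effects = beta_sd, seed = config$seed)
  list(matrix = em, covariates = cov, chemicals = config$chemicals,
       truth = truth)
}

#' Simulate the repeated-measures subsample
#'
#' Two wristbands per participant for the first `n_repeated` participants.
#' Per chemical, log10 concentrations follow the variance-components model
#' `y_it = mu + week_effect * 1(t = 2) + u_i + e_it` with
#' `Var(u) = sigma2_between` and `Var(e) = sigma2_within` taken from
#' `config$icc_targets`; values below the quantitation limit are censored
#' to 0. The true ICC per chemical,
#' `sigma2_between / (sigma2_between + sigma2_within)`, is recorded in the
#' truth ledger.
#'
#' @param config A [sim_config()] with `icc_targets`.
#' @return List with elements `matrix` (an [exposure_matrix()] with
#'   timepoints `"week12"` and `"week24"`) and `truth` (ledger list with
#'   the true ICC vector and seed).
#' @export
simulate_repeated <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_repeated < 2) {
    stop("need at least 2 repeated-measures participants", call. = FALSE)
  }
  set.seed(config$seed + 1L)
  n <- config$n_repeated
  p <- config$n_chemicals
  chem <- config$chemicals$chemical
  s2b <- config$icc_targets[, 1]
  s2w <- config$icc_targets[, 2]

  u <- matrix(stats::rnorm(n * p), n, p) * rep(sqrt(s2b), each = n)
  mk <- function(week) {
    e <- matrix(stats::rnorm(n * p), n, p) * rep(sqrt(s2w), each = n)
    logc <- rep(config$log_mu, each = n) + u + e +
      if (week == 2) config$week_effect else 0
    conc <- 10^logc
    conc[conc < rep(config$loq, each = n)] <- 0
    conc
  }
  conc <- rbind(mk(1), mk(2))
  colnames(conc) <- chem
  ids <- sprintf("P%03d", seq_len(n))
  batch <- sprintf("B%d", sample.int(config$n_batches, 2 * n, replace = TRUE))
  em <- exposure_matrix(conc, rep(ids, 2),
                        rep(c("week12", "week24"), each = n), batch)
  true_icc <- stats::setNames(s2b / pmax(s2b + s2w, .Machine$double.eps), chem)
  list(matrix = em, truth = list(icc = true_icc, seed = config$seed))
}

#' Write a simulated cohort to a directory
#'
#' Emits `exposure.csv`, `covariates.csv`, `chemicals.csv`, `truth.json`
#' and, when the configuration includes a repeated subsample,
#' `exposure_repeated.csv`.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list returned by [simulate_cohort()] with an
#'   added `repeated` element.
#' @export
write_cohort <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- simulate_cohort(config)
  write_exposure_csv(cohort$matrix, file.path(dir, "exposure.csv"),
                     chemicals = cohort$chemicals,
                     metadata_path = file.path(dir, "chemicals.csv"))
  write_covariates(cohort$covariates, file.path(dir, "covariates.csv"))
  rep_data <- NULL
  if (config$n_repeated >= 2) {
    rep_data <- simulate_repeated(config)
    write_exposure_csv(rep_data$matrix, file.path(dir, "exposure_repeated.csv"))
  }
  truth <- cohort$truth
  truth$profile <- as.list(truth$profile)
  truth$icc <- as.list(truth$icc)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cohort$repeated <- rep_data
  invisible(cohort)
}
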