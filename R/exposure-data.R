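# Domain containers and CSV I/O for wristband concentration data.

#' Chemical category vocabulary
#'
#' The fixed set of chemical-category labels used throughout the package
#' (the classification scheme of the commercial wristband screen). A chemical
#' may belong to several categories at once.
#'
#' @return Character vector of allowed category labels.
#' @export
chemical_categories <- function() {
  c("chemicals in commerce", "personal care products", "pesticides",
    "flame retardants", "PAHs", "consumer products", "pharmacological")
}

.covariate_levels <- list(
  education       = c("less than college graduate", "college graduate",
                      "any post-graduate"),
  marital         = c("married", "unmarried"),
  race_ethnicity  = c("White non-Hispanic", "other"),
  parity          = c("0", ">=1"),
  smoke_exposure  = c("none", "first- or second-hand"),
  nail_polish_use = c("no", "yes"),
  gardening       = c("no", "yes")
)

.covariate_numeric <- c("age_years", "bmi", "handwashing_per_day",
                        "gestational_age_start")

.wear_columns <- c("start_date", "duration_days", "gestational_age_start",
                   "wristband_size", "season")

#' Construct an exposure matrix
#'
#' Container for a wristband concentration table: one row per
#' (participant, timepoint) sample, one column per chemical, values in
#' ng/g silicone with 0 meaning non-detect. Every sample carries an
#' analytical batch label and, optionally, wear metadata (start date,
#' duration, gestational age at start, wristband size, season).
#'
#' @param concentrations Numeric matrix, samples x chemicals, non-negative;
#'   0 codes a non-detect. Column names are chemical identifiers.
#' @param participant Character vector of participant identifiers, one per row.
#' @param timepoint Character vector of timepoint labels (e.g. `"week12"`),
#'   one per row.
#' @param batch Character vector of analytical batch labels, one per row.
#' @param wear Optional data frame of per-sample wear metadata with any of
#'   the columns `start_date`, `duration_days`, `gestational_age_start`,
#'   `wristband_size`, `season`. A missing `season` is derived from
#'   `start_date` via [season_of()].
#' @return An object of class `exposure_matrix`.
#' @seealso [read_exposure_csv()], [detection_frequency()],
#'   [batch_standardize()]
#' @export
exposure_matrix <- function(concentrations, participant, timepoint, batch,
                            wear = NULL) {
  concentrations <- as.matrix(concentrations)
  storage.mode(concentrations) <- "double"
  n <- nrow(concentrations)
  participant <- as.character(participant)
  timepoint <- as.character(timepoint)
  batch <- as.character(batch)
  if (length(participant) != n || length(timepoint) != n ||
      length(batch) != n) {
    stop("participant, timepoint and batch must have one entry per sample row",
         call. = FALSE)
  }
  if (is.null(colnames(concentrations))) {
    colnames(concentrations) <- sprintf("chem%02d", seq_len(ncol(concentrations)))
  }
  bad <- which(!is.finite(concentrations) | concentrations < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "negative or non-finite concentration at sample '%s', chemical '%s'",
      paste(participant[bad[1, 1]], timepoint[bad[1, 1]], sep = "/"),
      colnames(concentrations)[bad[1, 2]]), call. = FALSE)
  }
  key <- paste(participant, timepoint, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop(sprintf("duplicate sample for participant '%s' at timepoint '%s'",
                 strsplit(d, "\r")[[1]][1], strsplit(d, "\r")[[1]][2]),
         call. = FALSE)
  }
  if (anyNA(batch) || any(batch == "")) {
    stop("every sample must carry a batch label", call. = FALSE)
  }
  if (!is.null(wear)) {
    wear <- as.data.frame(wear)
    if (nrow(wear) != n) stop("wear metadata must have one row per sample",
                              call. = FALSE)
    unknown <- setdiff(names(wear), .wear_columns)
    if (length(unknown) > 0) {
      stop("unknown wear column(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    if ("start_date" %in% names(wear)) {
      wear$start_date <- as.Date(wear$start_date)
      if (!"season" %in% names(wear)) {
        wear$season <- season_of(wear$start_date)
      }
    }
    if ("duration_days" %in% names(wear) &&
        any(wear$duration_days <= 0, na.rm = TRUE)) {
      stop("duration_days must be positive", call. = FALSE)
    }
  }
  rownames(concentrations) <- paste(participant, timepoint, sep = "_")
  structure(
    list(concentrations = concentrations, participant = participant,
         timepoint = timepoint, batch = batch, wear = wear),
    class = "exposure_matrix")
}

#' @export
dim.exposure_matrix <- function(x) dim(x$concentrations)

#' @export
print.exposure_matrix <- function(x, ...) {
  cat(sprintf("<exposure_matrix> %d samples x %d chemicals\n",
              nrow(x$concentrations), ncol(x$concentrations)))
  cat(sprintf("  participants: %d  timepoints: %s  batches: %s\n",
              length(unique(x$participant)),
              paste(sort(unique(x$timepoint)), collapse = ", "),
              paste(sort(unique(x$batch)), collapse = ", ")))
  det <- mean(x$concentrations > 0)
  cat(sprintf("  overall detection fraction: %.3f\n", det))
  invisible(x)
}

# restrict an exposure matrix to a subset of chemicals (order preserved)
em_keep_chemicals <- function(x, keep) {
  x$concentrations <- x$concentrations[, keep, drop = FALSE]
  x
}

# restrict to a subset of sample rows
em_keep_samples <- function(x, keep) {
  x$concentrations <- x$concentrations[keep, , drop = FALSE]
  x$participant <- x$participant[keep]
  x$timepoint <- x$timepoint[keep]
  x$batch <- x$batch[keep]
  if (!is.null(x$wear)) x$wear <- x$wear[keep, , drop = FALSE]
  x
}

#' Season of a calendar date
#'
#' Maps dates to meteorological seasons: December-February winter,
#' March-May spring, June-August summer, September-November fall.
#'
#' @param date A `Date` vector (or something coercible to one).
#' @return Character vector with values `"winter"`, `"spring"`, `"summer"`,
#'   `"fall"`.
#' @examples
#' season_of(as.Date(c("2018-01-15", "2018-06-01", "2018-12-01")))
#' @export
season_of <- function(date) {
  m <- as.integer(format(as.Date(date), "%m"))
  c("winter", "winter", "spring", "spring", "spring", "summer", "summer",
    "summer", "fall", "fall", "fall", "winter")[m]
}

validate_chemicals <- function(meta) {
  req <- c("chemical", "casn", "categories")
  miss <- setdiff(req, names(meta))
  if (length(miss) > 0) {
    stop("chemical metadata missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- !grepl("^[0-9]{2,7}-[0-9]{2}-[0-9]$", meta$casn)
  if (any(bad)) {
    stop(sprintf("invalid CAS number '%s' for chemical '%s'",
                 meta$casn[bad][1], meta$chemical[bad][1]), call. = FALSE)
  }
  cats <- strsplit(meta$categories, ";", fixed = TRUE)
  cats <- lapply(cats, trimws)
  if (any(lengths(cats) == 0L)) {
    stop("every chemical needs at least one category", call. = FALSE)
  }
  unknown <- setdiff(unique(unlist(cats)), chemical_categories())
  if (length(unknown) > 0) {
    stop("unknown chemical category label(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  meta$categories <- vapply(cats, paste, "", collapse = ";")
  meta
}

#' Read a wristband concentration CSV with chemical metadata
#'
#' The concentration CSV has one row per (participant, timepoint) sample
#' with columns `participant`, `timepoint`, `batch`, optional wear columns
#' (`start_date`, `duration_days`, `gestational_age_start`,
#' `wristband_size`, `season`) and one column per chemical. The metadata
#' CSV has columns `chemical`, `casn` and `categories`
#' (semicolon-separated labels from [chemical_categories()]).
#'
#' @param path Path to the concentration CSV.
#' @param metadata_path Path to the chemical metadata CSV.
#' @return A list with elements `matrix` (an [exposure_matrix()]) and
#'   `chemicals` (validated metadata data frame).
#' @export
read_exposure_csv <- function(path, metadata_path) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- utils::read.csv(metadata_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  meta <- validate_chemicals(meta)
  fixed <- c("participant", "timepoint", "batch")
  miss <- setdiff(fixed, names(raw))
  if (length(miss) > 0) {
    stop("exposure CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  wear_cols <- intersect(.wear_columns, names(raw))
  chem_cols <- setdiff(names(raw), c(fixed, wear_cols))
  unknown <- setdiff(chem_cols, meta$chemical)
  if (length(unknown) > 0) {
    stop("chemical(s) in exposure CSV absent from metadata: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  conc <- as.matrix(raw[chem_cols])
  wear <- if (length(wear_cols) > 0) raw[wear_cols] else NULL
  em <- exposure_matrix(conc, raw$participant, raw$timepoint, raw$batch, wear)
  list(matrix = em, chemicals = meta[match(chem_cols, meta$chemical), ,
                                     drop = FALSE])
}

#' Write an exposure matrix (and optional chemical metadata) to CSV
#'
#' Inverse of [read_exposure_csv()]; the written file round-trips.
#'
#' @param x An [exposure_matrix()].
#' @param path Output CSV path.
#' @param chemicals Optional chemical metadata data frame; when given it is
#'   written to `metadata_path`.
#' @param metadata_path Output path for the metadata CSV.
#' @return Invisibly, `path`.
#' @export
write_exposure_csv <- function(x, path, chemicals = NULL,
                               metadata_path = NULL) {
  out <- data.frame(participant = x$participant, timepoint = x$timepoint,
                    batch = x$batch, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (!is.null(x$wear)) out <- cbind(out, x$wear)
  out <- cbind(out, as.data.frame(x$concentrations, check.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE)
  if (!is.null(chemicals)) {
    if (is.null(metadata_path)) {
      stop("metadata_path required when writing chemical metadata",
           call. = FALSE)
    }
    utils::write.csv(chemicals, metadata_path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a participant covariate table
#'
#' Columns: `participant` plus any of `age_years`, `bmi`, `education`,
#' `marital`, `race_ethnicity`, `parity`, `smoke_exposure`,
#' `nail_polish_use`, `handwashing_per_day`, `gardening`,
#' `gestational_age_start`. Blank cells are missing values and are kept
#' missing (imputation happens later, explicitly). Categorical labels are
#' validated against the allowed level sets; anything else is rejected.
#'
#' @param path Path to the covariate CSV.
#' @return Data frame with one row per participant; categorical columns are
#'   factors with the full allowed level set, missing values are `NA`.
#' @export
read_covariates <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  if (!"participant" %in% names(raw)) {
    stop("covariate CSV must have a 'participant' column", call. = FALSE)
  }
  if (anyDuplicated(raw$participant)) {
    stop("duplicate participant in covariate table", call. = FALSE)
  }
  validate_covariates(raw)
}

#' Validate a covariate data frame
#'
#' @param cov Data frame as described in [read_covariates()].
#' @return The validated data frame with categorical columns as factors.
#' @export
validate_covariates <- function(cov) {
  cov <- as.data.frame(cov)
  for (v in intersect(names(.covariate_levels), names(cov))) {
    vals <- as.character(cov[[v]])
    bad <- !is.na(vals) & !(vals %in% .covariate_levels[[v]])
    if (any(bad)) {
      stop(sprintf("covariate '%s' has disallowed value '%s'", v,
                   vals[bad][1]), call. = FALSE)
    }
    cov[[v]] <- factor(vals, levels = .covariate_levels[[v]])
  }
  for (v in intersect(.covariate_numeric, names(cov))) {
    cov[[v]] <- as.numeric(cov[[v]])
  }
  cov
}

#' Write a covariate table to CSV
#'
#' @param cov Covariate data frame.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_covariates <- function(cov, path) {
  out <- cov
  for (v in names(out)) if (is.factor(out[[v]])) out[[v]] <- as.character(out[[v]])
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
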