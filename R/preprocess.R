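# Detection screening, per-wristband counts, batch-median standardization.

#' Per-chemical detection frequency and concentration summary
#'
#' Detection is concentration > 0 (non-detects are coded 0). Medians and
#' quartiles are computed over all samples including the zeros, with
#' type-7 (linear interpolation) quantiles.
#'
#' @param x An [exposure_matrix()].
#' @return Data frame with columns `chemical`, `n`, `detected`,
#'   `detection` (fraction in `[0, 1]`), `median`, `q1`, `q3`.
#' @export
detection_frequency <- function(x) {
  stopifnot(inherits(x, "exposure_matrix"))
  conc <- x$concentrations
  if (nrow(conc) == 0) stop("empty exposure matrix", call. = FALSE)
  q <- apply(conc, 2, stats::quantile, probs = c(0.25, 0.5, 0.75),
             names = FALSE)
  data.frame(chemical = colnames(conc), n = nrow(conc),
             detected = colSums(conc > 0),
             detection = colMeans(conc > 0),
             median = q[2, ], q1 = q[1, ], q3 = q[3, ],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Restrict to frequently detected chemicals
#'
#' Keeps the chemicals whose detection fraction strictly exceeds
#' `threshold` (default 0.60, the conventional screen for downstream
#' correlation, regression and profile analyses). Chemical order is
#' preserved; the operation is idempotent.
#'
#' @param x An [exposure_matrix()].
#' @param threshold Detection fraction cutoff in (0, 1]; strictly greater
#'   than this value is retained. `threshold = 0` keeps every chemical
#'   with at least one detect.
#' @return An [exposure_matrix()] restricted to the retained chemicals.
#' @export
filter_by_detection <- function(x, threshold = 0.60) {
  stopifnot(inherits(x, "exposure_matrix"))
  det <- colMeans(x$concentrations > 0)
  keep <- which(det > threshold)
  if (length(keep) == 0) {
    warning("no chemical exceeds the detection threshold; result is empty")
  }
  em_keep_chemicals(x, keep)
}

#' Chemicals detected per wristband, overall and by category
#'
#' Counts, for each sample, the number of chemicals detected (value > 0)
#' in total and within each chemical category. A chemical belonging to
#' k categories contributes 1 to each of those k category counts but
#' only 1 to the total.
#'
#' @param x An [exposure_matrix()].
#' @param chemicals Chemical metadata data frame (columns `chemical`,
#'   `casn`, `categories`) covering every chemical in `x`.
#' @return Data frame with `participant`, `timepoint`, `total`, and one
#'   count column per category in [chemical_categories()] (spaces replaced
#'   by `_` in column names).
#' @export
counts_per_wristband <- function(x, chemicals) {
  stopifnot(inherits(x, "exposure_matrix"))
  chem <- colnames(x$concentrations)
  miss <- setdiff(chem, chemicals$chemical)
  if (length(miss) > 0) {
    stop("chemical(s) without metadata: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cats <- strsplit(chemicals$categories[match(chem, chemicals$chemical)],
                   ";", fixed = TRUE)
  det <- x$concentrations > 0
  out <- data.frame(participant = x$participant, timepoint = x$timepoint,
                    total = as.integer(rowSums(det)),
                    stringsAsFactors = FALSE)
  for (cc in chemical_categories()) {
    member <- vapply(cats, function(v) cc %in% v, TRUE)
    out[[gsub(" ", "_", cc)]] <- as.integer(rowSums(det[, member,
                                                        drop = FALSE]))
  }
  out
}

#' Batch-median standardization
#'
#' Removes analytical batch effects and rescales: for each chemical, the
#' batch-specific median is subtracted from every value in that batch, and
#' the adjusted values are then centered to mean 0 and scaled to SD 1
#' (sample SD, pooled over all samples in the fit). Non-detect zeros
#' participate in medians and scaling. The transform parameters (per-batch
#' medians, center, scale) are stored so the identical transform can be
#' applied to later samples with [apply_standardization()].
#'
#' @param x An [exposure_matrix()].
#' @return An object of class `std_matrix`: list with `values` (samples x
#'   chemicals matrix of standardized concentrations), `participant`,
#'   `timepoint`, `batch`, and `transform` (list `batch_medians` —
#'   chemicals x batches matrix —, `center`, `scale`).
#' @examples
#' cohort <- simulate_cohort(sim_config(n_participants = 40, seed = 3))
#' std <- batch_standardize(filter_by_detection(cohort$matrix))
#' round(colMeans(std$values), 12)
#' @export
batch_standardize <- function(x) {
  stopifnot(inherits(x, "exposure_matrix"))
  conc <- x$concentrations
  batches <- sort(unique(x$batch))
  med <- vapply(batches, function(b) {
    apply(conc[x$batch == b, , drop = FALSE], 2, stats::median)
  }, numeric(ncol(conc)))
  med <- matrix(med, nrow = ncol(conc),
                dimnames = list(colnames(conc), batches))
  adj <- conc - t(med[, x$batch, drop = FALSE])
  ctr <- colMeans(adj)
  sc <- apply(adj, 2, stats::sd)
  zero <- which(!is.finite(sc) | sc < .Machine$double.eps^0.5)
  if (length(zero) > 0) {
    stop("constant chemical(s), cannot standardize: ",
         paste(colnames(conc)[zero], collapse = ", "), call. = FALSE)
  }
  values <- sweep(sweep(adj, 2, ctr), 2, sc, "/")
  structure(
    list(values = values, participant = x$participant,
         timepoint = x$timepoint, batch = x$batch,
         transform = list(batch_medians = med, center = ctr, scale = sc)),
    class = "std_matrix")
}

#' Apply a stored standardization transform to new samples
#'
#' Uses the batch medians, center and scale learned by
#' [batch_standardize()] on the fitting samples (e.g. the first-timepoint
#' wristbands) to transform later samples onto the same scale. Batches
#' unseen in the fit fall back to the chemical's cross-batch median
#' (with a warning).
#'
#' @param std A `std_matrix` from [batch_standardize()].
#' @param x An [exposure_matrix()] with the same chemicals.
#' @return A `std_matrix` for the new samples (carrying the original
#'   transform).
#' @export
apply_standardization <- function(std, x) {
  stopifnot(inherits(std, "std_matrix"), inherits(x, "exposure_matrix"))
  tr <- std$transform
  chem <- rownames(tr$batch_medians)
  if (!identical(colnames(x$concentrations), chem)) {
    stop("chemical axes do not match the fitted transform", call. = FALSE)
  }
  med <- tr$batch_medians
  new_b <- setdiff(unique(x$batch), colnames(med))
  if (length(new_b) > 0) {
    warning("batch(es) unseen in fit, using cross-batch median: ",
            paste(new_b, collapse = ", "))
    fallback <- apply(med, 1, stats::median)
    med <- cbind(med, matrix(fallback, nrow(med), length(new_b),
                             dimnames = list(chem, new_b)))
  }
  adj <- x$concentrations - t(med[, x$batch, drop = FALSE])
  values <- sweep(sweep(adj, 2, tr$center), 2, tr$scale, "/")
  structure(
    list(values = values, participant = x$participant,
         timepoint = x$timepoint, batch = x$batch, transform = tr),
    class = "std_matrix")
}

#' @export
print.std_matrix <- function(x, ...) {
  cat(sprintf("<std_matrix> %d samples x %d chemicals (batch-median standardized)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.std_matrix <- function(x) dim(x$values)
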