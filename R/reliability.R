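# Spearman correlation structure and repeated-measures reliability (ICC).

#' Spearman correlation matrix among chemicals
#'
#' Rank correlation (average ranks for ties; non-detect zeros form tie
#' blocks) between every pair of chemicals, plus a summary of the
#' off-diagonal coefficients. A chemical whose values are all tied has no
#' defined rank correlation; its row/column is `NA` and a warning names it.
#'
#' @param std A `std_matrix` from [batch_standardize()] (any rank-preserving
#'   transform gives identical results).
#' @return List with `rho` (symmetric correlation matrix, unit diagonal)
#'   and `summary` (median, q1, q3, min, max of the off-diagonal entries,
#'   `NA`s removed).
#' @export
spearman_matrix <- function(std) {
  stopifnot(inherits(std, "std_matrix"))
  v <- std$values
  if (ncol(v) < 2 || nrow(v) < 3) {
    stop("need at least 2 chemicals and 3 samples", call. = FALSE)
  }
  const <- apply(v, 2, function(col) length(unique(col)) == 1L)
  rho <- suppressWarnings(stats::cor(v, method = "spearman"))
  if (any(const)) {
    warning("all-tied chemical(s), correlation undefined: ",
            paste(colnames(v)[const], collapse = ", "))
    rho[const, ] <- NA_real_
    rho[, const] <- NA_real_
  }
  diag(rho) <- 1
  off <- rho[upper.tri(rho)]
  off <- off[!is.na(off)]
  q <- stats::quantile(off, c(0.25, 0.5, 0.75), names = FALSE)
  list(rho = rho,
       summary = list(median = q[2], q1 = q[1], q3 = q[3],
                      min = min(off), max = max(off)))
}

# sample variance of each row of a matrix
.row_var <- function(x) {
  n <- ncol(x)
  (rowSums(x^2) - n * rowMeans(x)^2) / (n - 1)
}

#' Intraclass correlation for one chemical across two timepoints
#'
#' Fits the random-intercept model `y_it = mu + beta * week_t + u_i + e_it`
#' (week fixed, participant random) to paired measurements. For this
#' balanced two-occasion design the variance components have the closed
#' form `sigma2_within = Var(d_i) / 2` with `d_i` the within-participant
#' difference and `sigma2_between = Var(m_i) - sigma2_within / 2` with
#' `m_i` the participant mean (truncated at 0), which coincides with the
#' REML solution whenever the estimate is interior. The ICC is
#' `sigma2_between / (sigma2_between + sigma2_within)`. The 95% confidence
#' interval is the 2.5/97.5 percentile of the ICC over `n_boot` resamples
#' of participants (both timepoints kept together, preserving the
#' within-person dependence); degenerate resamples (no variance)
#' contribute ICC 0, and the interval is clamped to `[0, 1]`.
#'
#' @param y1,y2 Numeric vectors: the chemical's (standardized) values at
#'   the first and second timepoint, aligned by participant.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Optional integer seed for the bootstrap.
#' @param chemical Optional chemical label carried into the result.
#' @return Object of class `icc_fit`: `chemical`, `sigma2_between`,
#'   `sigma2_within`, `icc`, `ci_low`, `ci_high`, `n`, `n_boot`,
#'   `reliability` (see [classify_reliability()]), `degenerate`.
#' @export
estimate_icc <- function(y1, y2, n_boot = 1000, seed = NULL,
                         chemical = NA_character_) {
  if (length(y1) != length(y2)) {
    stop("timepoints must be aligned by participant", call. = FALSE)
  }
  ok <- is.finite(y1) & is.finite(y2)
  y1 <- y1[ok]; y2 <- y2[ok]
  n <- length(y1)
  if (n < 3) stop("need at least 3 participants with both timepoints",
                  call. = FALSE)
  comp <- function(a, b) {
    s2w <- stats::var(b - a) / 2
    s2b <- max(stats::var((a + b) / 2) - s2w / 2, 0)
    tot <- s2b + s2w
    icc <- if (tot > 0) s2b / tot else 0
    c(s2b, s2w, icc)
  }
  est <- comp(y1, y2)
  degenerate <- (est[1] + est[2]) == 0
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    idx <- matrix(sample.int(n, n_boot * n, replace = TRUE), n_boot, n)
    D <- matrix((y2 - y1)[idx], n_boot, n)
    M <- matrix(((y1 + y2) / 2)[idx], n_boot, n)
    s2w_b <- .row_var(D) / 2
    s2b_b <- pmax(.row_var(M) - s2w_b / 2, 0)
    tot <- s2b_b + s2w_b
    icc_b <- ifelse(tot > 0, s2b_b / tot, 0)
    ci <- pmin(pmax(stats::quantile(icc_b, c(0.025, 0.975), names = FALSE),
                    0), 1)
  }
  structure(
    list(chemical = chemical, sigma2_between = est[1],
         sigma2_within = est[2], icc = est[3], ci_low = ci[1],
         ci_high = ci[2], n = n, n_boot = n_boot,
         reliability = classify_reliability(est[3]),
         degenerate = degenerate),
    class = "icc_fit")
}

#' @export
print.icc_fit <- function(x, ...) {
  cat(sprintf("ICC%s: %.2f (95%% CI %.2f, %.2f) [%s], n = %d pairs\n",
              if (is.na(x$chemical)) "" else paste0(" ", x$chemical),
              x$icc, x$ci_low, x$ci_high, x$reliability, x$n))
  if (x$degenerate) cat("  note: degenerate (no variance in either component)\n")
  invisible(x)
}

#' ICCs for every chemical in a two-timepoint standardized matrix
#'
#' Pairs samples by participant across the two timepoints (participants
#' missing either timepoint are dropped) and runs [estimate_icc()] per
#' chemical.
#'
#' @param std A `std_matrix` containing exactly two timepoints.
#' @param n_boot,seed Passed to [estimate_icc()]; per-chemical seeds are
#'   derived from `seed` so chemicals are independent but reproducible.
#' @return Data frame: `chemical`, `sigma2_between`, `sigma2_within`,
#'   `icc`, `ci_low`, `ci_high`, `n`, `reliability`.
#' @export
icc_by_chemical <- function(std, n_boot = 1000, seed = NULL) {
  stopifnot(inherits(std, "std_matrix"))
  tps <- sort(unique(std$timepoint))
  if (length(tps) != 2) stop("need exactly two timepoints", call. = FALSE)
  i1 <- which(std$timepoint == tps[1])
  i2 <- which(std$timepoint == tps[2])
  common <- intersect(std$participant[i1], std$participant[i2])
  i1 <- i1[match(common, std$participant[i1])]
  i2 <- i2[match(common, std$participant[i2])]
  res <- lapply(seq_len(ncol(std$values)), function(j) {
    fit <- estimate_icc(std$values[i1, j], std$values[i2, j],
                        n_boot = n_boot,
                        seed = if (is.null(seed)) NULL else seed + j,
                        chemical = colnames(std$values)[j])
    data.frame(chemical = fit$chemical,
               sigma2_between = fit$sigma2_between,
               sigma2_within = fit$sigma2_within, icc = fit$icc,
               ci_low = fit$ci_low, ci_high = fit$ci_high, n = fit$n,
               reliability = fit$reliability, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Reliability class of an ICC
#'
#' Conventional cutpoints: ICC <= 0.4 poor, 0.4 < ICC < 0.75 fair to good,
#' ICC >= 0.75 excellent.
#'
#' @param icc Numeric vector of ICCs in `[0, 1]`.
#' @return Character vector of classes.
#' @export
classify_reliability <- function(icc) {
  ifelse(icc >= 0.75, "excellent",
         ifelse(icc > 0.4, "fair to good", "poor"))
}

#' Cohort-level reliability summary
#'
#' @param icc Numeric vector of per-chemical ICC point estimates (or the
#'   data frame from [icc_by_chemical()]).
#' @return List with `table` (chemical-level classes, when input carries
#'   names/chemicals), `median`, `min`, `max`, and `percent` — integer
#'   percentages per reliability class (rounded to the nearest integer).
#' @export
summarize_reliability <- function(icc) {
  if (is.data.frame(icc)) {
    vals <- icc$icc
    chem <- icc$chemical
  } else {
    vals <- as.numeric(icc)
    chem <- names(icc)
  }
  if (length(vals) == 0) stop("no ICCs to summarize", call. = FALSE)
  cls <- classify_reliability(vals)
  pct <- vapply(c("poor", "fair to good", "excellent"),
                function(k) round(100 * mean(cls == k)), 0)
  list(table = data.frame(chemical = if (is.null(chem)) NA else chem,
                          icc = vals, reliability = cls,
                          stringsAsFactors = FALSE),
       median = stats::median(vals), min = min(vals), max = max(vals),
       percent = pct)
}
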