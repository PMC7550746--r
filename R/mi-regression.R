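# Chained-equation multiple imputation, OLS fits, Rubin-rules pooling.

#' Imputation specification
#'
#' Settings for [chained_impute()]: number of completed datasets, chained
#' sweeps, predictive-mean-matching donor pool, and seed. Defaults are the
#' conventional choices (m = 25 completed datasets, 10 sweeps, 5 donors).
#'
#' @param m Number of imputed datasets (>= 2).
#' @param n_iter Chained-equation sweeps per dataset (>= 1).
#' @param pmm_k Donor pool size for predictive mean matching of continuous
#'   variables.
#' @param seed Optional integer seed.
#' @return Object of class `impute_spec`.
#' @export
impute_spec <- function(m = 25, n_iter = 10, pmm_k = 5, seed = NULL) {
  stopifnot(m >= 2, n_iter >= 1, pmm_k >= 1)
  structure(list(m = as.integer(m), n_iter = as.integer(n_iter),
                 pmm_k = as.integer(pmm_k), seed = seed),
            class = "impute_spec")
}

# one conditional-model draw for the missing cells of variable `v`
.impute_one <- function(data, v, obs, pmm_k) {
  mis <- !obs
  others <- setdiff(names(data), v)
  X <- stats::model.matrix(
    stats::reformulate(sprintf("`%s`", others)), data = data)
  # drop aliased columns so the draw is well-defined
  qrX <- qr(X[obs, , drop = FALSE])
  keep <- qrX$pivot[seq_len(qrX$rank)]
  X <- X[, keep, drop = FALSE]
  y <- data[[v]]
  if (is.numeric(y)) {
    fit <- stats::lm.fit(X[obs, , drop = FALSE], y[obs])
    res <- fit$residuals
    df <- length(res) - fit$rank
    sigma2 <- sum(res^2) / max(df, 1)
    sigma2_star <- sigma2 * max(df, 1) / stats::rchisq(1, max(df, 1))
    R <- qr.R(fit$qr)[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE]
    beta_star <- fit$coefficients +
      backsolve(R, stats::rnorm(fit$rank)) * sqrt(sigma2_star)
    yhat_obs <- drop(X[obs, , drop = FALSE] %*% fit$coefficients)
    yhat_mis <- drop(X[mis, , drop = FALSE] %*% beta_star)
    donors <- vapply(yhat_mis, function(h) {
      near <- order(abs(yhat_obs - h))[seq_len(min(pmm_k, length(yhat_obs)))]
      y[obs][sample(near, 1)]
    }, numeric(1))
    y[mis] <- donors
  } else if (nlevels(y) == 2L) {
    yo <- as.integer(y[obs]) - 1L
    fit <- suppressWarnings(
      stats::glm.fit(X[obs, , drop = FALSE], yo,
                     family = stats::binomial()))
    Vc <- chol2inv(chol(crossprod(X[obs, , drop = FALSE] *
                                    sqrt(fit$weights + 1e-10))))
    beta_star <- fit$coefficients + drop(chol(Vc) %*% stats::rnorm(ncol(X)))
    p <- stats::plogis(drop(X[mis, , drop = FALSE] %*% beta_star))
    y[mis] <- levels(y)[1L + stats::rbinom(sum(mis), 1, p)]
  } else {
    # polytomous: parameter uncertainty via a bootstrap refit
    oi <- which(obs)
    boot <- sample(oi, length(oi), replace = TRUE)
    dfit <- data.frame(.y = y[boot], X[boot, -1, drop = FALSE],
                       check.names = TRUE)
    fit <- nnet::multinom(.y ~ ., data = dfit, trace = FALSE)
    dmis <- data.frame(X[mis, -1, drop = FALSE], check.names = TRUE)
    pr <- stats::predict(fit, newdata = dmis, type = "probs")
    pr <- matrix(pr, nrow = sum(mis),
                 dimnames = list(NULL, fit$lev))
    draw <- apply(pr, 1, function(p) sample(fit$lev, 1, prob = p))
    y[mis] <- draw
  }
  y
}

#' Multiple imputation by chained equations
#'
#' Fills missing covariate cells with draws from per-variable conditional
#' models iterated over `n_iter` sweeps: predictive mean matching for
#' continuous variables, a Bayesian logistic draw for binary factors, and
#' polytomous regression (bootstrap-refitted for parameter uncertainty)
#' for factors with more than two levels. Observed cells are never
#' altered. Columns named `participant` are carried through untouched and
#' excluded from the models.
#'
#' @param cov Data frame (e.g. from [read_covariates()]); missing values
#'   are `NA`.
#' @param spec An [impute_spec()].
#' @return List of `spec$m` completed data frames.
#' @export
chained_impute <- function(cov, spec = impute_spec()) {
  stopifnot(inherits(spec, "impute_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  id <- cov[["participant"]]
  work <- cov[setdiff(names(cov), "participant")]
  for (v in names(work)) {
    if (is.character(work[[v]])) work[[v]] <- factor(work[[v]])
  }
  frac <- vapply(work, function(x) mean(is.na(x)), 0)
  if (any(frac > 0.95)) {
    stop("variable(s) with more than 95% missingness: ",
         paste(names(work)[frac > 0.95], collapse = ", "), call. = FALSE)
  }
  targets <- names(work)[frac > 0]
  obs_mask <- lapply(work, function(x) !is.na(x))
  complete_once <- function() {
    cur <- work
    for (v in targets) {  # start from random draws of the observed values
      mis <- !obs_mask[[v]]
      cur[[v]][mis] <- sample(cur[[v]][!mis], sum(mis), replace = TRUE)
    }
    for (it in seq_len(spec$n_iter)) {
      for (v in targets) {
        cur[[v]] <- .impute_one(cur, v, obs_mask[[v]], spec$pmm_k)
      }
    }
    cur
  }
  out <- vector("list", spec$m)
  for (i in seq_len(spec$m)) {
    cur <- if (length(targets) == 0) work else complete_once()
    if (!is.null(id)) cur <- cbind(participant = id, cur,
                                   stringsAsFactors = FALSE)
    out[[i]] <- cur
  }
  out
}

#' Ordinary least squares fit with aliasing check
#'
#' Thin wrapper around [stats::lm()] that refuses silently rank-deficient
#' designs (aliased terms are an analysis error here, not something to
#' drop quietly).
#'
#' @param formula Model formula.
#' @param data Data frame.
#' @return The fitted `lm` object.
#' @export
fit_linear <- function(formula, data) {
  fit <- stats::lm(formula, data = data)
  if (anyNA(stats::coef(fit))) {
    stop("rank-deficient design; aliased term(s): ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "), call. = FALSE)
  }
  fit
}

#' Pool fits across imputations by Rubin's rules
#'
#' Combines m per-imputation fits: pooled coefficient = mean of the m
#' coefficients; within-imputation variance W = mean of the m squared
#' standard errors; between-imputation variance B = sample variance of
#' the coefficients; total variance T = W + (1 + 1/m) B. Degrees of
#' freedom use the Barnard-Rubin small-sample adjustment, and 95%
#' confidence intervals are t-based on those df.
#'
#' @param fits List of `lm` objects (or lists with elements `coef`,
#'   `vcov`, `df`) sharing one term set.
#' @return Object of class `pooled_fit` with a `pooled` data frame:
#'   `term`, `estimate`, `W`, `B`, `T`, `df`, `se`, `ci_low`, `ci_high`.
#' @examples
#' d <- data.frame(x = rnorm(50)); d$y <- 1 + 2 * d$x + rnorm(50)
#' pool_rubin(list(fit_linear(y ~ x, d), fit_linear(y ~ x, d)))
#' @export
pool_rubin <- function(fits) {
  m <- length(fits)
  if (m < 1) stop("no fits to pool", call. = FALSE)
  get <- function(f) {
    if (inherits(f, "lm")) {
      list(coef = stats::coef(f), var = diag(stats::vcov(f)),
           df = stats::df.residual(f))
    } else {
      list(coef = f$coef, var = diag(as.matrix(f$vcov)),
           df = if (is.null(f$df)) Inf else f$df)
    }
  }
  parts <- lapply(fits, get)
  terms <- names(parts[[1]]$coef)
  for (p in parts) {
    if (!identical(names(p$coef), terms)) {
      stop("fits have mismatched term sets", call. = FALSE)
    }
  }
  Q <- do.call(rbind, lapply(parts, `[[`, "coef"))
  U <- do.call(rbind, lapply(parts, `[[`, "var"))
  qbar <- colMeans(Q)
  W <- colMeans(U)
  B <- if (m > 1) apply(Q, 2, stats::var) else rep(0, length(terms))
  Tv <- W + (1 + 1 / m) * B
  dfcom <- parts[[1]]$df
  lambda <- ifelse(Tv > 0, (1 + 1 / m) * B / Tv, 0)
  df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
  df_old <- ifelse(lambda > 1e-12, (m - 1) / lambda^2, Inf)
  df <- ifelse(is.finite(df_old), df_old * df_obs / (df_old + df_obs),
               df_obs)
  se <- sqrt(Tv)
  tq <- stats::qt(0.975, df)
  pooled <- data.frame(term = terms, estimate = qbar, W = W, B = B, T = Tv,
                       df = df, se = se, ci_low = qbar - tq * se,
                       ci_high = qbar + tq * se, row.names = NULL,
                       stringsAsFactors = FALSE)
  structure(list(pooled = pooled, m = m, dfcom = dfcom),
            class = "pooled_fit")
}

#' @export
print.pooled_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Pooled fit over %d imputation(s)\n", x$m))
  p <- x$pooled
  out <- data.frame(term = p$term,
                    beta = round(p$estimate, digits),
                    `95% CI` = sprintf("(%s, %s)",
                                       format(round(p$ci_low, digits)),
                                       format(round(p$ci_high, digits))),
                    check.names = FALSE)
  print(out, row.names = FALSE)
  invisible(x)
}

#' @export
coef.pooled_fit <- function(object, ...) {
  stats::setNames(object$pooled$estimate, object$pooled$term)
}

#' @export
confint.pooled_fit <- function(object, parm, level = 0.95, ...) {
  p <- object$pooled
  tq <- stats::qt(1 - (1 - level) / 2, p$df)
  ci <- cbind(p$estimate - tq * p$se, p$estimate + tq * p$se)
  dimnames(ci) <- list(p$term,
                       sprintf("%.1f %%", c((1 - level) / 2,
                                            1 - (1 - level) / 2) * 100))
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
summary.pooled_fit <- function(object, ...) {
  p <- object$pooled
  p$statistic <- p$estimate / p$se
  p$p.value <- 2 * stats::pt(-abs(p$statistic), p$df)
  p
}

#' Fit one outcome across imputed datasets and pool
#'
#' @param formula Model formula; the outcome must be complete (it is taken
#'   from each completed dataset, where it is identical).
#' @param data_list List of completed data frames from [chained_impute()].
#' @return A [pool_rubin()] `pooled_fit`.
#' @export
mi_lm <- function(formula, data_list) {
  pool_rubin(lapply(data_list, function(d) fit_linear(formula, d)))
}

.adjustment_terms <- c("age_years", "bmi", "education", "marital",
                       "race_ethnicity", "parity", "smoke_exposure",
                       "gestational_age_start", "season")

# the six a-priori exposure hypotheses: exposure term, chemical-concentration
# targets, and category/total count targets
.apriori_hypotheses <- function() {
  list(
    list(name = "nail_polish", exposure = "nail_polish_use",
         counts = "personal_care_products",
         chemicals = c("Triphenyl phosphate", "Di-n-butyl phthalate",
                       "Diisobutyl phthalate", "Butyl benzyl phthalate",
                       "Di-n-nonyl phthalate", "Diethyl phthalate")),
    list(name = "handwashing", exposure = "handwashing_per_day",
         counts = "total", chemicals = character(0)),
    list(name = "gardening", exposure = "gardening",
         counts = "pesticides",
         chemicals = c("N,N-Diethyl-m-toluamide", "Benzyl benzoate",
                       "Permethrin", "Di-n-butyl phthalate",
                       "Diethyl phthalate")),
    list(name = "parity", exposure = NULL,
         counts = character(0), chemicals = "Triphenyl phosphate"),
    list(name = "season", exposure = NULL,
         counts = "pesticides", chemicals = "Benzophenone")
  )
}

#' Run the full multiply-imputed regression suite
#'
#' Fits, on `spec$m` chained-equation completions of the covariates, the
#' standard model set for a wristband deployment: (i) total chemicals
#' detected as a function of the core covariate set (age, BMI, education,
#' marital status, race/ethnicity, parity, smoke exposure, gestational age
#' at start, season of wear — with "fall", "married", "White non-Hispanic",
#' parity 0, no smoke exposure and lowest education as reference levels);
#' (ii) the a-priori exposure hypotheses — nail polish use against the
#' personal-care detection count and the concentrations of triphenyl
#' phosphate and five phthalates; handwashing frequency against the total
#' count; gardening against the pesticide count and five named chemicals;
#' parity against triphenyl phosphate; season against benzophenone and the
#' pesticide count; and (iii) a season model for every frequently detected
#' chemical. Concentration outcomes are the standardized values, so their
#' betas are in SD units. Every model adjusts for the same core covariate
#' set; hypothesis models whose target chemical was filtered out are
#' skipped with a warning.
#'
#' @param std A `std_matrix` of the frequently detected chemicals
#'   (first-timepoint samples).
#' @param counts Per-wristband counts from [counts_per_wristband()].
#' @param cov Covariate data frame (with missing values); must include the
#'   exposure variables `nail_polish_use`, `handwashing_per_day`,
#'   `gardening`.
#' @param spec An [impute_spec()].
#' @param wear Optional data frame with `participant`, `season`,
#'   `gestational_age_start` used when `cov` lacks those columns (they
#'   normally live in the wristband wear metadata).
#' @return Named list of [pool_rubin()] `pooled_fit` objects, with
#'   attribute `skipped` naming hypothesis models that could not be fit.
#' @export
run_model_suite <- function(std, counts, cov, spec = impute_spec(),
                            wear = NULL) {
  stopifnot(inherits(std, "std_matrix"))
  if (!is.null(wear)) {
    add <- setdiff(intersect(c("season", "gestational_age_start"),
                             names(wear)), names(cov))
    if (length(add) > 0) {
      cov <- merge(cov, wear[c("participant", add)], by = "participant",
                   sort = FALSE)
    }
  }
  miss <- setdiff(c(.adjustment_terms, "nail_polish_use",
                    "handwashing_per_day", "gardening"), names(cov))
  if (length(miss) > 0) {
    stop("covariate table is missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cov$season <- factor(cov$season,
                       levels = c("fall", "winter", "spring", "summer"))

  # one shared imputation of the covariates; the (complete) total count
  # joins as an auxiliary predictor for congeniality with the count models
  aux <- counts[counts$timepoint == sort(unique(counts$timepoint))[1],
                c("participant", "total")]
  frame <- merge(cov, aux, by = "participant", sort = FALSE)
  completed <- chained_impute(frame, spec)

  ord <- match(completed[[1]]$participant, std$participant)
  if (anyNA(ord)) stop("covariates and samples do not align", call. = FALSE)
  cnt1 <- counts[counts$timepoint == sort(unique(counts$timepoint))[1], ,
                 drop = FALSE]
  cnt <- cnt1[match(completed[[1]]$participant, cnt1$participant), ,
              drop = FALSE]
  adj <- paste(.adjustment_terms, collapse = " + ")
  with_outcome <- function(y, extra_term = NULL) {
    rhs <- if (is.null(extra_term)) adj else paste(adj, extra_term,
                                                   sep = " + ")
    lapply(completed, function(d) {
      d$.y <- y
      fit_linear(stats::as.formula(paste(".y ~", rhs)), d)
    })
  }
  fits <- list()
  skipped <- character(0)
  fits[["total_detects"]] <- pool_rubin(with_outcome(cnt$total))

  chem_avail <- colnames(std$values)
  for (h in .apriori_hypotheses()) {
    for (ct in h$counts) {
      col <- if (ct == "total") "total" else ct
      nm <- paste(h$name, col, "count", sep = "_")
      if (ct == "total" && is.null(h$exposure)) next
      fits[[nm]] <- pool_rubin(with_outcome(cnt[[col]], h$exposure))
    }
    for (ch in h$chemicals) {
      nm <- paste(h$name, ch, sep = ": ")
      if (!ch %in% chem_avail) {
        warning(sprintf(
          "hypothesis '%s': chemical '%s' not among retained chemicals; skipped",
          h$name, ch))
        skipped <- c(skipped, nm)
        next
      }
      fits[[nm]] <- pool_rubin(
        with_outcome(std$values[ord, ch], h$exposure))
    }
  }
  for (ch in chem_avail) {
    fits[[paste0("season: ", ch)]] <- pool_rubin(
      with_outcome(std$values[ord, ch]))
  }
  attr(fits, "skipped") <- skipped
  fits
}
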