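test_that("complete data pass through imputation untouched", {
  cov <- data.frame(participant = c("P1", "P2", "P3", "P4"),
                    age_years = c(30, 31, 28, 35),
                    marital = factor(c("married", "unmarried",
                                       "married", "married")))
  out <- chained_impute(cov, impute_spec(m = 3, n_iter = 2, seed = 1))
  expect_length(out, 3)
  for (d in out) expect_equal(d, out[[1]])
  expect_equal(out[[1]]$age_years, cov$age_years)
})

test_that("imputed cells stay in range and observed cells never change", {
  set.seed(5)
  n <- 80
  cov <- data.frame(
    participant = sprintf("P%02d", 1:n),
    age_years = rnorm(n, 30, 4),
    bmi = rnorm(n, 25, 3),
    marital = factor(sample(c("married", "unmarried"), n, TRUE)),
    education = factor(sample(c("less than college graduate",
                                "college graduate", "any post-graduate"),
                              n, TRUE)))
  holes <- list(bmi = sample(n, 15), marital = sample(n, 12),
                education = sample(n, 18))
  cov$bmi[holes$bmi] <- NA
  cov$marital[holes$marital] <- NA
  cov$education[holes$education] <- NA
  out <- chained_impute(cov, impute_spec(m = 4, n_iter = 3, seed = 9))
  for (d in out) {
    expect_false(anyNA(d))
    # observed cells identical
    obs <- setdiff(seq_len(n), holes$bmi)
    expect_equal(d$bmi[obs], cov$bmi[obs])
    # binary and polytomous draws stay within the observed level sets
    expect_true(all(d$marital %in% levels(cov$marital)))
    expect_true(all(d$education %in% levels(cov$education)))
    # PMM draws are donations of observed values
    expect_true(all(d$bmi[holes$bmi] %in% cov$bmi[obs]))
  }
  # different imputations actually differ
  expect_false(identical(out[[1]]$bmi, out[[2]]$bmi))
})

test_that("variables with near-total missingness are refused", {
  cov <- data.frame(participant = sprintf("P%d", 1:25),
                    age_years = rnorm(25),
                    bmi = c(24, rep(NA, 24)))
  expect_error(chained_impute(cov, impute_spec(m = 2, n_iter = 1)),
               "95%.*bmi")
})

test_that("MCAR imputation recovers the generating mean", {
  set.seed(77)
  n <- 300
  x <- rnorm(n, 2, 1)
  y <- 5 + 1.5 * x + rnorm(n)  # y informative for x, used as predictor
  xm <- x
  drop <- sample(n, 60)
  xm[drop] <- NA
  cov <- data.frame(participant = sprintf("P%03d", 1:n),
                    x = xm, y = y)
  out <- chained_impute(cov, impute_spec(m = 10, n_iter = 5, seed = 3))
  pooled_mean <- mean(vapply(out, function(d) mean(d$x), 0))
  se <- sd(x) / sqrt(n)
  expect_lt(abs(pooled_mean - mean(x)), 3 * se)
})

test_that("OLS wrapper fits exactly and refuses aliased designs", {
  d <- data.frame(x = 1:6)
  d$y <- 2 * d$x + 1
  fit <- fit_linear(y ~ x, d)
  expect_equal(unname(coef(fit)), c(1, 2), tolerance = 1e-12)
  expect_lt(suppressWarnings(summary(fit)$sigma), 1e-10)
  d$x2 <- d$x * 2
  expect_error(fit_linear(y ~ x + x2, d), "aliased.*x2")
})

test_that("Rubin pooling matches the hand formulas", {
  # two fits with betas {0, 2} and equal within-variance 0.5:
  # pooled beta 1, B = 2, T = 0.5 + (1 + 1/2) * 2 = 3.5
  f <- function(b, v, df = 20) list(coef = c(x = b),
                                    vcov = matrix(v, 1, 1,
                                                  dimnames = list("x", "x")),
                                    df = df)
  pf <- pool_rubin(list(f(0, 0.5), f(2, 0.5)))
  p <- pf$pooled
  expect_equal(p$estimate, 1)
  expect_equal(p$W, 0.5)
  expect_equal(p$B, 2)
  expect_equal(p$T, 3.5)
  # Barnard-Rubin df by hand: lambda = 3/3.5, dfcom = 20
  lambda <- (1 + 1 / 2) * 2 / 3.5
  df_old <- (2 - 1) / lambda^2
  df_obs <- (21 / 23) * 20 * (1 - lambda)
  expect_equal(p$df, df_old * df_obs / (df_old + df_obs))
  expect_equal(p$ci_low, 1 - qt(0.975, p$df) * sqrt(3.5))

  # identical fits: B = 0, T = W, pooled beta equals the single fit
  pf2 <- pool_rubin(list(f(1.3, 0.2), f(1.3, 0.2), f(1.3, 0.2)))
  expect_equal(pf2$pooled$B, 0)
  expect_equal(pf2$pooled$T, pf2$pooled$W)
  expect_equal(pf2$pooled$estimate, 1.3)

  expect_error(pool_rubin(list(f(0, 1), list(coef = c(z = 1),
                                             vcov = matrix(1), df = 5))),
               "mismatched term")
})

test_that("with zero missingness MI equals the complete-data OLS", {
  set.seed(12)
  d <- data.frame(participant = sprintf("P%d", 1:50),
                  x = rnorm(50), g = factor(sample(c("a", "b"), 50, TRUE)))
  d$y <- 1 + 0.8 * d$x + (d$g == "b") * 0.5 + rnorm(50)
  completed <- chained_impute(d, impute_spec(m = 5, n_iter = 2, seed = 2))
  mi <- mi_lm(y ~ x + g, completed)
  ols <- fit_linear(y ~ x + g, d)
  expect_equal(coef(mi), coef(ols), tolerance = 1e-10)
  expect_equal(mi$pooled$B, rep(0, 3), tolerance = 1e-10)
  expect_equal(mi$pooled$T, unname(diag(vcov(ols))), tolerance = 1e-10)
})

test_that("the model suite recovers planted effects and skips absent targets", {
  cfg <- sim_config(seed = 303)
  cohort <- simulate_cohort(cfg)
  std <- batch_standardize(filter_by_detection(cohort$matrix))
  cnt <- counts_per_wristband(cohort$matrix, cohort$chemicals)
  wear <- data.frame(participant = cohort$matrix$participant,
                     cohort$matrix$wear)
  suite <- suppressWarnings(
    run_model_suite(std, cnt, cohort$covariates,
                    impute_spec(m = 5, n_iter = 3, seed = 1),
                    wear = wear))
  expect_true("total_detects" %in% names(suite))
  expect_s3_class(suite[["total_detects"]], "pooled_fit")

  # planted nail-polish shift on diethyl phthalate: +0.18 log10 units
  # = +0.30 SD units of the generating log-scale spread
  nm <- "nail_polish: Diethyl phthalate"
  if (nm %in% names(suite)) {
    p <- summary(suite[[nm]])
    row <- p[p$term == "nail_polish_useyes", ]
    expect_lt(abs(row$estimate - 0.30), 3.5 * row$se)
    expect_gt(row$estimate, 0)
  }

  # summer deficit planted on the background chemicals shows up in the
  # total-detects model as a negative summer coefficient
  tot <- summary(suite[["total_detects"]])
  summer <- tot[tot$term == "seasonsummer", ]
  expect_lt(summer$estimate, 0)

  # a target chemical pushed below the screen is skipped with a warning
  cfg2 <- sim_config(n_participants = 120, seed = 404)
  cfg2$det[cfg2$chemicals$chemical == "Diethyl phthalate"] <- 0.2
  cfg2$loq <- 10^(cfg2$log_mu - cfg2$log_sigma * qnorm(cfg2$det))
  cohort2 <- simulate_cohort(cfg2)
  std2 <- batch_standardize(filter_by_detection(cohort2$matrix))
  cnt2 <- counts_per_wristband(cohort2$matrix, cohort2$chemicals)
  wear2 <- data.frame(participant = cohort2$matrix$participant,
                      cohort2$matrix$wear)
  w <- capture_warnings(
    suite2 <- run_model_suite(std2, cnt2, cohort2$covariates,
                              impute_spec(m = 2, n_iter = 2, seed = 2),
                              wear = wear2))
  expect_true(any(grepl("Diethyl phthalate.*skipped", w)))
  expect_true(any(grepl("Diethyl phthalate",
                        attr(suite2, "skipped"))))
})
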