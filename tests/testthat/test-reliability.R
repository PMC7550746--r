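mk_std <- function(values, participant = NULL, timepoint = NULL) {
  n <- nrow(values)
  structure(list(
    values = values,
    participant = if (is.null(participant)) sprintf("P%d", seq_len(n))
                  else participant,
    timepoint = if (is.null(timepoint)) rep("w12", n) else timepoint,
    batch = rep("B1", n),
    transform = list()), class = "std_matrix")
}

test_that("Spearman matrix matches direction and the rank oracle", {
  x <- 1:6
  v <- cbind(a = x, b = x^3, c = rev(x))
  sp <- spearman_matrix(mk_std(v))
  expect_equal(sp$rho["a", "b"], 1)
  expect_equal(sp$rho["a", "c"], -1)
  expect_equal(diag(sp$rho), rep(1, 3), ignore_attr = TRUE)

  # tie blocks (non-detect zeros) against the average-rank oracle
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(6:20, 1)
    a <- round(rexp(n) * sample(c(0, 1), n, TRUE, prob = c(0.4, 0.6)), 1)
    b <- round(rexp(n) * sample(c(0, 1), n, TRUE, prob = c(0.3, 0.7)), 1)
    if (length(unique(a)) == 1 || length(unique(b)) == 1) next
    got <- spearman_matrix(mk_std(cbind(a = a, b = b, c = rnorm(n))))
    expect_equal(got$rho["a", "b"], brute_spearman(a, b),
                 tolerance = 1e-12)
  }
})

test_that("all-tied chemicals yield NA with a warning", {
  v <- cbind(a = rnorm(10), b = rep(0, 10), c = rnorm(10))
  expect_warning(sp <- spearman_matrix(mk_std(v)), "all-tied.*b")
  expect_true(all(is.na(sp$rho["b", c("a", "c")])))
  expect_false(anyNA(sp$rho["a", "c"]))
  expect_equal(sp$rho["b", "b"], 1)
})

test_that("ICC limit cases behave as the variance decomposition dictates", {
  means <- rnorm(20)
  # identical timepoints, varying participant means -> ICC 1
  f1 <- estimate_icc(means, means, n_boot = 50, seed = 1)
  expect_equal(f1$icc, 1)
  expect_equal(f1$sigma2_within, 0)
  # equal participant means, pure within-pair noise -> ICC 0 (truncated)
  noise <- rnorm(20)
  f0 <- estimate_icc(5 + noise, 5 - noise, n_boot = 50, seed = 1)
  expect_equal(f0$icc, 0)
  expect_equal(f0$sigma2_between, 0)
  # all participants identical -> degenerate, flagged, ICC 0
  fd <- estimate_icc(rep(2, 10), rep(2, 10), n_boot = 20, seed = 1)
  expect_true(fd$degenerate)
  expect_equal(fd$icc, 0)
})

test_that("closed-form variance components equal the REML fit", {
  skip_if_not_installed("nlme")
  set.seed(7)
  for (case in 1:8) {
    n <- sample(c(15, 30, 60), 1)
    s2b <- runif(1, 0.2, 2)
    s2w <- runif(1, 0.2, 2)
    u <- rnorm(n, 0, sqrt(s2b))
    y1 <- u + rnorm(n, 0, sqrt(s2w))
    y2 <- 0.3 + u + rnorm(n, 0, sqrt(s2w))
    fit <- estimate_icc(y1, y2, n_boot = 0)
    d <- data.frame(y = c(y1, y2), week = rep(0:1, each = n),
                    id = factor(rep(seq_len(n), 2)))
    m <- nlme::lme(y ~ week, random = ~ 1 | id, data = d,
                   method = "REML",
                   control = nlme::lmeControl(tolerance = 1e-12,
                                              msTol = 1e-12,
                                              opt = "optim"))
    vc <- suppressWarnings(as.numeric(nlme::VarCorr(m)[, "Variance"]))
    if (min(vc) < 1e-8) next  # boundary solution; closed form truncates
    expect_equal(fit$sigma2_between, vc[1], tolerance = 1e-6)
    expect_equal(fit$sigma2_within, vc[2], tolerance = 1e-6)
  }
})

test_that("the ICC is invariant to a constant week shift", {
  set.seed(11)
  u <- rnorm(40); y1 <- u + rnorm(40, 0, 0.7); y2 <- u + rnorm(40, 0, 0.7)
  a <- estimate_icc(y1, y2, n_boot = 0)
  b <- estimate_icc(y1, y2 + 3.14, n_boot = 0)
  expect_equal(a$icc, b$icc, tolerance = 1e-12)
})

test_that("ICC recovery: generator truth 0.5 is estimated without bias", {
  cfg <- function(seed) {
    sim_config(n_participants = 500, n_chemicals = 2, loq = 0,
               icc_targets = cbind(c(1, 1), c(1, 1)),
               n_repeated = 500, seed = seed)
  }
  est <- vapply(1:10, function(s) {
    rp <- simulate_repeated(cfg(s))$matrix
    y1 <- log10(rp$concentrations[rp$timepoint == "week12", 1])
    y2 <- log10(rp$concentrations[rp$timepoint == "week24", 1])
    estimate_icc(y1, y2, n_boot = 0)$icc
  }, 0)
  expect_lt(abs(mean(est) - 0.5), 0.05)
})

test_that("reliability classes and cohort summary follow the cutpoints", {
  expect_identical(classify_reliability(c(0.4, 0.41, 0.75, 0.749, 0)),
                   c("poor", "fair to good", "excellent", "fair to good",
                     "poor"))
  fc <- frequent_chemicals()
  s <- summarize_reliability(setNames(fc$icc, fc$chemical))
  expect_equal(unname(s$percent["poor"]), 71)
  expect_equal(unname(s$percent["fair to good"]), 29)
  expect_equal(unname(s$percent["excellent"]), 0)
  expect_equal(s$median, 0.22)
  expect_equal(c(s$min, s$max), c(0.00, 0.69))
})

test_that("icc_by_chemical pairs participants across timepoints", {
  cfg <- sim_config(n_participants = 40, n_chemicals = 4,
                    det = rep(0.999, 4),
                    icc_targets = cbind(rep(1, 4), rep(1, 4)),
                    n_repeated = 40, seed = 3)
  rp <- simulate_repeated(cfg)$matrix
  std <- batch_standardize(rp)
  tab <- icc_by_chemical(std, n_boot = 100, seed = 5)
  expect_equal(nrow(tab), 4)
  expect_true(all(tab$icc >= 0 & tab$icc <= 1))
  expect_true(all(tab$ci_low <= tab$icc + 1e-9))
  expect_true(all(tab$ci_high >= tab$icc - 1e-9))
  expect_equal(tab$n, rep(40L, 4))
})
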