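test_that("cluster validity matches hand arithmetic on the 4-point instance", {
  X <- matrix(c(0, 1, 10, 11), 4, 1)
  v <- cluster_validity(X, c("A", "A", "B", "B"))
  expect_equal(unname(v["wss_bss"]), 0.01, tolerance = 1e-12)
  expect_equal(unname(v["calinski_harabasz"]), 200, tolerance = 1e-12)
  expect_equal(unname(v["dunn"]), 9, tolerance = 1e-12)
  expect_equal(unname(v["silhouette"]), 0.8997, tolerance = 1e-4)
  expect_equal(unname(v["pearson_gamma"]), 0.9909, tolerance = 1e-4)
})

test_that("cluster validity equals the brute-force pairwise oracle", {
  set.seed(8)
  for (case in 1:6) {
    n <- sample(10:30, 1)
    p <- sample(1:4, 1)
    k <- sample(2:4, 1)
    X <- matrix(rnorm(n * p), n, p) +
      matrix(rnorm(k * p, sd = 2), k, p)[sample(k, n, TRUE), , drop = FALSE]
    labels <- kmeans(X, k, nstart = 3)$cluster
    if (length(unique(labels)) < 2) next
    expect_equal(cluster_validity(X, labels), brute_validity(X, labels),
                 tolerance = 1e-9)
  }
  # two coincident clusters: inter-cluster distance 0 forces Dunn to 0
  Xc <- matrix(c(1, 1, 2, 2), 4, 1)
  expect_equal(unname(cluster_validity(Xc, c(1, 2, 1, 2))["dunn"]), 0)
  expect_error(cluster_validity(Xc, rep(1, 4)), "at least 2")
})

test_that("batch SOM training is deterministic and interpolates k points", {
  set.seed(2)
  X <- matrix(rnorm(60 * 5), 60, 5)
  f1 <- som_map(X, 2, 3, epochs = 40, seed = 99)
  f2 <- som_map(X, 2, 3, epochs = 40, seed = 99)
  expect_identical(f1$codebook, f2$codebook)
  expect_identical(f1$assignment, f2$assignment)

  # k well-separated points, tight neighborhood, radius -> 0: the
  # codebook reproduces the points exactly (interpolation limit)
  pts <- matrix(c(0, 0, 10, 0, 0, 10, 10, 10, 5, 20, -5, -5), 6, 2,
                byrow = TRUE)
  fit <- som_map(pts, 2, 3, epochs = 200, radius_init = 0.25,
                 radius_final = 0, seed = 1)
  expect_lt(fit$quantization_error, 1e-6)
  expect_equal(length(fit$occupied), 6)

  # quantization error is non-increasing over the final 10% of epochs
  tail_qe <- tail(f1$qe_trace, max(2, ceiling(0.1 * length(f1$qe_trace))))
  expect_true(all(diff(tail_qe) <= 1e-6))
})

test_that("duplicated samples leave the batch update unchanged", {
  set.seed(3)
  X <- matrix(rnorm(40 * 4), 40, 4)
  init <- X[sample(40, 6), ]
  f1 <- som_map(X, 2, 3, epochs = 30, codebook_init = init)
  f2 <- som_map(rbind(X, X), 2, 3, epochs = 30, codebook_init = init)
  expect_equal(f1$codebook, f2$codebook, tolerance = 1e-12)
})

test_that("profile assignment is nearest-codebook with low-index ties", {
  set.seed(4)
  cb <- matrix(rnorm(8 * 3), 8, 3)
  fit <- structure(list(codebook = cb, rows = 2, cols = 4),
                   class = "som_fit")
  X <- matrix(rnorm(25 * 3), 25, 3)
  expect_equal(assign_profiles(fit, X), unname(brute_nearest(X, cb)))
  # an exact tie between nodes 2 and 5 resolves to node 2
  cb2 <- matrix(0, 5, 1); cb2[2, ] <- 1; cb2[5, ] <- 3
  cb2[1, ] <- -10; cb2[3, ] <- -20; cb2[4, ] <- -30
  fit2 <- structure(list(codebook = cb2), class = "som_fit")
  expect_equal(assign_profiles(fit2, matrix(2, 1, 1)), 2L)
  # a sample sitting on a codebook vector maps to that node
  expect_equal(assign_profiles(fit, cb[6, , drop = FALSE]), 6L)
})

test_that("radius-zero SOM approaches the k-means objective", {
  cfg <- planted_config(1)
  std <- batch_standardize(filter_by_detection(simulate_cohort(cfg)$matrix))
  fit <- som_map(std$values, 2, 2, epochs = 60, radius_init = 0,
                 radius_final = 0, seed = 5)
  wss_som <- sum(vapply(unique(fit$assignment), function(g) {
    rows <- fit$assignment == g
    sum(sweep(std$values[rows, , drop = FALSE], 2,
              colMeans(std$values[rows, , drop = FALSE]))^2)
  }, 0))
  km <- kmeans(std$values, 4, nstart = 10)
  expect_lt(wss_som, km$tot.withinss * 1.05)
})

test_that("planted four-profile structure is recovered by the consensus", {
  hits <- 0
  for (s in 1:3) {
    cohort <- simulate_cohort(planted_config(100 + s))
    std <- batch_standardize(filter_by_detection(cohort$matrix))
    sel <- select_som_size(std, seed = s)
    lab <- sel$fit$assignment
    truth <- cohort$truth$profile[match(std$participant,
                                        names(cohort$truth$profile))]
    occ <- length(sel$fit$occupied)
    if (ari(truth, lab) >= 0.9 && occ >= 4 && occ <= 6) hits <- hits + 1
  }
  expect_gte(hits, 2)
})

test_that("selection is invariant to sample order", {
  cohort <- simulate_cohort(planted_config(55, n = 120))
  std <- batch_standardize(filter_by_detection(cohort$matrix))
  sel1 <- select_som_size(std$values, epochs = 40, seed = 7)
  perm <- sample(nrow(std$values))
  sel2 <- select_som_size(std$values[perm, ], epochs = 40, seed = 7)
  pick <- function(s) unlist(s$report[s$report$selected,
                                      c("rows", "cols")])
  expect_equal(pick(sel1), pick(sel2))
  expect_equal(sel2$fit$assignment, sel1$fit$assignment[perm])
})

test_that("profile characterization flags exceptional chemicals and rare profiles", {
  cohort <- simulate_cohort(planted_config(9))
  std <- batch_standardize(filter_by_detection(cohort$matrix))
  fit <- som_map(std$values, 2, 2, epochs = 80, seed = 2)
  cov <- simulate_cohort(sim_config(n_participants = 200, seed = 9))$covariates
  cov$participant <- std$participant[seq_len(nrow(cov))]
  rep <- characterize_profiles(fit, std, cov, min_n = 10)
  expect_equal(sum(rep$sizes), nrow(std$values))
  # profiles built from +3 SD blocks flag at least one exceptional chemical
  expect_true(any(lengths(rep$exceptional) > 0))
  # covariate percentages per profile sum to 100 up to rounding
  if (!is.null(rep$covariates)) {
    mar <- rep$covariates[grep("^marital", names(rep$covariates))]
    expect_true(all(abs(rowSums(mar) - 100) <= 2))
  }
  # a tiny profile is reported rare, not characterized
  fit$assignment[1:2] <- 999L
  fit$occupied <- sort(unique(fit$assignment))
  rep2 <- characterize_profiles(fit, std, cov, min_n = 10)
  expect_true(999 %in% rep2$rare)
})
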