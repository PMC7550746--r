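# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use naive loops / textbook formulas, not the package's
# vectorized code paths.

# Spearman rho as Pearson on average ranks
brute_spearman <- function(x, y) {
  stats::cor(rank(x, ties.method = "average"),
             rank(y, ties.method = "average"))
}

# the five cluster-validity statistics from explicit pair loops
brute_validity <- function(X, labels) {
  X <- as.matrix(X)
  n <- nrow(X)
  cl <- as.integer(factor(labels))
  k <- max(cl)
  dmat <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    dmat[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
  }
  wss <- 0
  for (g in seq_len(k)) {
    rows <- which(cl == g)
    cen <- colMeans(X[rows, , drop = FALSE])
    for (i in rows) wss <- wss + sum((X[i, ] - cen)^2)
  }
  gc_all <- colMeans(X)
  tss <- 0
  for (i in seq_len(n)) tss <- tss + sum((X[i, ] - gc_all)^2)
  bss <- tss - wss
  ch <- (bss / (k - 1)) / (wss / (n - k))
  inter <- Inf
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (cl[i] != cl[j]) inter <- min(inter, dmat[i, j])
  }
  diam <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (cl[i] == cl[j]) diam <- max(diam, dmat[i, j])
  }
  dunn <- if (inter == 0) 0 else if (diam == 0) Inf else inter / diam
  sil <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(cl == cl[i])
    if (length(own) == 1) { sil[i] <- 0; next }
    a <- mean(dmat[i, setdiff(own, i)])
    b <- Inf
    for (g in setdiff(seq_len(k), cl[i])) {
      b <- min(b, mean(dmat[i, cl == g]))
    }
    sil[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  dv <- iv <- numeric(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dv <- c(dv, dmat[i, j]); iv <- c(iv, as.numeric(cl[i] != cl[j]))
  }
  c(wss_bss = wss / bss, calinski_harabasz = ch, dunn = dunn,
    silhouette = mean(sil), pearson_gamma = stats::cor(dv, iv))
}

# nearest-codebook assignment by explicit scan, ties to lowest index
brute_nearest <- function(X, cb) {
  apply(X, 1, function(x) {
    d <- apply(cb, 1, function(c) sum((x - c)^2))
    which(d <= min(d) + 1e-12)[1]
  })
}

# simulation config for the 4-profile planted-cluster benchmark:
# 200 participants, 16 chemicals, each profile shifted +3 SD on its own
# disjoint block of 4 chemicals, high baseline detection. The log-scale
# spread is kept modest so the raw concentrations (what the
# batch-median standardization sees) stay near-Gaussian and "3 SD"
# means 3 SD in the analyzed feature space too.
planted_config <- function(seed, n = 200, shift_sd = 3) {
  p <- 16
  sig <- 0.15
  chems <- exposband::frequent_chemicals()$chemical[seq_len(p)]
  profiles <- lapply(0:3, function(k) {
    s <- rep(shift_sd * sig, 4)
    names(s) <- chems[4 * k + 1:4]
    list(weight = 0.25, shift = s)
  })
  sim_config(n_participants = n, n_chemicals = p, det = rep(0.95, p),
             log_sigma = sig, profile_spec = profiles,
             covariate_effects = list(), n_repeated = 0, seed = seed)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# a small fast pipeline configuration for smoke tests
small_pipeline_config <- function(seed, n_repeated = 10) {
  pipeline_config(
    sim = sim_config(n_participants = 60, n_chemicals = 25,
                     n_repeated = n_repeated, seed = seed),
    n_boot = 50, imputation = impute_spec(m = 3, n_iter = 3),
    som_min = 4, som_max = 9, som_epochs = 30, seed = seed)
}
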