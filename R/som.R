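# Batch self-organizing map, cluster-validity statistics, size selection,
# and profile characterization.

# squared Euclidean distances between rows of A and rows of B
.cross_dist2 <- function(A, B) {
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) - 2 * tcrossprod(A, B) +
    outer(rep(1, nrow(A)), rowSums(B^2))
  pmax(d2, 0)
}

.som_values <- function(x) {
  if (inherits(x, "std_matrix")) x$values else as.matrix(x)
}

#' Train a batch self-organizing map
#'
#' Batch-mode SOM on a rectangular grid with a Gaussian neighborhood. Each
#' epoch assigns every sample to its best-matching unit (nearest codebook
#' vector, Euclidean distance) and then replaces every codebook vector by
#' the neighborhood-weighted mean of the samples, with the neighborhood
#' radius decaying linearly from `radius_init` to `radius_final` over the
#' epochs; at radius 0 the update degenerates to batch k-means on the
#' grid nodes. Training is deterministic for a fixed seed (the seed
#' controls only the codebook initialization, a random sample of data
#' rows).
#'
#' @param x Numeric matrix (samples x chemicals) or a `std_matrix`.
#' @param rows,cols Grid dimensions; `rows * cols` nodes (profiles).
#' @param epochs Training epochs (default 100).
#' @param radius_init Initial neighborhood radius in grid units; default
#'   `max(rows, cols) / 2`.
#' @param radius_final Final radius (default 0).
#' @param init `"sample"` (codebook seeded from random rows of the
#'   lexicographically sorted data, so initialization — and hence the whole
#'   fit — does not depend on sample order) or `"pca"` (grid spanned by
#'   the first two principal components).
#' @param seed Optional integer seed.
#' @param codebook_init Optional explicit initial codebook
#'   (`rows * cols` x chemicals matrix), overriding `init`.
#' @return Object of class `som_fit`: `codebook` (nodes x chemicals),
#'   `grid` (node, row, col), `assignment` (per-sample best-matching
#'   node, ties to the lowest index), `occupied`, `quantization_error`
#'   (mean sample-to-BMU distance), `qe_trace`, and the training
#'   parameters.
#' @seealso [assign_profiles()], [select_som_size()],
#'   [characterize_profiles()]
#' @export
som_map <- function(x, rows, cols, epochs = 100, radius_init = NULL,
                    radius_final = 0, init = c("sample", "pca"),
                    seed = NULL, codebook_init = NULL) {
  X <- .som_values(x)
  init <- match.arg(init)
  k <- rows * cols
  n <- nrow(X)
  if (n == 0) stop("empty input", call. = FALSE)
  if (n < k) stop("need at least rows * cols samples", call. = FALSE)
  if (is.null(radius_init)) radius_init <- max(rows, cols) / 2
  grid <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  grid <- data.frame(node = seq_len(k), row = grid$row, col = grid$col)
  gd2 <- .cross_dist2(as.matrix(grid[c("row", "col")]),
                      as.matrix(grid[c("row", "col")]))
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(codebook_init)) {
    cb <- as.matrix(codebook_init)
    stopifnot(nrow(cb) == k, ncol(cb) == ncol(X))
  } else if (init == "sample") {
    ord <- do.call(order, as.data.frame(X))
    cb <- X[ord, , drop = FALSE][sample.int(n, k), , drop = FALSE]
  } else {
    pc <- stats::prcomp(X, rank. = 2)
    u <- scale(grid$row, scale = FALSE) / max(1, (rows - 1) / 2)
    v <- scale(grid$col, scale = FALSE) / max(1, (cols - 1) / 2)
    cb <- matrix(rep(colMeans(X), each = k), k) +
      cbind(u, v) %*% t(pc$rotation[, seq_len(min(2, ncol(pc$rotation))),
                                    drop = FALSE] *
                          rep(pc$sdev[seq_len(min(2, ncol(pc$rotation)))],
                              each = nrow(pc$rotation)))
  }
  qe_trace <- numeric(epochs)
  for (e in seq_len(epochs)) {
    sigma <- if (epochs == 1) radius_final else
      radius_init + (radius_final - radius_init) * (e - 1) / (epochs - 1)
    d2 <- .cross_dist2(X, cb)
    bmu <- max.col(-d2, ties.method = "first")
    qe_trace[e] <- mean(sqrt(d2[cbind(seq_len(n), bmu)]))
    H <- if (sigma > 0) exp(-gd2 / (2 * sigma^2)) else diag(k)
    Wgt <- H[, bmu, drop = FALSE]          # k x n
    den <- rowSums(Wgt)
    num <- Wgt %*% X
    upd <- den > .Machine$double.eps
    cb[upd, ] <- num[upd, , drop = FALSE] / den[upd]
  }
  d2 <- .cross_dist2(X, cb)
  bmu <- max.col(-d2, ties.method = "first")
  fit <- structure(
    list(codebook = cb, grid = grid, rows = rows, cols = cols,
         assignment = bmu, occupied = sort(unique(bmu)),
         quantization_error = mean(sqrt(d2[cbind(seq_len(n), bmu)])),
         qe_trace = qe_trace,
         params = list(epochs = epochs, radius_init = radius_init,
                       radius_final = radius_final, init = init),
         seed = seed),
    class = "som_fit")
  fit
}

#' @export
print.som_fit <- function(x, ...) {
  cat(sprintf("<som_fit> %d x %d grid (%d profiles, %d occupied)\n",
              x$rows, x$cols, x$rows * x$cols, length(x$occupied)))
  cat(sprintf("  quantization error: %.4f\n", x$quantization_error))
  invisible(x)
}

#' @export
summary.som_fit <- function(object, ...) {
  sizes <- table(factor(object$assignment,
                        levels = seq_len(object$rows * object$cols)))
  out <- list(grid = c(rows = object$rows, cols = object$cols),
              profile_sizes = sizes,
              occupied = object$occupied,
              quantization_error = object$quantization_error)
  class(out) <- "summary.som_fit"
  out
}

#' @export
print.summary.som_fit <- function(x, ...) {
  cat(sprintf("SOM %d x %d, %d occupied profiles, QE %.4f\n",
              x$grid["rows"], x$grid["cols"], length(x$occupied),
              x$quantization_error))
  print(x$profile_sizes)
  invisible(x)
}

#' @export
plot.som_fit <- function(x, ...) {
  cb <- x$codebook
  graphics::image(seq_len(nrow(cb)), seq_len(ncol(cb)), cb,
                  xlab = "profile (node)", ylab = "chemical",
                  main = "SOM codebook (standardized concentration)",
                  axes = FALSE, ...)
  graphics::axis(1, at = seq_len(nrow(cb)))
  graphics::axis(2, at = seq_len(ncol(cb)), labels = colnames(cb),
                 las = 2, cex.axis = 0.6)
  invisible(x)
}

#' Assign samples to SOM profiles
#'
#' Labels each sample with the index of its nearest codebook vector
#' (Euclidean distance); exact ties go to the lowest node index.
#'
#' @param fit A `som_fit`.
#' @param x Matrix or `std_matrix` with the same chemical axes as the
#'   codebook.
#' @return Integer vector of node indices.
#' @export
assign_profiles <- function(fit, x) {
  X <- .som_values(x)
  if (ncol(X) != ncol(fit$codebook)) {
    stop("chemical axes do not match the codebook", call. = FALSE)
  }
  d2 <- .cross_dist2(X, fit$codebook)
  # round distances so floating-point noise cannot hide an exact tie
  max.col(-round(d2, 12), ties.method = "first")
}

#' @export
predict.som_fit <- function(object, newdata, ...) {
  assign_profiles(object, newdata)
}

#' Internal cluster-validity statistics
#'
#' Computes, over the occupied clusters of a labelling: the ratio of
#' within-cluster to between-cluster sum of squares (WSS/BSS, smaller is
#' better), the Calinski-Harabasz index `(BSS/(k-1)) / (WSS/(n-k))`, the
#' Dunn index (minimum single-linkage inter-cluster distance divided by
#' the maximum intra-cluster diameter; 0 when two clusters touch), the
#' mean silhouette width (singleton clusters contribute 0), and the
#' Pearson Gamma statistic (Pearson correlation between the pairwise
#' distance vector and the 0/1 different-cluster indicator).
#'
#' @param x Numeric matrix or `std_matrix`.
#' @param labels Cluster label per row (any type; occupied clusters only).
#' @return Named numeric vector: `wss_bss`, `calinski_harabasz`, `dunn`,
#'   `silhouette`, `pearson_gamma`.
#' @export
cluster_validity <- function(x, labels) {
  X <- .som_values(x)
  labels <- as.vector(labels)
  stopifnot(nrow(X) == length(labels))
  cl <- factor(labels)
  k <- nlevels(cl)
  n <- nrow(X)
  if (k < 2) stop("need at least 2 occupied clusters", call. = FALSE)
  idx <- split(seq_len(n), cl)
  cm <- vapply(idx, function(i) colMeans(X[i, , drop = FALSE]),
               numeric(ncol(X)))
  centroids <- if (is.matrix(cm)) t(cm) else matrix(cm, ncol = 1)
  wss <- sum(vapply(seq_len(k), function(j) {
    sum(sweep(X[idx[[j]], , drop = FALSE], 2, centroids[j, ])^2)
  }, 0))
  tss <- sum(sweep(X, 2, colMeans(X))^2)
  bss <- tss - wss
  ch <- (bss / (k - 1)) / (wss / (n - k))

  D <- as.matrix(stats::dist(X))
  ci <- as.integer(cl)
  same <- outer(ci, ci, "==")
  diag(same) <- NA
  inter <- suppressWarnings(min(D[!same], na.rm = TRUE))
  intra_diam <- max(vapply(idx, function(i) {
    if (length(i) < 2) 0 else max(D[i, i])
  }, 0))
  dunn <- if (inter == 0) 0 else if (intra_diam == 0) Inf else
    inter / intra_diam

  # silhouette
  sizes <- lengths(idx)
  sil <- vapply(seq_len(n), function(i) {
    own <- ci[i]
    if (sizes[own] == 1L) return(0)
    a <- sum(D[i, ci == own]) / (sizes[own] - 1)
    b <- min(vapply(which(seq_len(k) != own), function(j) {
      mean(D[i, ci == j])
    }, 0))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, 0)

  dv <- D[upper.tri(D)]
  iv <- (!same)[upper.tri(same)]
  pg <- suppressWarnings(stats::cor(dv, as.numeric(iv)))

  c(wss_bss = wss / bss, calinski_harabasz = ch, dunn = dunn,
    silhouette = mean(sil), pearson_gamma = pg)
}

# all grid shapes (r <= c) with node count in [lo, hi]
som_candidates <- function(lo = 4, hi = 25) {
  out <- list()
  for (kk in lo:hi) {
    for (r in seq_len(floor(sqrt(kk)))) {
      if (kk %% r == 0) out[[length(out) + 1L]] <- c(r, kk / r)
    }
  }
  do.call(rbind, out)
}

#' Choose a SOM size by cluster-validity consensus
#'
#' Trains one SOM per candidate grid (all shapes `r <= c` with between
#' `min_profiles` and `max_profiles` nodes, sharing one seed), computes
#' the five validity statistics on the occupied-profile assignment, ranks
#' the candidates per statistic (WSS/BSS ascending; the other four
#' descending), and selects the candidate with the smallest mean rank.
#' Ties prefer fewer profiles, then the shape closest to square.
#' Candidates whose fit occupies fewer than two profiles are dropped as
#' degenerate. The consensus rule ("most agreement" = minimum mean rank)
#' is a package convention; the statistics themselves are reported so
#' other rules can be applied.
#'
#' @param x Matrix or `std_matrix`.
#' @param min_profiles,max_profiles Node-count range (defaults 4 and 25).
#' @param candidates Optional 2-column matrix of (rows, cols) overriding
#'   the enumeration.
#' @param epochs,radius_final,init Passed to [som_map()].
#' @param seed Integer seed shared by every candidate fit.
#' @return Object of class `som_selection`: `report` (one row per
#'   candidate with the statistics, per-statistic ranks, mean rank and a
#'   `selected` flag), `fit` (the chosen `som_fit`), `seed`.
#' @export
select_som_size <- function(x, min_profiles = 4, max_profiles = 25,
                            candidates = NULL, epochs = 100,
                            radius_final = 0, init = "sample", seed = 1L) {
  X <- .som_values(x)
  if (is.null(candidates)) {
    candidates <- som_candidates(min_profiles, max_profiles)
  }
  stats_names <- c("wss_bss", "calinski_harabasz", "dunn", "silhouette",
                   "pearson_gamma")
  rows <- candidates[, 1]
  cols <- candidates[, 2]
  fits <- vector("list", nrow(candidates))
  stat <- matrix(NA_real_, nrow(candidates), length(stats_names),
                 dimnames = list(NULL, stats_names))
  occ <- integer(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    fits[[i]] <- som_map(X, rows[i], cols[i], epochs = epochs,
                         radius_final = radius_final, init = init,
                         seed = seed)
    occ[i] <- length(fits[[i]]$occupied)
    if (occ[i] >= 2) {
      stat[i, ] <- cluster_validity(X, fits[[i]]$assignment)
    }
  }
  valid <- occ >= 2 & apply(is.finite(stat) | is.na(stat), 1, all) &
    !is.na(stat[, 1])
  if (!any(valid)) stop("every candidate fit is degenerate", call. = FALSE)
  rk <- matrix(NA_real_, nrow(candidates), length(stats_names),
               dimnames = list(NULL, paste0("rank_", stats_names)))
  rk[valid, "rank_wss_bss"] <- rank(stat[valid, "wss_bss"])
  for (s in stats_names[-1]) {
    rk[valid, paste0("rank_", s)] <- rank(-stat[valid, s])
  }
  mean_rank <- rowMeans(rk)
  nodes <- rows * cols
  ord <- order(mean_rank, nodes, abs(rows - cols), seq_along(nodes),
               na.last = TRUE)
  best <- ord[1]
  report <- data.frame(rows = rows, cols = cols, n_profiles = nodes,
                       occupied = occ, stat, rk, mean_rank = mean_rank,
                       selected = seq_along(nodes) == best,
                       row.names = NULL, check.names = FALSE)
  structure(list(report = report, fit = fits[[best]], seed = seed),
            class = "som_selection")
}

#' @export
print.som_selection <- function(x, ...) {
  sel <- x$report[x$report$selected, ]
  cat(sprintf(
    "<som_selection> chose %d x %d (%d profiles, %d occupied) by mean validity rank %.2f\n",
    sel$rows, sel$cols, sel$n_profiles, sel$occupied, sel$mean_rank))
  cat(sprintf("  %d candidate grids evaluated; consensus = minimum mean rank over\n  WSS/BSS, Calinski-Harabasz, Dunn, silhouette, Pearson Gamma\n",
              nrow(x$report)))
  invisible(x)
}

#' Characterize SOM exposure profiles
#'
#' For every occupied profile: membership count, per-chemical median
#' standardized concentration, and the "exceptional" chemicals whose
#' profile median is at least `exceptional` SD units above the cohort
#' mean. Profiles with at least `min_n` members additionally get a
#' covariate panel (medians for continuous covariates, integer
#' percentages per level for categorical ones); smaller profiles are
#' listed as rare.
#'
#' @param fit A `som_fit` trained on the same samples as `std`.
#' @param std The `std_matrix` the map was trained on.
#' @param cov Covariate data frame keyed by `participant` (profile
#'   percentages ignore missing values).
#' @param min_n Minimum membership for the covariate panel (default 10).
#' @param exceptional Threshold, in standardized units, above which a
#'   profile median flags the chemical (default 1.0).
#' @return Object of class `profile_report`: `sizes`, `medians`
#'   (profiles x chemicals), `exceptional` (list), `rare` (profile ids),
#'   `covariates` (data frame, one row per non-rare profile).
#' @export
characterize_profiles <- function(fit, std, cov = NULL, min_n = 10,
                                  exceptional = 1.0) {
  stopifnot(inherits(fit, "som_fit"), inherits(std, "std_matrix"))
  lab <- fit$assignment
  profs <- sort(unique(lab))
  med <- t(vapply(profs, function(p) {
    apply(std$values[lab == p, , drop = FALSE], 2, stats::median)
  }, numeric(ncol(std$values))))
  rownames(med) <- paste0("profile_", profs)
  sizes <- stats::setNames(as.integer(table(factor(lab, levels = profs))),
                           rownames(med))
  exc <- apply(med, 1, function(r) {
    colnames(med)[r >= exceptional]
  }, simplify = FALSE)
  rare <- profs[sizes < min_n]
  cov_tab <- NULL
  if (!is.null(cov)) {
    rows <- list()
    for (p in profs[sizes >= min_n]) {
      members <- std$participant[lab == p]
      cc <- cov[cov$participant %in% members, , drop = FALSE]
      row <- list(profile = p, n = length(members))
      for (v in setdiff(names(cc), "participant")) {
        if (is.numeric(cc[[v]])) {
          row[[paste0(v, "_median")]] <- stats::median(cc[[v]], na.rm = TRUE)
        } else {
          tab <- table(cc[[v]])
          pct <- round(100 * tab / sum(tab))
          for (lv in names(pct)) {
            row[[paste0(v, ": ", lv, " %")]] <- as.integer(pct[[lv]])
          }
        }
      }
      rows[[length(rows) + 1L]] <- as.data.frame(row, check.names = FALSE)
    }
    if (length(rows) > 0) cov_tab <- do.call(rbind, rows)
  }
  structure(list(sizes = sizes, medians = med, exceptional = exc,
                 rare = rare, min_n = min_n, covariates = cov_tab),
            class = "profile_report")
}

#' @export
print.profile_report <- function(x, ...) {
  cat(sprintf("<profile_report> %d occupied profiles (%d rare, n < %d)\n",
              length(x$sizes), length(x$rare), x$min_n))
  for (i in seq_along(x$sizes)) {
    nm <- names(x$sizes)[i]
    ex <- x$exceptional[[nm]]
    cat(sprintf("  %s: n = %d%s\n", nm, x$sizes[i],
                if (length(ex) > 0)
                  paste0("  exceptional: ", paste(ex, collapse = ", "))
                else ""))
  }
  invisible(x)
}
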