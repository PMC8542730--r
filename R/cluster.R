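# Clustering of latent coordinates and objective selection of the latent
# dimension and the number of clusters by the gap statistic.

new_cluster_solution <- function(method, labels, coords, extra = list()) {
  labels <- as.integer(labels)
  k <- length(unique(labels))
  cent <- cluster_centroids(coords, labels)
  sol <- c(list(method = method, k = k, labels = labels, centroids = cent,
                d = ncol(coords), W_k = within_dispersion(coords, labels),
                sizes = as.integer(table(labels))), extra)
  class(sol) <- "cluster_solution"
  sol
}

cluster_centroids <- function(coords, labels) {
  ks <- sort(unique(labels))
  cent <- t(vapply(ks, function(g)
    colMeans(coords[labels == g, , drop = FALSE]), numeric(ncol(coords))))
  rownames(cent) <- ks
  cent
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("cluster_solution: %s, k = %d (sizes %s), d = %d, W_k = %.4g\n",
              x$method, x$k, paste(x$sizes, collapse = "/"), x$d, x$W_k))
  if (!is.null(x$gap)) cat(sprintf("  gap = %.4f (se %.4f)\n", x$gap, x$gap_se))
  invisible(x)
}

#' Within-cluster dispersion for the gap statistic
#'
#' `W_k = sum_r (1 / (2 n_r)) sum_{i, i' in C_r} ||x_i - x_i'||^2`, which
#' equals the pooled within-cluster sum of squares about the centroids.
#'
#' @param emb an `embedding` or a numeric coordinate matrix.
#' @param labels cluster labels, one per row.
#' @return non-negative scalar.
#' @export
within_dispersion <- function(emb, labels) {
  coords <- if (inherits(emb, "embedding")) emb$coords else as.matrix(emb)
  if (anyNA(labels)) stop("labels contain NA", call. = FALSE)
  if (length(labels) != nrow(coords)) stop("labels do not match coordinates",
                                           call. = FALSE)
  if (any(table(labels) == 0L)) stop("empty cluster", call. = FALSE)
  total <- 0
  for (g in unique(labels)) {
    x <- coords[labels == g, , drop = FALSE]
    total <- total + sum(sweep(x, 2, colMeans(x))^2)
  }
  total
}

#' Agglomerative (Ward) clustering of an embedding
#'
#' Ward linkage on Euclidean distances, cut at `k` groups; deterministic.
#'
#' @param emb an `embedding`.
#' @param k number of clusters.
#' @return a `cluster_solution`.
#' @export
cluster_hierarchical <- function(emb, k) {
  coords <- emb$coords
  if (k > nrow(coords)) stop("k exceeds the number of points", call. = FALSE)
  tree <- stats::hclust(stats::dist(coords), method = "ward.D2")
  new_cluster_solution("hierarchical", stats::cutree(tree, k = k), coords)
}

# D^2-weighted seeding (k-means++)
kmeanspp_seed <- function(coords, k) {
  n <- nrow(coords)
  centers <- matrix(NA_real_, k, ncol(coords))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- coords[idx, ]
  if (k > 1L) {
    d2 <- rowSums(sweep(coords, 2, centers[1L, ])^2)
    for (j in 2:k) {
      if (sum(d2) <= 0) {
        idx <- sample.int(n, 1L)  # all remaining points coincide with centres
      } else {
        idx <- sample.int(n, 1L, prob = d2)
      }
      centers[j, ] <- coords[idx, ]
      d2 <- pmin(d2, rowSums(sweep(coords, 2, centers[j, ])^2))
    }
  }
  centers
}

#' k-means++ clustering of an embedding
#'
#' D^2-weighted seeding followed by Lloyd iterations; the best of `n_init`
#' seeded restarts (by within-cluster sum of squares) is returned.
#' Deterministic for a fixed seed.
#'
#' @param emb an `embedding`.
#' @param k number of clusters.
#' @param seed integer seed.
#' @param n_init number of restarts.
#' @return a `cluster_solution`.
#' @export
cluster_kmeanspp <- function(emb, k, seed = 1L, n_init = 10L) {
  coords <- emb$coords
  if (k > nrow(coords)) stop("k exceeds the number of points", call. = FALSE)
  with_seed(seed, {
    best <- NULL
    for (i in seq_len(n_init)) {
      centers <- kmeanspp_seed(coords, k)
      centers <- unique(centers)
      km <- tryCatch(
        suppressWarnings(stats::kmeans(coords, centers = centers,
                                       iter.max = 100L, algorithm = "Lloyd")),
        error = function(e) NULL)
      if (is.null(km)) next
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    if (is.null(best)) stop("k-means failed for every restart", call. = FALSE)
    new_cluster_solution("kmeanspp", best$cluster, coords)
  })
}

cluster_backend <- function(method = c("hierarchical", "kmeanspp")) {
  method <- match.arg(method)
  if (method == "hierarchical") {
    function(coords, k_grid, seed) {
      tree <- stats::hclust(stats::dist(coords), method = "ward.D2")
      cuts <- stats::cutree(tree, k = k_grid)
      cuts <- matrix(cuts, nrow = nrow(coords))
      colnames(cuts) <- k_grid
      cuts
    }
  } else {
    function(coords, k_grid, seed) {
      emb <- structure(list(coords = coords, d = ncol(coords)),
                       class = "embedding")
      cuts <- vapply(seq_along(k_grid), function(i)
        cluster_kmeanspp(emb, k_grid[i],
                         seed = derive_seed(seed, paste0("k", k_grid[i])),
                         n_init = 5L)$labels,
        integer(nrow(coords)))
      colnames(cuts) <- k_grid
      cuts
    }
  }
}

# Uniform reference draws over the data's principal-axis-aligned bounding box
# (Tibshirani's recommended variant of the gap-statistic null).
gap_reference_sampler <- function(coords) {
  ctr <- colMeans(coords)
  xc <- sweep(coords, 2, ctr)
  sv <- svd(xc, nu = 0)
  rot <- xc %*% sv$v
  lo <- apply(rot, 2, min); hi <- apply(rot, 2, max)
  if (all(hi - lo <= 0)) stop("degenerate (zero-volume) bounding box", call. = FALSE)
  function(n) {
    z <- vapply(seq_along(lo), function(j) runif(n, lo[j], hi[j]), numeric(n))
    matrix(z, n) %*% t(sv$v) + rep(ctr, each = n)
  }
}

#' Gap statistic over a grid of cluster numbers
#'
#' For each `k`, compares `log W_k` of the data clustering against the mean
#' `log W*_k` of `B` reference datasets drawn uniformly over the data's
#' principal-axis-aligned bounding box:
#' `gap(k) = mean_b log W*_kb - log W_k`, with standard error
#' `sd_b(log W*_kb) * sqrt(1 + 1/B)`.
#'
#' @param emb an `embedding`.
#' @param k_grid integer vector of candidate cluster numbers.
#' @param method clustering backend, `"hierarchical"` or `"kmeanspp"`.
#' @param B number of reference datasets (>= 10).
#' @param seed integer seed.
#' @return data.frame with columns `k`, `logW`, `logW_ref`, `gap`, `se`.
#' @export
gap_curve <- function(emb, k_grid, method = "hierarchical", B = 50L, seed = 1L) {
  if (B < 10L) stop("B must be at least 10", call. = FALSE)
  coords <- emb$coords
  backend <- cluster_backend(method)
  sampler <- gap_reference_sampler(coords)
  logW <- function(coords, cuts) {
    vapply(seq_len(ncol(cuts)), function(i)
      log(within_dispersion(coords, cuts[, i])), numeric(1))
  }
  with_seed(seed, {
    obs <- logW(coords, backend(coords, k_grid, derive_seed(seed, "obs")))
    ref <- vapply(seq_len(B), function(b) {
      rc <- sampler(nrow(coords))
      logW(rc, backend(rc, k_grid, derive_seed(seed, paste0("ref", b))))
    }, numeric(length(k_grid)))
    ref <- matrix(ref, nrow = length(k_grid))
    data.frame(k = k_grid,
               logW = obs,
               logW_ref = rowMeans(ref),
               gap = rowMeans(ref) - obs,
               se = apply(ref, 1, stats::sd) * sqrt(1 + 1 / B))
  })
}

#' Gap statistic at a single k
#'
#' @inheritParams gap_curve
#' @param k number of clusters.
#' @return list with `gap` and `gap_se`.
#' @export
gap_statistic <- function(emb, k, method = "hierarchical", B = 50L, seed = 1L) {
  g <- gap_curve(emb, k_grid = k, method = method, B = B, seed = seed)
  list(gap = g$gap[1], gap_se = g$se[1])
}

# ---- internal cluster-quality indices (reported, never used for selection) --

silhouette_mean <- function(coords, labels, max_n = 2500L, seed = 1L) {
  n <- nrow(coords)
  if (n > max_n) {
    idx <- with_seed(seed, sample.int(n, max_n))
    coords <- coords[idx, , drop = FALSE]; labels <- labels[idx]
  }
  dm <- as.matrix(stats::dist(coords))
  ks <- unique(labels)
  if (length(ks) < 2L) return(NA_real_)
  s <- numeric(nrow(dm))
  for (i in seq_len(nrow(dm))) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1L) sum(dm[i, own]) / (sum(own) - 1L) else 0
    b <- min(vapply(ks[ks != labels[i]], function(g)
      mean(dm[i, labels == g]), numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

calinski_harabasz <- function(coords, labels) {
  n <- nrow(coords); k <- length(unique(labels))
  if (k < 2L || k >= n) return(NA_real_)
  w <- within_dispersion(coords, labels)
  grand <- colMeans(coords)
  b <- 0
  for (g in unique(labels)) {
    x <- coords[labels == g, , drop = FALSE]
    b <- b + nrow(x) * sum((colMeans(x) - grand)^2)
  }
  (b / (k - 1)) / (w / (n - k))
}

davies_bouldin <- function(coords, labels) {
  ks <- sort(unique(labels))
  if (length(ks) < 2L) return(NA_real_)
  cent <- cluster_centroids(coords, labels)
  s <- vapply(seq_along(ks), function(i) {
    x <- coords[labels == ks[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(x, 2, cent[i, ])^2)))
  }, numeric(1))
  db <- vapply(seq_along(ks), function(i) {
    max(vapply(seq_along(ks)[-i], function(j) {
      dij <- sqrt(sum((cent[i, ] - cent[j, ])^2))
      if (dij == 0) Inf else (s[i] + s[j]) / dij
    }, numeric(1)))
  }, numeric(1))
  mean(db)
}

internal_indices <- function(coords, labels) {
  c(silhouette = silhouette_mean(coords, labels),
    calinski_harabasz = calinski_harabasz(coords, labels),
    davies_bouldin = davies_bouldin(coords, labels))
}

#' Joint selection of latent dimension and cluster number
#'
#' For every latent dimension in `d_grid`, fits the embedder and computes the
#' gap statistic across `k_grid`; the model with the highest gap value wins
#' (ties broken toward smaller k, then smaller d).  The winning solution is
#' annotated with three internal performance measures (mean silhouette,
#' Calinski-Harabasz, Davies-Bouldin), which are reported but play no role in
#' selection.
#'
#' @param X a `feature_matrix`.
#' @param d_grid candidate latent dimensions.
#' @param k_grid candidate cluster numbers.
#' @param method clustering backend.
#' @param B reference datasets per gap evaluation.
#' @param seed master seed.
#' @param embedder `"vae"` or `"pca"`.
#' @param vae_args list of overrides passed to [vae_config()] (e.g. `epochs`).
#' @return list with `gap` (a `gap_result`), `solution` (the winning
#'   `cluster_solution`), `embedding`, and `embedder` (the fitted embedder of
#'   the winning dimension).
#' @export
select_model <- function(X, d_grid = 2:12, k_grid = 2:10,
                         method = c("hierarchical", "kmeanspp"),
                         B = 50L, seed = 1L,
                         embedder = c("vae", "pca"), vae_args = list()) {
  method <- match.arg(method); embedder <- match.arg(embedder)
  if (!length(d_grid) || !length(k_grid)) stop("empty grid", call. = FALSE)
  fits <- list(); embs <- list()
  gap_m <- matrix(NA_real_, length(d_grid), length(k_grid),
                  dimnames = list(d_grid, k_grid))
  se_m <- gap_m
  for (i in seq_along(d_grid)) {
    d <- d_grid[i]
    if (embedder == "vae") {
      cfg <- do.call(vae_config, c(list(latent_dim = d,
                                        seed = derive_seed(seed, paste0("vae", d))),
                                   vae_args))
      fit <- fit_vae(X, cfg)
      emb <- encode_mean(fit, X)
    } else {
      fit <- NULL
      emb <- fit_pca(X, d)
    }
    fits[i] <- list(fit); embs[[i]] <- emb
    gc <- gap_curve(emb, k_grid, method = method, B = B,
                    seed = derive_seed(seed, paste0("gap", d)))
    gap_m[i, ] <- gc$gap; se_m[i, ] <- gc$se
  }
  # argmax with parsimony tie-breaks: smaller k first, then smaller d
  best <- c(1L, 1L); bestval <- -Inf
  for (ki in seq_along(k_grid)) for (di in seq_along(d_grid)) {
    if (gap_m[di, ki] > bestval + 1e-12) { bestval <- gap_m[di, ki]; best <- c(di, ki) }
  }
  d_star <- d_grid[best[1]]; k_star <- k_grid[best[2]]
  emb <- embs[[best[1]]]
  sol <- if (method == "hierarchical") cluster_hierarchical(emb, k_star)
         else cluster_kmeanspp(emb, k_star, seed = derive_seed(seed, "final"))
  sol$gap <- gap_m[best[1], best[2]]
  sol$gap_se <- se_m[best[1], best[2]]
  sol$internal_indices <- internal_indices(emb$coords, sol$labels)
  kmin_i <- which.min(k_grid)
  gap_res <- structure(list(
    d_grid = d_grid, k_grid = k_grid, gap_matrix = gap_m, se_matrix = se_m,
    B = B, reference_model = "uniform over principal-axis-aligned bounding box",
    best = c(d = d_star, k = k_star),
    weak_structure = (bestval - gap_m[best[1], kmin_i]) <
      2 * se_m[best[1], kmin_i]),
    class = "gap_result")
  list(gap = gap_res, solution = sol, embedding = emb,
       embedder = fits[[best[1]]])
}

#' @export
print.gap_result <- function(x, ...) {
  cat(sprintf("gap_result: best d = %d, k = %d (gap %.4f), B = %d%s\n",
              x$best["d"], x$best["k"],
              x$gap_matrix[as.character(x$best["d"]), as.character(x$best["k"])],
              x$B, if (isTRUE(x$weak_structure)) " [weak structure]" else ""))
  invisible(x)
}

#' Canonical cluster numbering by mortality risk
#'
#' Renumbers cluster labels 1..k in ascending order of observed death
#' proportion, so that reported cluster ids are stable across runs
#' (cluster 1 = lowest mortality).
#'
#' @param labels cluster labels.
#' @param death 0/1 outcome vector aligned with `labels`.
#' @return integer labels 1..k.
#' @export
canonicalise_labels <- function(labels, death) {
  stopifnot(length(labels) == length(death))
  rate <- tapply(death, labels, mean)
  ord <- names(sort(rate))
  match(as.character(labels), ord)
}

#' Per-cluster covariate profile for radar plots
#'
#' Continuous variables: cluster median divided by cohort median (undefined
#' when the cohort median is zero, reported as `NA`).  Binary variables:
#' cluster proportion, with the cohort proportion alongside.
#'
#' @param table patient table.
#' @param labels cluster labels aligned with the table rows.
#' @return data.frame with one row per cluster x variable.
#' @export
cluster_profile <- function(table, labels) {
  stopifnot(nrow(table) == length(labels))
  cv <- continuous_variables(); bv <- binary_variables()
  binval <- function(v) {
    if (v == "gender") as.numeric(table$gender == "female")
    else if (v == "nyha") as.numeric(table$nyha %in% c(3, 4))
    else as.numeric(table[[v]])
  }
  rows <- list()
  for (v in cv) {
    med <- stats::median(table[[v]])
    for (g in sort(unique(labels))) {
      cl_med <- stats::median(table[[v]][labels == g])
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = g, variable = v, type = "continuous",
        cluster_value = cl_med, cohort_value = med,
        scaled = if (med == 0) NA_real_ else cl_med / med)
    }
  }
  for (v in bv) {
    x <- binval(v)
    coh <- mean(x)
    for (g in sort(unique(labels))) {
      pr <- mean(x[labels == g])
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = g, variable = v, type = "binary",
        cluster_value = pr, cohort_value = coh,
        scaled = if (coh == 0) NA_real_ else pr / coh)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
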