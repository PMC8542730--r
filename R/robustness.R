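# Cluster-stability protocol: repeated clustering of random subsets
# (bootstrapping), scored by the weighted Jaccard overlap against the
# reference partition, with a proportion-preserving random-assignment null
# and a two-sample Kolmogorov-Smirnov comparison.

#' Weighted Jaccard score between two partitions
#'
#' Each cluster of `labels_a` is matched to the cluster of `labels_b` with
#' the highest Jaccard overlap of member sets (|intersection| / |union|);
#' the score is the cluster-size-weighted mean of these best overlaps.
#' Invariant to label renaming; 1 for identical partitions.
#'
#' @param labels_a,labels_b partitions over the same patient index set.  If
#'   named (or accompanied by `index_a`/`index_b`), the indices must agree.
#' @param index_a,index_b optional patient indices aligning the two label
#'   vectors.
#' @param symmetric if `TRUE`, return the mean of the A-to-B and B-to-A
#'   scores.
#' @return score in \[0, 1\].
#' @export
weighted_jaccard <- function(labels_a, labels_b, index_a = NULL, index_b = NULL,
                             symmetric = FALSE) {
  if (!is.null(index_a) || !is.null(index_b)) {
    if (is.null(index_a) || is.null(index_b) ||
        length(setdiff(index_a, index_b)) || length(setdiff(index_b, index_a))) {
      stop("label vectors are over different patient index sets", call. = FALSE)
    }
    labels_b <- labels_b[match(index_a, index_b)]
  }
  if (length(labels_a) != length(labels_b)) {
    stop("label vectors are over different patient index sets", call. = FALSE)
  }
  one_way <- function(a, b) {
    n <- length(a)
    tab <- table(a, b)
    ra <- rowSums(tab); cb <- colSums(tab)
    # Jaccard of cluster i of a vs j of b: n_ij / (n_i + n_j - n_ij)
    jac <- tab / (outer(ra, cb, "+") - tab)
    sum((ra / n) * apply(jac, 1, max))
  }
  if (symmetric) {
    (one_way(labels_a, labels_b) + one_way(labels_b, labels_a)) / 2
  } else {
    one_way(labels_a, labels_b)
  }
}

#' Two-sample Kolmogorov-Smirnov comparison of score distributions
#'
#' @param obs observed score vector.
#' @param null null score vector.
#' @return list with `D` (sup ECDF difference) and `p` (asymptotic two-sided).
#' @export
ks_compare <- function(obs, null) {
  if (!length(obs) || !length(null)) stop("empty score vector", call. = FALSE)
  kt <- suppressWarnings(stats::ks.test(obs, null, exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Bootstrap stability of a fitted clustering
#'
#' Repeatedly draws a random subset of the data (fraction `frac`, without
#' replacement), re-embeds and re-clusters it at the fixed `(d*, k*)` of the
#' reference model, and scores the weighted Jaccard overlap between the new
#' partition and the reference partition restricted to the subset.  A
#' matched null replaces the re-clustered labels with random labels drawn
#' with the reference cluster-size proportions.
#'
#' @param fit a [phenomap()] fit (carries the data, embedder and reference
#'   labels).
#' @param n_boot number of bootstrap iterations.
#' @param frac subset fraction in (0, 1].
#' @param seed integer seed.
#' @param refit_embedding refit the embedder on every subset (default,
#'   conservative); if `FALSE` the reference embedding is frozen and only
#'   the clustering is redone.
#' @return object of class `stability_result`: `jaccard_scores`,
#'   `random_scores`, their means and SDs, and the KS comparison.
#' @export
bootstrap_stability <- function(fit, n_boot = 100L, frac = 0.8, seed = 1L,
                                refit_embedding = TRUE) {
  stopifnot(inherits(fit, "phenomap"))
  if (frac <= 0 || frac > 1) stop("frac must be in (0, 1]", call. = FALSE)
  n <- nrow(fit$features$values)
  m <- max(2L, round(frac * n))
  k <- fit$solution$k
  if (m < k) stop("subset smaller than the number of clusters", call. = FALSE)
  ref_labels <- fit$solution$labels
  prop <- as.numeric(table(ref_labels)) / n
  method <- fit$solution$method
  jac <- numeric(n_boot); ran <- numeric(n_boot)
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- if (frac < 1) sample.int(n, m) else seq_len(n)
      Xb <- fm_subset(fit$features, idx)
      if (refit_embedding && fit$embedder_type == "vae") {
        cfg <- fit$embedder$config
        cfg$seed <- derive_seed(seed, paste0("boot", b))
        emb <- encode_mean(fit_vae(Xb, cfg), Xb)
      } else if (fit$embedder_type == "vae") {
        emb <- encode_mean(fit$embedder, Xb)
      } else {
        emb <- if (refit_embedding) fit_pca(Xb, fit$solution$d) else {
          structure(list(coords = fit$embedding$coords[idx, , drop = FALSE],
                         source = "pca", d = fit$solution$d),
                    class = "embedding")
        }
      }
      sol <- if (method == "hierarchical") cluster_hierarchical(emb, k)
             else cluster_kmeanspp(emb, k,
                                   seed = derive_seed(seed, paste0("km", b)))
      jac[b] <- weighted_jaccard(sol$labels, ref_labels[idx])
      rand_labels <- sample.int(k, m, replace = TRUE, prob = prop)
      ran[b] <- weighted_jaccard(rand_labels, ref_labels[idx])
    }
  })
  ks <- ks_compare(jac, ran)
  structure(list(jaccard_scores = jac, random_scores = ran,
                 mean_jaccard = mean(jac), sd_jaccard = stats::sd(jac),
                 mean_random = mean(ran), sd_random = stats::sd(ran),
                 ks_statistic = ks$D, ks_p = ks$p,
                 n_boot = n_boot, frac = frac,
                 refit_embedding = refit_embedding),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf(paste0("stability_result: mean Jaccard %.3f (SD %.3f) vs random ",
                     "%.3f (SD %.3f); KS D = %.3f, p = %.3g (%d bootstraps)\n"),
              x$mean_jaccard, x$sd_jaccard, x$mean_random, x$sd_random,
              x$ks_statistic, x$ks_p, x$n_boot))
  invisible(x)
}
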