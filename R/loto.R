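# Leave-one-trial-out external validation: refit the embedding + clustering
# on all trials but one, compare with the full-data partition (ARI), and
# predict cluster membership for the held-out trial.

#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected pairwise agreement,
#' `(Index - ExpectedIndex) / (MaxIndex - ExpectedIndex)` from the label
#' contingency table: 1 for identical partitions (up to renaming),
#' expectation 0 under random permutation of either labelling.
#'
#' @param labels_a,labels_b partitions over the same elements (length >= 2).
#' @return value in \[-1, 1\].
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("partitions are over different index sets", call. = FALSE)
  }
  n <- length(labels_a)
  if (n < 2L) stop("ARI is undefined for fewer than 2 elements", call. = FALSE)
  tab <- table(labels_a, labels_b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  n2 <- choose(n, 2)
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (maxi - expected)
}

#' Leave-one-trial-out validation of the clustering pipeline
#'
#' For every trial `t`: the embedding and clustering are refit on the
#' remaining trials at the full-data `(d*, k*)`; `ari_iteration` scores the
#' agreement of that refit partition with the full-data partition on the
#' shared patients, and `ari_prediction` scores the agreement of
#' nearest-centroid predicted labels for trial `t` with the full-data
#' partition on that trial.  Significance against a random model is assessed
#' by permuting the full-data labels (`n_perm` permutations of the mean
#' prediction ARI).
#'
#' @param table prepared single-stratum patient table (complete cases, with
#'   `trial_id`).
#' @param d,k latent dimension and cluster number, fixed at the full-data
#'   selection.
#' @param method clustering backend.
#' @param embedder `"vae"` or `"pca"`.
#' @param vae_args overrides for [vae_config()].
#' @param n_perm permutations for the random-model comparison.
#' @param seed integer seed.
#' @return object of class `loto_result`: per-trial data frame, means/SDs,
#'   and `permutation_p`.
#' @export
leave_one_trial_out <- function(table, d, k, method = "hierarchical",
                                embedder = c("vae", "pca"), vae_args = list(),
                                n_perm = 1000L, seed = 1L) {
  embedder <- match.arg(embedder)
  trials <- unique(table$trial_id)
  if (length(trials) < 3L) stop("need at least 3 trials", call. = FALSE)
  full <- phenomap(table, d_grid = d, k_grid = k, method = method,
                   embedder = embedder, vae_args = vae_args,
                   B = 10L, seed = derive_seed(seed, "full"))
  full_labels <- full$solution$labels
  ids <- table$patient_id %||% seq_len(nrow(table))
  per <- list(); preds <- list()
  for (t in trials) {
    hold <- table$trial_id == t
    if (sum(!hold) < k || sum(hold) < 2L) {
      warning("trial ", t, " skipped: too few patients", call. = FALSE)
      next
    }
    fold <- phenomap(table[!hold, , drop = FALSE], d_grid = d, k_grid = k,
                     method = method, embedder = embedder, vae_args = vae_args,
                     B = 10L, seed = derive_seed(seed, paste0("fold", t)))
    ari_iter <- adjusted_rand_index(fold$solution$labels, full_labels[!hold])
    pred <- predict(fold, table[hold, , drop = FALSE])
    ari_pred <- adjusted_rand_index(pred, full_labels[hold])
    per[[length(per) + 1L]] <- data.frame(trial_id = t,
                                          ari_iteration = ari_iter,
                                          ari_prediction = ari_pred)
    preds[[as.character(t)]] <- list(pred = pred, idx = which(hold))
  }
  per <- do.call(rbind, per)
  obs_mean <- mean(per$ari_prediction)
  null_means <- with_seed(derive_seed(seed, "perm"), {
    vapply(seq_len(n_perm), function(r) {
      mean(vapply(preds, function(pp) {
        adjusted_rand_index(pp$pred, sample(full_labels[pp$idx]))
      }, numeric(1)))
    }, numeric(1))
  })
  p <- (1 + sum(null_means >= obs_mean)) / (n_perm + 1)
  structure(list(per_trial = per,
                 mean_ari_iteration = mean(per$ari_iteration),
                 sd_ari_iteration = stats::sd(per$ari_iteration),
                 mean_ari_prediction = obs_mean,
                 sd_ari_prediction = stats::sd(per$ari_prediction),
                 permutation_p = p, n_perm = n_perm,
                 d = d, k = k, method = method, embedder = embedder),
            class = "loto_result")
}

#' @export
print.loto_result <- function(x, ...) {
  cat(sprintf(paste0("loto_result over %d trials: iteration ARI %.3f (SD %.3f), ",
                     "prediction ARI %.3f (SD %.3f), permutation p = %.4f\n"),
              nrow(x$per_trial), x$mean_ari_iteration, x$sd_ari_iteration,
              x$mean_ari_prediction, x$sd_ari_prediction, x$permutation_p))
  invisible(x)
}
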