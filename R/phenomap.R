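# The central model object: a fitted phenotype map of one rhythm stratum —
# embedding (VAE or PCA), gap-selected cluster solution, and everything
# needed to place new patients into the discovered clusters.

#' Fit a phenotype map of a patient stratum
#'
#' Encodes the prespecified baseline variables, fits the embedder over a grid
#' of latent dimensions, clusters the latent coordinates over a grid of
#' cluster numbers, and selects the `(d*, k*)` with the highest gap
#' statistic.  When the table carries the outcome column, cluster ids are
#' canonicalised in ascending order of observed mortality (cluster 1 =
#' lowest risk) so numbering is stable across runs.
#'
#' @param x a prepared single-stratum patient table (complete cases), or a
#'   `feature_matrix` from [encode_features()].
#' @param d_grid,k_grid candidate latent dimensions and cluster numbers; a
#'   single cell (one d, one k) skips the selection sweep apart from the gap
#'   evaluation of that cell.
#' @param method clustering backend: `"hierarchical"` (Ward, the primary
#'   method) or `"kmeanspp"`.
#' @param B reference datasets per gap evaluation.
#' @param seed master seed; every stochastic stage derives its own seed from
#'   it.
#' @param embedder `"vae"` (default) or `"pca"`.
#' @param vae_args overrides for [vae_config()], e.g. `list(epochs = 40)`.
#' @return object of class `phenomap`.
#' @export
phenomap <- function(x, d_grid = 2:12, k_grid = 2:10,
                     method = c("hierarchical", "kmeanspp"), B = 50L,
                     seed = 1L, embedder = c("vae", "pca"),
                     vae_args = list()) {
  method <- match.arg(method); embedder <- match.arg(embedder)
  if (inherits(x, "feature_matrix")) {
    X <- x; table <- NULL
  } else {
    table <- x
    X <- encode_features(table)
  }
  sel <- select_model(X, d_grid = d_grid, k_grid = k_grid, method = method,
                      B = B, seed = seed, embedder = embedder,
                      vae_args = vae_args)
  sol <- sel$solution
  if (!is.null(table) && "death" %in% names(table)) {
    sol$labels <- canonicalise_labels(sol$labels, table$death)
    sol$centroids <- cluster_centroids(sel$embedding$coords, sol$labels)
    sol$sizes <- as.integer(base::table(sol$labels))
  }
  structure(list(features = X, table = table, gap = sel$gap, solution = sol,
                 embedding = sel$embedding, embedder = sel$embedder,
                 embedder_type = embedder, method = method, seed = seed,
                 call = match.call()),
            class = "phenomap")
}

# latent coordinates of new data on the reference scale
phenomap_embed_new <- function(object, X_new) {
  if (object$embedder_type == "vae") {
    encode_mean(object$embedder, X_new)$coords
  } else {
    sweep(X_new$values, 2, object$embedding$center) %*% object$embedding$rotation
  }
}

#' Predict cluster membership for new patients
#'
#' New data are standardised with the reference stratum's scaling
#' parameters, encoded with the reference embedder, and assigned to the
#' nearest reference centroid in latent space (Euclidean); exact ties go to
#' the lowest canonical label.  Idempotent: predicting twice gives identical
#' labels.
#'
#' @param object a fitted [phenomap()].
#' @param newdata patient table or `feature_matrix` with the training schema.
#' @param ... unused.
#' @return integer cluster labels.
#' @export
predict.phenomap <- function(object, newdata, ...) {
  X_new <- if (inherits(newdata, "feature_matrix")) newdata
           else encode_features(newdata, scaling = object$features$scaling)
  check_schema(object$features$schema, X_new)
  coords <- phenomap_embed_new(object, X_new)
  cent <- object$solution$centroids
  d2 <- vapply(seq_len(nrow(cent)), function(j)
    rowSums(sweep(coords, 2, cent[j, ])^2), numeric(nrow(coords)))
  d2 <- matrix(d2, nrow = nrow(coords))
  labs <- as.integer(rownames(cent))[max.col(-d2, ties.method = "first")]
  labs
}

#' @export
print.phenomap <- function(x, ...) {
  cat(sprintf("phenomap (%s embedding, %s clustering): d* = %d, k* = %d\n",
              x$embedder_type, x$method, x$solution$d, x$solution$k))
  cat(sprintf("  %d patients; cluster sizes %s; gap %.4f (se %.4f)%s\n",
              nrow(x$features$values),
              paste(x$solution$sizes, collapse = "/"),
              x$solution$gap, x$solution$gap_se,
              if (isTRUE(x$gap$weak_structure)) " [weak structure]" else ""))
  invisible(x)
}

#' @export
summary.phenomap <- function(object, ...) {
  structure(list(fit = object), class = "summary.phenomap")
}

#' @export
print.summary.phenomap <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nGap statistic (rows = latent dim, cols = k):\n")
  print(round(f$gap$gap_matrix, 3))
  cat("\nInternal indices of the selected solution:\n")
  print(round(f$solution$internal_indices, 3))
  if (!is.null(f$table) && "death" %in% names(f$table)) {
    cat("\nPer-cluster mortality:\n")
    print(round(tapply(f$table$death, f$solution$labels, mean), 3))
  }
  invisible(x)
}

#' @export
plot.phenomap <- function(x, ...) {
  if (is.null(x$table)) stop("no patient table attached; cannot profile",
                             call. = FALSE)
  prof <- cluster_profile(x$table, x$solution$labels)
  render_radar(prof, ...)
  invisible(x)
}
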