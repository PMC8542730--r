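# Orchestration of the full analysis: preparation -> embedding -> gap
# selection -> stability -> leave-one-trial-out validation -> per-cluster
# effect tables, per rhythm stratum, with seeded reproducibility and
# serialised artefacts.

#' Configure a pipeline run
#'
#' @param input path to a patient-table CSV, a patient table, or a
#'   [cohort_spec()] to simulate from.
#' @param stratum `"SR"`, `"AF"` or `"both"`.
#' @param d_grid,k_grid selection grids; single-cell grids skip the sweep.
#' @param method clustering backend.
#' @param embedder `"vae"` or `"pca"`.
#' @param B reference datasets per gap evaluation.
#' @param n_boot bootstrap iterations for the stability protocol.
#' @param frac bootstrap subset fraction.
#' @param n_perm permutations for the leave-one-trial-out comparison.
#' @param vae_args overrides for [vae_config()].
#' @param run_stability,run_loto,run_effects stage switches.
#' @param master_seed one seed; each stage derives its own from it.
#' @param output_dir directory for artefacts, or `NULL` to skip writing.
#' @return object of class `run_config`.
#' @export
run_config <- function(input, stratum = c("both", "SR", "AF"),
                       d_grid = 2:12, k_grid = 2:10,
                       method = c("hierarchical", "kmeanspp"),
                       embedder = c("vae", "pca"), B = 50L, n_boot = 100L,
                       frac = 0.8, n_perm = 1000L, vae_args = list(),
                       run_stability = TRUE, run_loto = TRUE,
                       run_effects = TRUE, master_seed = 1L,
                       output_dir = NULL) {
  stratum <- match.arg(stratum); method <- match.arg(method)
  embedder <- match.arg(embedder)
  stopifnot(B >= 10, n_boot >= 1, frac > 0, frac <= 1, n_perm >= 1,
            length(d_grid) >= 1, length(k_grid) >= 1)
  structure(list(input = input, stratum = stratum, d_grid = d_grid,
                 k_grid = k_grid, method = method, embedder = embedder,
                 B = as.integer(B), n_boot = as.integer(n_boot), frac = frac,
                 n_perm = as.integer(n_perm), vae_args = vae_args,
                 run_stability = run_stability, run_loto = run_loto,
                 run_effects = run_effects,
                 master_seed = as.integer(master_seed),
                 output_dir = output_dir),
            class = "run_config")
}

#' Execute the full clustering and validation pipeline
#'
#' Runs cohort preparation, phenotype mapping ([phenomap()]), bootstrap
#' stability, leave-one-trial-out validation and per-cluster effect
#' estimation for each requested rhythm stratum.  All randomness derives
#' from `master_seed`; rerunning with the same config reproduces every
#' numeric artefact.
#'
#' @param config a [run_config()].
#' @return object of class `pipeline_result`: per-stratum list with `fit`,
#'   `stability`, `loto`, `effects`, `profile`, plus the preparation
#'   `reports` and a `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  input <- config$input
  table <- if (inherits(input, "cohort_spec")) generate_cohort(input)
           else if (is.character(input)) read_cohort(input)
           else input
  table$true_cluster <- NULL  # the pipeline is blind to planted labels
  prep <- prepare_cohort(table)
  strata <- if (config$stratum == "both") c("SR", "AF") else config$stratum
  results <- list()
  for (str in strata) {
    tab <- prep$strata[[str]]$table
    if (is.null(tab) || nrow(tab) == 0L) {
      warning("stratum ", str, " is empty; skipped", call. = FALSE)
      next
    }
    seed_s <- derive_seed(config$master_seed, str)
    fit <- phenomap(tab, d_grid = config$d_grid, k_grid = config$k_grid,
                    method = config$method, B = config$B,
                    seed = derive_seed(seed_s, "fit"),
                    embedder = config$embedder, vae_args = config$vae_args)
    res <- list(fit = fit)
    if (config$run_stability) {
      res$stability <- bootstrap_stability(fit, n_boot = config$n_boot,
                                           frac = config$frac,
                                           seed = derive_seed(seed_s, "boot"))
    }
    if (config$run_loto && length(unique(tab$trial_id)) >= 3L) {
      res$loto <- leave_one_trial_out(tab, d = fit$solution$d,
                                      k = fit$solution$k,
                                      method = config$method,
                                      embedder = config$embedder,
                                      vae_args = config$vae_args,
                                      n_perm = config$n_perm,
                                      seed = derive_seed(seed_s, "loto"))
    }
    if (config$run_effects) {
      res$effects <- cluster_effect_table(tab, fit$solution$labels,
                                          prefix = str)
      res$profile <- cluster_profile(tab, fit$solution$labels)
    }
    results[[str]] <- res
  }
  manifest <- list(
    stratum = config$stratum, d_grid = config$d_grid, k_grid = config$k_grid,
    method = config$method, embedder = config$embedder, B = config$B,
    n_boot = config$n_boot, frac = config$frac, n_perm = config$n_perm,
    master_seed = config$master_seed,
    package_version = as.character(utils::packageVersion("bbcluster")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC"))
  out <- structure(list(strata = results, reports = prep$reports,
                        manifest = manifest, config = config),
                   class = "pipeline_result")
  if (!is.null(config$output_dir)) write_pipeline_artifacts(out, config$output_dir)
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result:\n")
  for (str in names(x$strata)) {
    cat(sprintf("-- stratum %s --\n", str))
    print(x$strata[[str]]$fit)
    if (!is.null(x$strata[[str]]$stability)) print(x$strata[[str]]$stability)
    if (!is.null(x$strata[[str]]$loto)) print(x$strata[[str]]$loto)
  }
  invisible(x)
}

# fixed directory schema: tables/, figures/, manifests/
write_pipeline_artifacts <- function(result, dir) {
  for (sub in c("tables", "figures", "manifests")) {
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  }
  jsonlite::write_json(result$manifest,
                       file.path(dir, "manifests", "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  for (str in names(result$strata)) {
    res <- result$strata[[str]]
    base <- function(name) file.path(dir, "tables", paste0(str, "_", name))
    utils::write.csv(data.frame(patient_id = res$fit$features$patient_id,
                                label = res$fit$solution$labels),
                     base("labels.csv"), row.names = FALSE)
    gm <- as.data.frame(res$fit$gap$gap_matrix)
    gm <- cbind(d = rownames(res$fit$gap$gap_matrix), gm)
    utils::write.csv(gm, base("gap_matrix.csv"), row.names = FALSE)
    if (!is.null(res$effects)) {
      utils::write.csv(res$effects, base("effects.csv"), row.names = FALSE)
    }
    if (!is.null(res$profile)) {
      utils::write.csv(res$profile, base("profile.csv"), row.names = FALSE)
    }
    if (!is.null(res$stability)) {
      jsonlite::write_json(unclass(res$stability),
                           file.path(dir, "manifests",
                                     paste0(str, "_stability.json")),
                           auto_unbox = TRUE, digits = NA)
    }
    if (!is.null(res$loto)) {
      lt <- unclass(res$loto)
      utils::write.csv(lt$per_trial, base("loto.csv"), row.names = FALSE)
      lt$per_trial <- NULL
      jsonlite::write_json(lt, file.path(dir, "manifests",
                                         paste0(str, "_loto.json")),
                           auto_unbox = TRUE, digits = NA)
    }
    if (!is.null(res$profile)) {
      render_radar(res$profile,
                   file = file.path(dir, "figures",
                                    paste0(str, "_radar.png")))
      for (g in sort(unique(res$profile$cluster))) {
        render_radar(res$profile[res$profile$cluster == g, , drop = FALSE],
                     file = file.path(dir, "figures",
                                      sprintf("%s_radar_cluster%s.png", str, g)))
      }
    }
  }
  invisible(dir)
}

#' Radar plots of per-cluster covariate profiles
#'
#' One radar polygon per cluster over the profiled variables (scaled value =
#' cluster median / cohort median for continuous variables, cluster
#' proportion / cohort proportion for binary ones), with the cohort average
#' as a reference ring at radius 1.
#'
#' @param profile profile table from [cluster_profile()].
#' @param file optional PNG path; when `NULL`, draws on the active device.
#' @param max_radius radial axis limit.
#' @return invisibly, the per-cluster coordinate list (for testing the
#'   geometry).
#' @export
render_radar <- function(profile, file = NULL, max_radius = 2) {
  if (!nrow(profile)) stop("empty profile", call. = FALSE)
  clusters <- sort(unique(profile$cluster))
  vars <- unique(profile$variable)
  ang <- seq(0, 2 * pi, length.out = length(vars) + 1L)[-(length(vars) + 1L)]
  coords <- list()
  for (g in clusters) {
    r <- vapply(vars, function(v) {
      val <- profile$scaled[profile$cluster == g & profile$variable == v]
      if (!length(val) || is.na(val)) 1 else val
    }, numeric(1))
    r <- pmin(r, max_radius)
    coords[[as.character(g)]] <- cbind(x = r * cos(ang), y = r * sin(ang),
                                       r = r)
  }
  draw <- function() {
    nc <- ceiling(sqrt(length(clusters)))
    nr <- ceiling(length(clusters) / nc)
    op <- graphics::par(mfrow = c(nr, nc), mar = c(1, 1, 2, 1))
    on.exit(graphics::par(op), add = TRUE)
    for (g in clusters) {
      graphics::plot(NA, xlim = c(-max_radius, max_radius),
                     ylim = c(-max_radius, max_radius), asp = 1, axes = FALSE,
                     xlab = "", ylab = "", main = paste("cluster", g))
      graphics::polygon(cos(seq(0, 2 * pi, length.out = 121)),
                        sin(seq(0, 2 * pi, length.out = 121)),
                        border = "orange", lwd = 2)
      xy <- coords[[as.character(g)]]
      graphics::polygon(xy[, "x"], xy[, "y"], border = "steelblue",
                        col = grDevices::adjustcolor("steelblue", 0.3))
      graphics::text(1.1 * max_radius * cos(ang), 1.1 * max_radius * sin(ang),
                     vars, cex = 0.6, xpd = NA)
    }
  }
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 900)
    on.exit(grDevices::dev.off(), add = TRUE)
    draw()
  } else {
    draw()
  }
  invisible(coords)
}
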