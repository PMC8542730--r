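# Per-cluster intention-to-treat effect estimation from 2x2 mortality
# tables: odds ratios (Woolf confidence intervals), risk ratios, absolute
# risk reduction, number needed to treat, annualised mortality.

#' A 2x2 mortality table
#'
#' @param deaths_bb,n_bb deaths and randomised patients in the beta-blocker
#'   arm.
#' @param deaths_placebo,n_placebo same for the placebo arm.
#' @return object of class `two_by_two`.
#' @export
two_by_two <- function(deaths_bb, n_bb, deaths_placebo, n_placebo) {
  if (n_bb <= 0 || n_placebo <= 0) stop("both arms must be non-empty", call. = FALSE)
  if (deaths_bb < 0 || deaths_bb > n_bb || deaths_placebo < 0 ||
      deaths_placebo > n_placebo) {
    stop("deaths must lie in [0, n] for each arm", call. = FALSE)
  }
  structure(list(deaths_bb = deaths_bb, n_bb = n_bb,
                 deaths_placebo = deaths_placebo, n_placebo = n_placebo),
            class = "two_by_two")
}

# cells a = deaths_bb, b = survivors_bb, c = deaths_placebo, d = survivors_placebo,
# with the Haldane-Anscombe 0.5 correction iff any cell is zero
tbt_cells <- function(t) {
  cells <- c(a = t$deaths_bb, b = t$n_bb - t$deaths_bb,
             c = t$deaths_placebo, d = t$n_placebo - t$deaths_placebo)
  if (any(cells == 0)) cells <- cells + 0.5
  cells
}

#' Odds ratio with Woolf confidence interval and chi-square p-value
#'
#' `OR = (deaths_bb / survivors_bb) / (deaths_placebo / survivors_placebo)`;
#' 95% CI `exp(log OR +- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`; two-tailed
#' Pearson chi-square p without continuity correction.  A 0.5 correction is
#' added to all cells when any cell is zero; the OR is undefined (NA) when
#' there are no deaths in either arm.
#'
#' @param t a [two_by_two()].
#' @param conf_level confidence level.
#' @return list with `or`, `ci_low`, `ci_high`, `p`.
#' @export
odds_ratio <- function(t, conf_level = 0.95) {
  stopifnot(inherits(t, "two_by_two"))
  if (t$deaths_bb == 0 && t$deaths_placebo == 0) {
    return(list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                p = NA_real_))
  }
  cells <- tbt_cells(t)
  or <- (cells["a"] / cells["b"]) / (cells["c"] / cells["d"])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- exp(log(or) + c(-1, 1) * z * se)
  m <- matrix(c(t$deaths_bb, t$n_bb - t$deaths_bb,
                t$deaths_placebo, t$n_placebo - t$deaths_placebo),
              nrow = 2, byrow = TRUE)
  p <- tryCatch(suppressWarnings(stats::chisq.test(m, correct = FALSE)$p.value),
                error = function(e) NA_real_)
  list(or = unname(or), ci_low = ci[1], ci_high = ci[2], p = p)
}

#' Risk ratio with log-scale confidence interval
#'
#' @inheritParams odds_ratio
#' @return list with `rr`, `ci_low`, `ci_high`.
#' @export
risk_ratio <- function(t, conf_level = 0.95) {
  stopifnot(inherits(t, "two_by_two"))
  if (t$deaths_bb == 0 && t$deaths_placebo == 0) {
    return(list(rr = NA_real_, ci_low = NA_real_, ci_high = NA_real_))
  }
  if (t$deaths_bb == 0 || t$deaths_placebo == 0) {
    a <- t$deaths_bb + 0.5; n1 <- t$n_bb + 0.5
    c_ <- t$deaths_placebo + 0.5; n0 <- t$n_placebo + 0.5
  } else {
    a <- t$deaths_bb; n1 <- t$n_bb
    c_ <- t$deaths_placebo; n0 <- t$n_placebo
  }
  rr <- (a / n1) / (c_ / n0)
  se <- sqrt(1 / a - 1 / n1 + 1 / c_ - 1 / n0)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- exp(log(rr) + c(-1, 1) * z * se)
  list(rr = rr, ci_low = ci[1], ci_high = ci[2])
}

#' Absolute risk reduction and number needed to treat
#'
#' `ARR = risk_placebo - risk_bb`, with a Wald confidence interval on the
#' risk difference; `NNT = 1 / ARR`, reported only when the ARR interval
#' excludes zero (otherwise `NA`, the "not applicable" convention when the
#' absolute risk reduction is not significant).
#'
#' @inheritParams odds_ratio
#' @return list with `arr`, `ci_low`, `ci_high`, `nnt`.
#' @export
arr_nnt <- function(t, conf_level = 0.95) {
  stopifnot(inherits(t, "two_by_two"))
  p1 <- t$deaths_bb / t$n_bb
  p0 <- t$deaths_placebo / t$n_placebo
  arr <- p0 - p1
  se <- sqrt(p1 * (1 - p1) / t$n_bb + p0 * (1 - p0) / t$n_placebo)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- arr + c(-1, 1) * z * se
  significant <- ci[1] > 0 || ci[2] < 0
  nnt <- if (significant && arr != 0) 1 / arr else NA_real_
  list(arr = arr, ci_low = ci[1], ci_high = ci[2], nnt = nnt)
}

#' Annualised mortality rate
#'
#' @param deaths number of deaths.
#' @param person_years total follow-up time in person-years.
#' @return deaths per 100 person-years.
#' @export
annualised_mortality <- function(deaths, person_years) {
  if (person_years <= 0) stop("person_years must be positive", call. = FALSE)
  100 * deaths / person_years
}

effect_row <- function(cluster_id, t, person_years = NULL) {
  or <- odds_ratio(t); rr <- risk_ratio(t); an <- arr_nnt(t)
  data.frame(
    cluster = cluster_id,
    deaths_placebo = t$deaths_placebo, n_placebo = t$n_placebo,
    deaths_bb = t$deaths_bb, n_bb = t$n_bb,
    or = or$or, or_low = or$ci_low, or_high = or$ci_high,
    rr = rr$rr, rr_low = rr$ci_low, rr_high = rr$ci_high,
    arr = an$arr, arr_low = an$ci_low, arr_high = an$ci_high,
    nnt = an$nnt, p = or$p,
    annualised_mortality = if (is.null(person_years)) NA_real_ else
      annualised_mortality(t$deaths_bb + t$deaths_placebo, person_years),
    stringsAsFactors = FALSE)
}

#' Per-cluster intention-to-treat effect table
#'
#' One row per cluster in canonical order plus an `"all"` row for the whole
#' stratum; outcomes attributed to the randomised arm (intention to treat).
#' Clusters with a single-arm population are flagged with `NA` estimates.
#' When `followup_years` is present, annualised mortality (deaths per 100
#' person-years) is included.
#'
#' @param table patient table with `arm` and `death` (and optionally
#'   `followup_years`).
#' @param labels cluster labels aligned with the table.
#' @param prefix optional string prefixed to cluster ids (e.g. `"SR"`).
#' @return data.frame of effect rows.
#' @export
cluster_effect_table <- function(table, labels, prefix = "") {
  stopifnot(all(c("arm", "death") %in% names(table)),
            nrow(table) == length(labels))
  py <- if ("followup_years" %in% names(table)) table$followup_years else NULL
  mk <- function(sel, id) {
    bb <- sel & table$arm == "bb"; pl <- sel & table$arm == "placebo"
    if (!sum(bb) || !sum(pl)) {
      row <- effect_row(id, two_by_two(0, 1, 0, 1),
                        if (is.null(py)) NULL else sum(py[sel]))
      row[c("or", "or_low", "or_high", "rr", "rr_low", "rr_high",
            "arr", "arr_low", "arr_high", "nnt", "p")] <- NA_real_
      row$deaths_bb <- sum(table$death[bb]); row$n_bb <- sum(bb)
      row$deaths_placebo <- sum(table$death[pl]); row$n_placebo <- sum(pl)
      return(row)
    }
    effect_row(id, two_by_two(sum(table$death[bb]), sum(bb),
                              sum(table$death[pl]), sum(pl)),
               if (is.null(py)) NULL else sum(py[sel]))
  }
  rows <- lapply(sort(unique(labels)), function(g)
    mk(labels == g, paste0(prefix, g)))
  out <- rbind(mk(rep(TRUE, nrow(table)), paste0(prefix, "all")),
               do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Effect table from a CSV of 2x2 counts
#'
#' Accepts a bare table of per-cluster counts (columns `cluster`,
#' `deaths_bb`, `n_bb`, `deaths_placebo`, `n_placebo`), e.g. counts
#' transcribed from a publication, and computes the same effect measures as
#' [cluster_effect_table()].
#'
#' @param counts data.frame or path to a CSV file.
#' @return data.frame of effect rows.
#' @export
effect_table_from_counts <- function(counts) {
  if (is.character(counts)) counts <- utils::read.csv(counts)
  need <- c("cluster", "deaths_bb", "n_bb", "deaths_placebo", "n_placebo")
  if (!all(need %in% names(counts))) {
    stop("counts needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  out <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    effect_row(counts$cluster[i],
               two_by_two(counts$deaths_bb[i], counts$n_bb[i],
                          counts$deaths_placebo[i], counts$n_placebo[i]))
  }))
  rownames(out) <- NULL
  out
}

#' Published per-cluster mortality counts from the pooled beta-blocker trials
#'
#' The per-cluster 2x2 all-cause mortality counts (deaths/N per randomised
#' arm for the sinus-rhythm and atrial-fibrillation strata and their
#' clusters) as published for the pooled nine-trial beta-blocker heart
#' failure cohort.  Used as a fixed input to reproduce the published odds
#' ratios and numbers needed to treat.
#'
#' @return data.frame with columns `cluster`, `deaths_bb`, `n_bb`,
#'   `deaths_placebo`, `n_placebo`.
#' @export
published_counts <- function() {
  utils::read.csv(system.file("extdata", "table2_counts.csv",
                              package = "bbcluster"))
}
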