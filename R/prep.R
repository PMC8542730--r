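# Cohort preparation: inclusion/exclusion rules, complete-case filtering,
# rhythm stratification and encoding of the prespecified baseline variables
# into a typed feature matrix.

#' Apply the trial-pooling exclusion rules
#'
#' Removes participants with LVEF of 50% or more and those with a paced,
#' other or missing baseline ECG rhythm; atrial flutter is relabelled into
#' the atrial fibrillation group.  Rows with missing LVEF are excluded (the
#' inclusion rule cannot be verified for them).
#'
#' @param table a patient table with columns `lvef` and `rhythm_raw`.
#' @return a list with `table` (filtered, plus a `rhythm` column in
#'   `{"SR","AF"}`) and `report` (a data.frame of exclusion counts mirroring
#'   the study flowchart).
#' @export
apply_exclusions <- function(table) {
  stopifnot(all(c("lvef", "rhythm_raw") %in% names(table)))
  n0 <- nrow(table)
  lvef_high <- !is.na(table$lvef) & table$lvef >= 50
  lvef_missing <- is.na(table$lvef)
  tab <- table[!(lvef_high | lvef_missing), , drop = FALSE]
  rhythm <- as.character(tab$rhythm_raw)
  rhythm[is.na(rhythm)] <- "missing"
  rhythm[rhythm == "flutter"] <- "AF"
  keep <- rhythm %in% c("SR", "AF")
  n_rhythm <- sum(!keep)
  tab <- tab[keep, , drop = FALSE]
  tab$rhythm <- rhythm[keep]
  if (nrow(tab) == 0L) warning("all rows excluded", call. = FALSE)
  report <- data.frame(
    step = c("input", "lvef_ge_50", "lvef_missing", "rhythm_excluded", "retained"),
    n = c(n0, sum(lvef_high), sum(lvef_missing), n_rhythm, nrow(tab))
  )
  list(table = tab, report = report)
}

#' Complete-case filter
#'
#' Drops every row with a missing value in any of the listed variables, the
#' complete-case rule used to establish the clustering subsets (no
#' imputation, to avoid bias when data are not missing completely at
#' random).
#'
#' @param table a patient table.
#' @param variables character vector of column names to require.
#' @return list with `table` (complete cases) and `report`: per-variable
#'   missing counts plus `n_removed` overall (rows missing more than one
#'   variable counted once).
#' @export
complete_case_filter <- function(table, variables = feature_variables()) {
  bad <- setdiff(variables, names(table))
  if (length(bad)) stop("unknown variable(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (!length(variables)) {
    return(list(table = table,
                report = list(per_variable = integer(0), n_removed = 0L)))
  }
  miss <- vapply(variables, function(v) is.na(table[[v]]),
                 logical(nrow(table)))
  miss <- matrix(miss, nrow = nrow(table),
                 dimnames = list(NULL, variables))
  drop <- rowSums(miss) > 0
  list(table = table[!drop, , drop = FALSE],
       report = list(per_variable = colSums(miss), n_removed = sum(drop)))
}

#' Stratify a prepared table by baseline rhythm
#'
#' @param table a patient table after [apply_exclusions()] (column `rhythm`).
#' @return list with elements `SR` and `AF`; their union is the input.
#' @export
stratify_by_rhythm <- function(table) {
  stopifnot("rhythm" %in% names(table))
  list(SR = table[table$rhythm == "SR", , drop = FALSE],
       AF = table[table$rhythm == "AF", , drop = FALSE])
}

#' Encode the prespecified baseline variables as a typed feature matrix
#'
#' Continuous variables are standardised to zero mean and unit standard
#' deviation using the statistics of the table itself (i.e. of the analysis
#' stratum); NYHA class is binarised to III/IV vs I/II and gender to an
#' indicator of female sex; drug-therapy flags pass through.  Treatment arm
#' and outcome are never encoded: clustering must be blind to both.
#'
#' @param table complete-case patient table.
#' @param scaling optional scaling parameters from a reference stratum (as
#'   stored in the result), used to encode new data on the reference scale.
#' @return object of class `feature_matrix`: list with `values` (n x 13
#'   numeric matrix), `schema` (data.frame of name/type), `scaling`
#'   (per-continuous-variable centre and spread) and `patient_id`.
#' @export
encode_features <- function(table, scaling = NULL) {
  cv <- continuous_variables(); bv <- binary_variables()
  need <- c(cv, bv)
  bad <- setdiff(need, names(table))
  if (length(bad)) stop("missing column(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  n <- nrow(table)
  cols <- list()
  for (v in cv) {
    x <- table[[v]]
    if (anyNA(x)) stop("missing values in ", v, "; run complete_case_filter first",
                       call. = FALSE)
    cols[[v]] <- as.numeric(x)
  }
  cols$gender <- as.numeric(table$gender == "female")
  cols$prior_mi <- as.numeric(table$prior_mi)
  cols$nyha <- as.numeric(table$nyha %in% c(3, 4))
  for (v in c("acei_arb", "diuretic", "anticoagulant", "digoxin")) {
    cols[[v]] <- as.numeric(table[[v]])
  }
  vals <- do.call(cbind, cols)
  binm <- vals[, bv, drop = FALSE]
  if (anyNA(binm) || !all(binm %in% c(0, 1))) {
    stop("binary columns must be 0/1 with no missing values", call. = FALSE)
  }
  if (is.null(scaling)) {
    if (n < 2L) stop("need at least 2 rows to estimate spread", call. = FALSE)
    centre <- colMeans(vals[, cv, drop = FALSE])
    spread <- apply(vals[, cv, drop = FALSE], 2, stats::sd)
    zero <- spread <= 0 | !is.finite(spread)
    if (any(zero)) stop("zero spread in continuous column(s): ",
                        paste(cv[zero], collapse = ", "), call. = FALSE)
    scaling <- list(centre = centre, spread = spread)
  }
  vals[, cv] <- sweep(sweep(vals[, cv, drop = FALSE], 2, scaling$centre),
                      2, scaling$spread, "/")
  structure(list(
    values = vals,
    schema = data.frame(name = c(cv, bv),
                        type = c(rep("continuous", length(cv)),
                                 rep("binary", length(bv)))),
    scaling = scaling,
    patient_id = table$patient_id %||% seq_len(n)),
    class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d patients x %d features (%d continuous, %d binary)\n",
              nrow(x$values), ncol(x$values),
              sum(x$schema$type == "continuous"), sum(x$schema$type == "binary")))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

# subset rows of a feature matrix, keeping schema and scaling
fm_subset <- function(X, idx) {
  structure(list(values = X$values[idx, , drop = FALSE],
                 schema = X$schema, scaling = X$scaling,
                 patient_id = X$patient_id[idx]),
            class = "feature_matrix")
}

#' One-call preparation of a raw patient table
#'
#' Applies exclusions, the complete-case rule and rhythm stratification,
#' returning encoded feature matrices per stratum together with the
#' flowchart-style reports.
#'
#' @param table raw patient table (e.g. from [read_cohort()]).
#' @param variables variables required complete and encoded.
#' @return list with `strata` (named list of lists: `table`, `features`),
#'   and `reports`.
#' @export
prepare_cohort <- function(table, variables = feature_variables()) {
  ex <- apply_exclusions(table)
  cc <- complete_case_filter(ex$table, variables)
  st <- stratify_by_rhythm(cc$table)
  strata <- lapply(st, function(tab) {
    if (nrow(tab) == 0L) return(list(table = tab, features = NULL))
    list(table = tab, features = encode_features(tab))
  })
  list(strata = strata,
       reports = list(exclusions = ex$report, complete_case = cc$report))
}
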